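#' Scale base-year crop grids to country annual totals
#'
#' Distributes each country's annual grain production (and harvested area)
#' over its cells in proportion to the cell's share of the country total in
#' the base-year grid, turning a single gridded snapshot plus country
#' tables into a gridded time series.
#'
#' @param base_grid per-crop base-year production `grid_field` (Mg/yr).
#' @param base_area per-crop base-year harvested-area `grid_field` (ha).
#' @param countries a [country_series()] carrying `grain.<crop>` and
#'   `area.<crop>`.
#' @param mask a [country_mask()] on the same grid.
#' @param crop crop class name.
#' @param year target calendar year.
#' @return list with `production` and `area` grid_fields for `year`, plus
#'   `uncovered`: countries with table production but no base-year gridded
#'   production (their mass cannot be placed and is flagged, not dropped
#'   silently).
#' @export
scale_grain_to_country <- function(base_grid, base_area, countries, mask,
                                   crop, year) {
  stopifnot(inherits(base_grid, "grid_field"), inherits(mask, "country_mask"))
  if (!year %in% countries$years) stop("year outside configured range")
  tot_p <- cs_value(countries, paste0("grain.", crop), year)
  tot_a <- cs_value(countries, paste0("area.", crop), year)
  absent <- setdiff(names(tot_p), mask$countries)
  if (length(absent)) {
    warning("countries absent from mask skipped: ",
            paste(absent, collapse = ", "))
    tot_p <- tot_p[!names(tot_p) %in% absent]
    tot_a <- tot_a[!names(tot_a) %in% absent]
  }
  if (any(tot_p < 0, na.rm = TRUE) || any(tot_a < 0, na.rm = TRUE))
    stop("negative country totals")
  tot_p[is.na(tot_p)] <- 0
  tot_a[is.na(tot_a)] <- 0

  base_p <- country_sums(base_grid$values, mask)
  base_a <- country_sums(base_area$values, mask)
  uncovered <- names(tot_p)[tot_p > 0 &
                              base_p[names(tot_p)] <= 0]

  scale_one <- function(base_vals, base_tot, target) {
    fac <- ifelse(base_tot[names(target)] > 0,
                  target / base_tot[names(target)], 0)
    fac_grid <- country_to_grid(fac, mask)
    out <- base_vals * fac_grid
    out[is.na(out)] <- 0
    out
  }
  list(
    production = gf_like(base_grid, scale_one(base_grid$values, base_p, tot_p),
                         year = year),
    area = gf_like(base_area, scale_one(base_area$values, base_a, tot_a),
                   year = year, units = "ha"),
    uncovered = uncovered
  )
}

#' Residue yield from grain yield, exponential form
#'
#' R = a Y exp(-b Y) for Y <= 1/b, and the plateau a/(b e) above, so the
#' residue yield rises with grain yield, peaks at Y = 1/b and stays flat
#' beyond; the function is continuous at the junction.
#'
#' @param yield grain yield, Mg/ha (vectorised, >= 0).
#' @param crop crop class name.
#' @param params harvest-index table from [harvest_index_params()].
#' @return residue yield, Mg/ha.
#' @export
residue_yield_exponential <- function(yield, crop,
                                      params = harvest_index_params()) {
  i <- match(crop, params$crop)
  if (is.na(i)) stop("unknown crop: ", crop)
  a <- params$a[i]; b <- params$b[i]
  ifelse(yield <= 1 / b, a * yield * exp(-b * yield), a / (b * exp(1)))
}

#' Residue yield from grain yield, linear form
#'
#' R = Y (c - d Y), clamped at zero for yields beyond c/d where the fitted
#' parabola would go negative (mass cannot be negative).
#'
#' @inheritParams residue_yield_exponential
#' @return residue yield, Mg/ha.
#' @export
residue_yield_linear <- function(yield, crop,
                                 params = harvest_index_params()) {
  i <- match(crop, params$crop)
  if (is.na(i)) stop("unknown crop: ", crop)
  pmax(0, yield * (params$c[i] - params$d[i] * yield))
}

#' Residue production by fixed region-specific ratios
#'
#' Multiplies grain production by a constant residue-to-grain ratio looked
#' up by (region, crop) through the mask's `constant_ratio` region map.
#'
#' @param production per-crop grain-production `grid_field` (Mg/yr).
#' @param mask a [country_mask()].
#' @param crop crop class name.
#' @param ratios table from [constant_residue_ratios()].
#' @return residue-production `grid_field` (Mg/yr).
#' @export
residue_from_ratio <- function(production, mask, crop,
                               ratios = constant_residue_ratios()) {
  regions <- region_matrix(mask, "constant_ratio")
  used <- unique(regions[!is.na(regions) & production$values > 0])
  tab <- ratios[ratios$crop == crop, ]
  missing <- setdiff(used, tab$region)
  if (length(missing))
    stop("no constant ratio for region(s) ", paste(missing, collapse = ", "),
         " and crop ", crop)
  r <- matrix(tab$ratio[match(regions, tab$region)],
              nrow(regions), ncol(regions))
  out <- production$values * r
  out[is.na(out)] <- 0
  gf_like(production, out)
}

# Per-cell grain yield with a guard against near-zero areas: cells with
# less than `min_area` ha are treated as zero-yield so production/area
# noise cannot explode.
cell_yield <- function(production, area, min_area = 1e-6) {
  y <- matrix(0, nrow(production$values), ncol(production$values))
  ok <- area$values > min_area
  y[ok] <- production$values[ok] / area$values[ok]
  y
}

#' Per-crop residue production by one method
#'
#' Dispatches on the production method: `"constant"` applies the fixed
#' ratios to grain production; `"exponential"` and `"linear"` convert the
#' per-cell grain yield (production / harvested area) to a residue yield
#' and multiply by area, so zero-area cells produce zero residue.
#'
#' @param method one of `"constant"`, `"exponential"`, `"linear"`.
#' @param production,area per-crop grid_fields for one year.
#' @param mask a [country_mask()]. @param crop crop class name.
#' @param hi_params harvest-index table. @param ratios constant-ratio table.
#' @return residue-production `grid_field` (Mg/yr).
#' @export
residue_production_method <- function(method, production, area, mask, crop,
                                      hi_params = harvest_index_params(),
                                      ratios = constant_residue_ratios()) {
  method <- match.arg(method, c("constant", "exponential", "linear"))
  if (method == "constant")
    return(residue_from_ratio(production, mask, crop, ratios))
  y <- cell_yield(production, area)
  r <- switch(method,
              exponential = residue_yield_exponential(y, crop, hi_params),
              linear = residue_yield_linear(y, crop, hi_params))
  gf_like(production, matrix(r, nrow(y), ncol(y)) * area$values)
}

#' Total cereal residue production
#'
#' Cellwise sum of the per-crop residue fields.
#'
#' @param crop_fields list of per-crop residue `grid_field`s on one grid.
#' @return total residue-production `grid_field`.
#' @export
total_cereal_residue <- function(crop_fields) {
  stopifnot(length(crop_fields) >= 1)
  do.call(stopifnot_same_grid, crop_fields)
  vals <- Reduce(`+`, lapply(crop_fields, function(g) g$values))
  gf_like(crop_fields[[1]], vals)
}

#' Mean of the three production methods
#'
#' Cellwise arithmetic mean of the totals from the constant, exponential
#' and linear methods.
#'
#' @param method_fields list of exactly three total-residue `grid_field`s.
#' @return mean residue-production `grid_field`.
#' @export
mean_production <- function(method_fields) {
  if (length(method_fields) != 3)
    stop("mean_production needs the three method outputs")
  do.call(stopifnot_same_grid, method_fields)
  vals <- Reduce(`+`, lapply(method_fields, function(g) g$values)) / 3
  gf_like(method_fields[[1]], vals)
}
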