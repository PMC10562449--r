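#' Annual agricultural burning from monthly gridded fields
#'
#' Sums twelve monthly 0.25 deg agricultural-burning fields to an annual
#' total and aggregates to the 0.5 deg pipeline grid by summation, so the
#' global burnt mass is conserved.
#'
#' @param monthly list of 12 `grid_field`s (0.25 deg, Mg/month).
#' @return annual burning `grid_field` at 0.5 deg (Mg/yr).
#' @export
aggregate_gridded_burning <- function(monthly) {
  if (length(monthly) != 12) stop("need 12 monthly fields")
  do.call(stopifnot_same_grid, monthly)
  annual <- Reduce(`+`, lapply(monthly, function(g) g$values))
  aggregate_to_half_degree(gf_like(monthly[[1]], annual))
}

#' Annual agricultural burning from point fire records
#'
#' Bins the biomass burnt by agricultural fires of one year onto the grid.
#' Non-agricultural vegetation classes (forest, savanna, ...) are excluded;
#' records outside the grid extent are dropped with a warning.
#'
#' @param records data.frame with columns lat, lon, date (Date or
#'   yyyy-mm-dd string), biomass_burnt (Mg), vegetation_class.
#' @param year calendar year to aggregate.
#' @param template `grid_field` defining the target grid.
#' @return burning `grid_field` (Mg/yr).
#' @export
aggregate_fire_records <- function(records, year, template) {
  vals <- matrix(0, length(template$lat), length(template$lon))
  if (nrow(records)) {
    if (any(records$biomass_burnt < 0)) stop("negative biomass in records")
    yr <- as.integer(format(as.Date(records$date), "%Y"))
    keep <- records$vegetation_class == "agricultural" & yr == year
    rec <- records[keep, , drop = FALSE]
    if (nrow(rec)) {
      ij <- cell_index(template, rec$lat, rec$lon)
      out <- is.na(ij$row) | is.na(ij$col)
      if (any(out)) {
        warning(sum(out), " fire record(s) outside grid extent dropped")
        rec <- rec[!out, , drop = FALSE]
        ij <- lapply(ij, function(v) v[!out])
      }
      if (nrow(rec)) {
        lin <- ij$row + (ij$col - 1L) * length(template$lat)
        add <- rowsum(rec$biomass_burnt, lin)
        vals[as.integer(rownames(add))] <- vals[as.integer(rownames(add))] +
          as.vector(add)
      }
    }
  }
  grid_field(vals, template$lat, template$lon, year = year, units = "Mg/yr")
}

#' Cap burning at 90 % of residue production
#'
#' On-field burning in a cell cannot exceed `cap` times the cereal residue
#' production there; this also absorbs burning of non-cereal residues
#' (e.g. sugar cane) present in the fire data.
#'
#' @param burn,production `grid_field`s on one grid.
#' @param cap removal cap (default 0.90).
#' @return capped burning `grid_field`.
#' @export
cap_burning <- function(burn, production, cap = 0.90) {
  stopifnot_same_grid(burn, production)
  gf_like(burn, pmin(burn$values, cap * production$values))
}

#' Mean of the available burning datasets
#'
#' Cellwise mean of the per-dataset annual burning grids. Years covered by
#' only one dataset use that dataset alone (point-record inventories start
#' later than the gridded record; burning is never fabricated for
#' uncovered years).
#'
#' @param fields list of 1 or 2 burning `grid_field`s for one year.
#' @return mean burning `grid_field`.
#' @export
mean_burning <- function(fields) {
  fields <- Filter(Negate(is.null), fields)
  if (!length(fields)) stop("no burning dataset available")
  do.call(stopifnot_same_grid, fields)
  vals <- Reduce(`+`, lapply(fields, function(g) g$values)) / length(fields)
  gf_like(fields[[1]], vals)
}
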