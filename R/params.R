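#' Cereal crop classes
#'
#' The seven crop classes the pipeline tracks. Any cereal outside the six
#' named classes is accounted under `other_cereals`.
#' @export
cereal_crops <- function() {
  c("barley", "maize", "rice", "wheat", "millet", "sorghum", "other_cereals")
}

#' Harvest-index parameters
#'
#' Per-crop coefficients for the two yield-dependent residue formulas:
#' `a` (dimensionless) and `b` (ha/Mg) for the exponential form
#' R = a Y exp(-bY) with plateau a/(b e) above Y = 1/b, and `c`
#' (dimensionless) and `d` (ha/Mg) for the linear form R = Y (c - dY).
#' Defaults are the fitted literature values for the seven cereal classes.
#'
#' @param overrides optional named list, e.g.
#'   `list(wheat = list(a = 2.0))`, merged over the defaults.
#' @return data.frame with columns crop, a, b, c, d.
#' @export
harvest_index_params <- function(overrides = NULL) {
  p <- data.frame(
    crop = cereal_crops(),
    a = c(1.822, 2.656, 2.450, 2.183, 1.900, 2.302, 1.900),
    b = c(0.149, 0.103, 0.084, 0.127, 0.250, 0.100, 0.250),
    c = c(2.77, 2.20, 2.56, 1.96, 4.38, 4.55, 2.70),
    d = c(0.27, 0.13, 0.22, 0.14, 0.95, 0.55, 0.20),
    stringsAsFactors = FALSE
  )
  if (!is.null(overrides)) {
    for (cr in names(overrides)) {
      i <- match(cr, p$crop)
      if (is.na(i)) stop("unknown crop in overrides: ", cr)
      for (f in names(overrides[[cr]])) p[i, f] <- overrides[[cr]][[f]]
    }
  }
  stopifnot(all(p$a > 0), all(p$b > 0), all(p$c > 0), all(p$d > 0))
  p
}

#' Constant residue-to-grain ratios by region and crop
#'
#' Fixed, time-invariant residue production ratios for the constant-ratio
#' method. The published compilations are regional; the defaults here are
#' plausible magnitudes (straw/stover roughly 1-1.7 times grain mass) and
#' are meant to be overridden from a YAML parameter file for real work.
#'
#' @param regions region names to cover (defaults to the generic set).
#' @param overrides optional named list `region -> crop -> ratio`.
#' @return data.frame with columns region, crop, ratio.
#' @export
constant_residue_ratios <- function(regions = c("default"), overrides = NULL) {
  base <- c(barley = 1.2, maize = 1.0, rice = 1.4, wheat = 1.3,
            millet = 1.7, sorghum = 1.6, other_cereals = 1.3)
  tab <- expand.grid(region = regions, crop = names(base),
                     stringsAsFactors = FALSE)
  tab$ratio <- base[tab$crop]
  if (!is.null(overrides)) {
    for (rg in names(overrides)) for (cr in names(overrides[[rg]])) {
      i <- which(tab$region == rg & tab$crop == cr)
      if (!length(i)) {
        tab <- rbind(tab, data.frame(region = rg, crop = cr,
                                     ratio = overrides[[rg]][[cr]]))
      } else tab$ratio[i] <- overrides[[rg]][[cr]]
    }
  }
  rownames(tab) <- NULL
  tab
}

#' Animal bedding straw rates
#'
#' Daily straw bedding per head, plus the yearly straw allowance horses
#' chew. All masses are straw as-is.
#'
#' @param overrides optional named list replacing individual rates.
#' @return list with `kg_per_day` (named: cattle, sheep_goat, horse, pig)
#'   and `horse_chewing_kg_yr`.
#' @export
bedding_rates <- function(overrides = NULL) {
  r <- list(kg_per_day = c(cattle = 0.375, sheep_goat = 0.1,
                           horse = 1.5, pig = 0.0625),
            horse_chewing_kg_yr = 420)
  if (!is.null(overrides)) {
    if (!is.null(overrides$kg_per_day))
      r$kg_per_day[names(overrides$kg_per_day)] <-
        unlist(overrides$kg_per_day)
    if (!is.null(overrides$horse_chewing_kg_yr))
      r$horse_chewing_kg_yr <- overrides$horse_chewing_kg_yr
  }
  stopifnot(all(r$kg_per_day >= 0), r$horse_chewing_kg_yr >= 0)
  r
}

#' Allocation constants
#'
#' All caps, thresholds and bounds used to close the per-cell mass balance:
#' at most `removal_cap` (90 %) of production may leave the field, so at
#' least `min_left_fraction` (10 %) stays; residues can be traded up to
#' `trade_radius_cells` grid cells; other off-field uses are bounded by
#' 30 % of production below `gdp_poor_threshold` ($ per capita, 2015
#' prices), 10 % above `gdp_rich_threshold`, linear in between; and a few
#' regions have a ceiling on the fraction left on field (`max_return`).
#'
#' @param ... individual fields to override (e.g. `trade_radius_cells = 5`).
#' @return list of allocation parameters.
#' @export
allocation_params <- function(...) {
  p <- list(
    removal_cap = 0.90,
    min_left_fraction = 0.10,
    trade_radius_cells = 20L,
    other_use_poor = 0.30,
    other_use_rich = 0.10,
    gdp_poor_threshold = 1046,
    gdp_rich_threshold = 12735,
    max_return = c(china = 0.60, europe = 0.70, north_america_oceania = 0.80),
    residue_energy_mj_kg = 18
  )
  ov <- list(...)
  for (f in names(ov)) {
    if (!f %in% names(p)) stop("unknown allocation parameter: ", f)
    p[[f]] <- ov[[f]]
  }
  stopifnot(abs(p$min_left_fraction - (1 - p$removal_cap)) < 1e-12,
            p$gdp_poor_threshold < p$gdp_rich_threshold,
            p$other_use_poor > 0, p$other_use_poor < 1,
            p$other_use_rich > 0, p$other_use_rich < 1,
            all(p$max_return > 0), all(p$max_return < 1))
  p
}

#' Load parameter overrides from a YAML file
#'
#' Reads a YAML file with optional top-level keys `harvest_index`,
#' `constant_ratios`, `bedding`, `allocation` and returns the corresponding
#' fully-resolved parameter objects.
#'
#' @param path YAML file path, or NULL for all defaults.
#' @return list with elements harvest_index, constant_ratios, bedding,
#'   allocation.
#' @export
load_params <- function(path = NULL) {
  ov <- if (is.null(path)) list() else yaml::read_yaml(path)
  list(
    harvest_index = harvest_index_params(ov$harvest_index),
    constant_ratios = constant_residue_ratios(overrides = ov$constant_ratios),
    bedding = bedding_rates(ov$bedding),
    allocation = do.call(allocation_params,
                         if (is.null(ov$allocation)) list() else ov$allocation)
  )
}

#' Domestic-fuel share of residue production
#'
#' Share of a residue supply consumed when a given amount of energy is
#' generated by burning residues, at a given energy content. The default
#' arguments reproduce the mid-1990s China bookkeeping: 4 EJ of domestic
#' fuel at 18 MJ/kg against 730 Tg/yr of residue production gives roughly
#' 30 %, the basis for the poor-country other-use bound.
#'
#' @param energy_ej energy generated, EJ/yr.
#' @param energy_content_mj_kg energy released per kg of residue, MJ/kg.
#' @param production_tg_yr residue production, Tg/yr.
#' @return fuel share as a percentage of production.
#' @export
domestic_fuel_share <- function(energy_ej = 4, energy_content_mj_kg = 18,
                                production_tg_yr = 730) {
  burnt_tg <- energy_ej * 1e12 / energy_content_mj_kg / 1e9  # MJ -> kg -> Tg
  100 * burnt_tg / production_tg_yr
}

#' Trade radius in kilometres at the equator
#'
#' Physical distance corresponding to the trade search radius, measured
#' along the equator: n cells x cell width in degrees x km per degree of
#' longitude at the equator (Earth circumference / 360).
#'
#' @param n_cells radius in grid cells. @param resolution_deg cell width.
#' @return distance in km.
#' @export
trade_radius_km <- function(n_cells = 20, resolution_deg = 0.5) {
  km_per_deg <- 40075.017 / 360
  n_cells * resolution_deg * km_per_deg
}
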