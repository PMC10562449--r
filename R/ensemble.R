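#' Stage caches for one world
#'
#' Pre-computes, per year, the three residue-production variants, the two
#' burning datasets (uncapped), the three animal-demand variants and the
#' time-invariant bedding demand, so that ensemble runs do not repeat
#' shared work across combos.
#'
#' @param world a `synth_world` (or any bundle with the same fields).
#' @param params parameter list from [load_params()].
#' @param years years to compute (default: the world's full range).
#' @return list with elements production (method -> year -> grid_field),
#'   burning (dataset -> year -> grid_field or NULL), demand
#'   (source -> year -> grid_field), years, and the 0.5 deg systems grid.
#' @export
pipeline_stages <- function(world, params = load_params(), years = NULL) {
  if (is.null(years)) years <- world$config$years
  mask <- world$mask
  crops <- names(world$base_production)
  systems <- dominant_systems(world$systems_fine)
  bedding <- bedding_demand(world$head_counts[c("cattle", "sheep_goat",
                                                "horses", "pigs")],
                            params$bedding)

  production <- list()
  for (m in c("constant", "exponential", "linear")) production[[m]] <- list()
  demand <- list()
  feed_tabs <- lapply(c(herrero = "herrero", mottet = "mottet",
                        mekonnen = "mekonnen"), feed_params)
  for (s in names(feed_tabs)) demand[[s]] <- list()
  burning <- list(GFED4s = list(), FINN = list())
  finn_years <- if (nrow(world$fire_records))
    unique(as.integer(format(as.Date(world$fire_records$date), "%Y")))
  else integer(0)
  tmpl <- world$base_production[[1]]

  for (yr in years) {
    ystr <- as.character(yr)
    scaled <- lapply(crops, function(cr)
      scale_grain_to_country(world$base_production[[cr]],
                             world$base_area[[cr]],
                             world$countries, mask, cr, yr))
    names(scaled) <- crops
    for (m in names(production)) {
      percrop <- lapply(crops, function(cr)
        residue_production_method(m, scaled[[cr]]$production,
                                  scaled[[cr]]$area, mask, cr,
                                  params$harvest_index,
                                  params$constant_ratios))
      production[[m]][[ystr]] <- total_cereal_residue(percrop)
    }
    burning$GFED4s[[ystr]] <-
      aggregate_gridded_burning(world$burning_monthly[[ystr]])
    burning$FINN[[ystr]] <- if (yr %in% finn_years)
      aggregate_fire_records(world$fire_records, yr, tmpl)
    else NULL
    app <- apportion_production(world$countries, world$head_counts, mask, yr)
    for (s in names(feed_tabs)) {
      feed <- residue_feed_demand(app$grids, systems, feed_tabs[[s]], mask)
      demand[[s]][[ystr]] <- animal_usage(feed, bedding)
    }
  }
  list(production = production, burning = burning, demand = demand,
       years = years, systems = systems)
}

# Closing stages shared by every combo: cap burning, trade, other uses,
# return ceilings, ledger assembly.
close_allocation <- function(prod, burn_raw, dem, world, params, yr) {
  burnt <- cap_burning(burn_raw, prod, params$allocation$removal_cap)
  tr <- trade_residues(prod, burnt, dem, params$allocation)
  gdp <- cs_value(world$countries, "gdp_per_capita", yr)
  other <- assign_other_uses(prod, burnt, tr$animal_usage, gdp,
                             world$mask, params$allocation)
  lf <- left_on_field(prod, burnt, tr$animal_usage, other, world$mask,
                      params$allocation)
  assemble_ledger(prod, burnt, tr$animal_usage, lf$other_adjusted, lf$left,
                  params$allocation)
}

#' Run the pipeline for one method combination
#'
#' Executes production -> burning -> livestock -> trade -> other uses ->
#' left-on-field for the chosen combo. Years the combo's fire dataset does
#' not cover are omitted from the result (burning is never fabricated).
#' Deterministic for fixed inputs.
#'
#' @param world a `synth_world`.
#' @param combo a [method_combo()].
#' @param params parameter list from [load_params()].
#' @param years years to run (default all).
#' @param stages optional pre-computed [pipeline_stages()] cache.
#' @return named list (by year) of `usage_ledger`s.
#' @export
run_combo <- function(world, combo, params = load_params(), years = NULL,
                      stages = NULL) {
  stopifnot(inherits(combo, "method_combo"))
  if (is.null(stages)) stages <- pipeline_stages(world, params, years)
  out <- list()
  for (yr in stages$years) {
    ystr <- as.character(yr)
    burn <- stages$burning[[combo$fire_dataset]][[ystr]]
    if (is.null(burn)) next  # fire dataset does not cover this year
    out[[ystr]] <- close_allocation(
      stages$production[[combo$production_method]][[ystr]], burn,
      stages$demand[[combo$livestock_source]][[ystr]], world, params, yr)
  }
  out
}

#' Run the mean scheme
#'
#' Averages the stage inputs — the three production methods, the
#' available burning datasets and the three animal-demand estimates — and
#' runs the single allocation scheme once on the means
#' (`scheme = "inputs"`, the default). `scheme = "outputs"` instead
#' averages the final layers of the 18 combo ledgers per cell.
#'
#' @inheritParams run_combo
#' @param scheme `"inputs"` or `"outputs"`.
#' @return named list (by year) of `usage_ledger`s.
#' @export
run_mean <- function(world, params = load_params(), years = NULL,
                     stages = NULL, scheme = c("inputs", "outputs")) {
  scheme <- match.arg(scheme)
  if (is.null(stages)) stages <- pipeline_stages(world, params, years)
  if (scheme == "outputs") {
    runs <- lapply(all_method_combos(), function(cb)
      run_combo(world, cb, params, stages = stages))
    return(mean_of_ledgers(runs, params$allocation))
  }
  out <- list()
  for (yr in stages$years) {
    ystr <- as.character(yr)
    prod <- mean_production(lapply(stages$production, `[[`, ystr))
    burn <- mean_burning(lapply(stages$burning, `[[`, ystr))
    dem_fields <- lapply(stages$demand, `[[`, ystr)
    dem <- gf_like(dem_fields[[1]],
                   Reduce(`+`, lapply(dem_fields, `[[`, "values")) /
                     length(dem_fields))
    out[[ystr]] <- close_allocation(prod, burn, dem, world, params, yr)
  }
  out
}

# Cellwise mean of the layers of several ledger series (years present in
# at least one run; each year averages the runs that cover it).
mean_of_ledgers <- function(runs, alloc = allocation_params()) {
  years <- sort(unique(unlist(lapply(runs, names))))
  out <- list()
  for (ystr in years) {
    avail <- Filter(Negate(is.null), lapply(runs, `[[`, ystr))
    layers <- lapply(names(usage_layer_names()), function(layer)
      gf_like(avail[[1]][[layer]],
              Reduce(`+`, lapply(avail, function(l) l[[layer]]$values)) /
                length(avail)))
    names(layers) <- names(usage_layer_names())
    led <- structure(layers, class = "usage_ledger")
    validate_ledger(led, alloc)
    out[[ystr]] <- led
  }
  out
}

#' Run all 18 combos
#'
#' @inheritParams run_combo
#' @return named list (by combo filename stem) of ledger series.
#' @export
run_all_combos <- function(world, params = load_params(), years = NULL,
                           stages = NULL) {
  if (is.null(stages)) stages <- pipeline_stages(world, params, years)
  combos <- all_method_combos()
  runs <- lapply(combos, function(cb)
    run_combo(world, cb, params, stages = stages))
  names(runs) <- vapply(combos, function(cb)
    sub("\\.nc$", "", sub("^crop_residue_usage_", "", combo_filename(cb))),
    character(1))
  runs
}

#' Usage ranges across an ensemble of runs
#'
#' Regional totals of each usage layer per combo, reduced to min, max and
#' mean across the ensemble — the bracket notation of ensemble
#' uncertainty.
#'
#' @param runs list of ledger series (as from [run_all_combos()]).
#' @param mask a [country_mask()].
#' @param region `"global"`, a country name, or a region name of the
#'   mask's `max_return` map.
#' @return data.frame with columns layer, min, mean, max (Mg/yr, summed
#'   over the region's cells and all years of each run).
#' @export
ensemble_range <- function(runs, mask, region = "global") {
  stopifnot(length(runs) >= 1)
  sel <- if (identical(region, "global")) {
    matrix(TRUE, nrow(mask$codes), ncol(mask$codes))
  } else if (region %in% mask$countries) {
    mask_cells(mask, region)
  } else {
    rm_ <- region_matrix(mask, "max_return")
    !is.na(rm_) & rm_ == region
  }
  if (!any(sel)) stop("empty aggregation region: ", region)
  layers <- names(usage_layer_names())
  totals <- vapply(runs, function(series)
    vapply(layers, function(layer)
      sum(vapply(series, function(led) sum(led[[layer]]$values[sel]),
                 numeric(1))), numeric(1)),
    numeric(length(layers)))
  totals <- matrix(totals, nrow = length(layers),
                   dimnames = list(layers, names(runs)))
  data.frame(layer = layers,
             min = apply(totals, 1, min),
             mean = rowMeans(totals),
             max = apply(totals, 1, max),
             row.names = NULL)
}

#' Fractional usage layers
#'
#' Each usage layer divided by production per cell (NA where production
#' is zero); the four fractions sum to one wherever residues are
#' produced.
#'
#' @param ledger a `usage_ledger`.
#' @return named list of fraction matrices (burnt, animal, other, left).
#' @export
fractional_usage <- function(ledger) {
  p <- ledger$production$values
  out <- lapply(c("burnt", "animal", "other", "left"), function(layer) {
    f <- ledger[[layer]]$values / p
    f[p <= 0] <- NA_real_
    f
  })
  names(out) <- c("burnt", "animal", "other", "left")
  out
}
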