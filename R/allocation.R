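#' Trade residues from surplus to deficit cells
#'
#' A cell is in deficit when burning plus animal demand exceeds the
#' removal cap (90 %) of its residue production. Deficit cells import from
#' nearby surplus cells by an expanding Chebyshev-ring search: radius 1
#' first for every deficit cell, then radius 2, up to
#' `trade_radius_cells`, so local supply is always used before distant
#' supply. Within a ring, supply is drawn from exporters in proportion to
#' their remaining export capacity. Traded residues are booked as animal
#' usage in the EXPORTING cell — mass leaves the field there — which keeps
#' every cell's ledger balanced. Demand still unmet after the search is
#' treated as a local overestimate of animal usage and dropped.
#'
#' The procedure is fully deterministic: rings expand outward, deficit
#' cells are visited in a fixed row-major order, and draws are
#' proportional. On global grids the search wraps in longitude.
#'
#' @param production residue production `grid_field` (Mg/yr).
#' @param burnt capped burning `grid_field` (Mg/yr).
#' @param animal_demand animal demand `grid_field` (Mg/yr).
#' @param params an [allocation_params()] list.
#' @return list: `animal_usage` (`grid_field`, by source cell),
#'   `unmet_demand` (`grid_field`, the dropped deficits), `trade_log`
#'   (data.frame from_row, from_col, to_row, to_col, mass).
#' @export
trade_residues <- function(production, burnt, animal_demand,
                           params = allocation_params()) {
  stopifnot_same_grid(production, burnt, animal_demand)
  if (any(animal_demand$values < 0)) stop("negative animal demand")
  cap <- params$removal_cap
  nlat <- length(production$lat); nlon <- length(production$lon)
  wrap <- abs(nlon * production$resolution - 360) < 1e-6

  avail <- pmax(cap * production$values - burnt$values, 0)
  local <- pmin(animal_demand$values, avail)
  deficit <- animal_demand$values - local
  capacity <- avail - local
  exports <- matrix(0, nlat, nlon)
  log_rows <- list()

  dcells <- which(deficit > 1e-12, arr.ind = TRUE)
  if (nrow(dcells)) {
    ord <- order(dcells[, 1], dcells[, 2])
    dcells <- dcells[ord, , drop = FALSE]
    for (r in seq_len(params$trade_radius_cells)) {
      if (all(deficit[dcells] <= 1e-12)) break
      for (k in seq_len(nrow(dcells))) {
        i <- dcells[k, 1]; j <- dcells[k, 2]
        need <- deficit[i, j]
        if (need <= 1e-12) next
        ring <- chebyshev_ring(i, j, r, nlat, nlon, wrap)
        if (!nrow(ring)) next
        cap_ring <- capacity[cbind(ring[, 1], ring[, 2])]
        sup <- sum(cap_ring)
        if (sup <= 0) next
        draw <- min(need, sup)
        take <- cap_ring * (draw / sup)
        for (m in which(take > 0)) {
          fi <- ring[m, 1]; fj <- ring[m, 2]
          capacity[fi, fj] <- capacity[fi, fj] - take[m]
          exports[fi, fj] <- exports[fi, fj] + take[m]
          log_rows[[length(log_rows) + 1L]] <-
            c(fi, fj, i, j, take[m])
        }
        deficit[i, j] <- need - draw
      }
    }
  }
  trade_log <- if (length(log_rows)) {
    d <- as.data.frame(do.call(rbind, log_rows))
    names(d) <- c("from_row", "from_col", "to_row", "to_col", "mass")
    d
  } else data.frame(from_row = integer(0), from_col = integer(0),
                    to_row = integer(0), to_col = integer(0),
                    mass = numeric(0))
  list(
    animal_usage = gf_like(animal_demand, local + exports),
    unmet_demand = gf_like(animal_demand, deficit),
    trade_log = trade_log
  )
}

# Cells at exact Chebyshev distance r from (i, j); rows clipped at the
# grid edge, columns wrapped when the grid spans 360 deg of longitude.
chebyshev_ring <- function(i, j, r, nlat, nlon, wrap) {
  di <- rep(-r:r, times = 2 * r + 1)
  dj <- rep(-r:r, each = 2 * r + 1)
  keep <- pmax(abs(di), abs(dj)) == r
  ii <- i + di[keep]; jj <- j + dj[keep]
  ok <- ii >= 1 & ii <= nlat
  ii <- ii[ok]; jj <- jj[ok]
  if (wrap) {
    jj <- ((jj - 1) %% nlon) + 1
  } else {
    ok <- jj >= 1 & jj <= nlon
    ii <- ii[ok]; jj <- jj[ok]
  }
  cbind(row = ii, col = jj)
}

#' Income-dependent bound on other off-field uses
#'
#' Upper bound on the fraction of residue production taken by other
#' off-field uses (domestic fuel, construction, industry, mushroom
#' cultivation, biogas, transport losses) as a function of GDP per capita:
#' 30 % below the low-income threshold ($1046 per capita, 2015 prices),
#' 10 % above the high-income threshold ($12735), linearly interpolated in
#' between. Continuous and non-increasing in GDP.
#'
#' @param gdp_per_capita GDP per capita in 2015 US$ (vectorised, >= 0).
#' @param params an [allocation_params()] list.
#' @return bound as a fraction of production.
#' @export
gdp_other_use_bound <- function(gdp_per_capita,
                                params = allocation_params()) {
  lo <- params$gdp_poor_threshold; hi <- params$gdp_rich_threshold
  fp <- params$other_use_poor; fr <- params$other_use_rich
  frac <- (pmin(pmax(gdp_per_capita, lo), hi) - lo) / (hi - lo)
  fp + (fr - fp) * frac
}

#' Assign other off-field uses
#'
#' Per cell, other usage is the GDP-dependent bound times production,
#' limited by what the removal cap leaves after burning and animal usage;
#' in feed-scarce regions availability, not the bound, is binding.
#'
#' @param production,burnt,animal `grid_field`s (post-trade; burning and
#'   animal usage must already respect the removal cap).
#' @param gdp_by_country named numeric, GDP per capita per country for the
#'   year.
#' @param mask a [country_mask()].
#' @param params an [allocation_params()] list.
#' @return other-usage `grid_field` (Mg/yr).
#' @export
assign_other_uses <- function(production, burnt, animal, gdp_by_country,
                              mask, params = allocation_params()) {
  stopifnot_same_grid(production, burnt, animal)
  bound <- gdp_other_use_bound(country_to_grid(gdp_by_country, mask), params)
  bound[is.na(bound)] <- 0
  room <- params$removal_cap * production$values - burnt$values -
    animal$values
  other <- pmax(pmin(bound * production$values, room), 0)
  gf_like(production, other)
}

#' Residues left on field, with regional return ceilings
#'
#' The remainder after burning, animal usage and other uses stays on the
#' field. In regions with a maximum return fraction (China 60 %, Europe
#' 70 %, North America and Oceania 80 %) any excess above the ceiling is
#' shifted to other off-field uses, compensating for sparse data on
#' domestic fuel and industrial usage there.
#'
#' @param production,burnt,animal,other `grid_field`s (Mg/yr).
#' @param mask a [country_mask()] (its `max_return` map names the capped
#'   regions).
#' @param params an [allocation_params()] list.
#' @return list with `left` and `other_adjusted` grid_fields.
#' @export
left_on_field <- function(production, burnt, animal, other, mask,
                          params = allocation_params()) {
  stopifnot_same_grid(production, burnt, animal, other)
  left <- production$values - burnt$values - animal$values - other$values
  tol <- 1e-6 * pmax(production$values, 1)
  if (any(left < -tol)) {
    bad <- which(left < -tol, arr.ind = TRUE)[1, ]
    stop(sprintf("negative residues left on field at cell (%d, %d): %g",
                 bad[1], bad[2], left[bad[1], bad[2]]))
  }
  left <- pmax(left, 0)
  other_adj <- other$values
  regions <- region_matrix(mask, "max_return")
  for (rg in names(params$max_return)) {
    m <- params$max_return[[rg]]
    sel <- !is.na(regions) & regions == rg
    excess <- pmax(left - m * production$values, 0)
    excess[!sel] <- 0
    left <- left - excess
    other_adj <- other_adj + excess
  }
  list(left = gf_like(production, left),
       other_adjusted = gf_like(production, other_adj))
}

#' Assemble and validate a usage ledger
#'
#' Bundles the five layers into a `usage_ledger` and enforces its
#' invariants: per cell, production equals the sum of the four usages
#' (1e-6 relative tolerance), at least the minimum fraction stays on the
#' field, removals respect the cap, and every layer is non-negative.
#' Violations name the offending cell.
#'
#' @param production,burnt,animal,other,left `grid_field`s (Mg/yr) on one
#'   grid and year.
#' @param params an [allocation_params()] list.
#' @return object of class `usage_ledger`.
#' @export
assemble_ledger <- function(production, burnt, animal, other, left,
                            params = allocation_params()) {
  stopifnot_same_grid(production, burnt, animal, other, left)
  ledger <- structure(list(production = production, burnt = burnt,
                           animal = animal, other = other, left = left),
                      class = "usage_ledger")
  validate_ledger(ledger, params)
  ledger
}

#' @rdname assemble_ledger
#' @param ledger a `usage_ledger`.
#' @export
validate_ledger <- function(ledger, params = allocation_params()) {
  p <- ledger$production$values
  layers <- list(production = p, burnt = ledger$burnt$values,
                 animal = ledger$animal$values, other = ledger$other$values,
                 left = ledger$left$values)
  fail <- function(what, where) {
    stop(sprintf("ledger invariant '%s' violated at cell (%d, %d)",
                 what, where[1], where[2]))
  }
  for (nm in names(layers))
    if (any(layers[[nm]] < 0))
      fail(paste0(nm, " non-negative"),
           which(layers[[nm]] < 0, arr.ind = TRUE)[1, ])
  tol <- 1e-6 * pmax(p, 1e-12)
  resid <- abs(p - (layers$burnt + layers$animal + layers$other +
                      layers$left))
  if (any(resid > tol))
    fail("mass balance", which(resid > tol, arr.ind = TRUE)[1, ])
  prodpos <- p > 0
  minleft <- params$min_left_fraction * p - tol
  if (any(prodpos & layers$left < minleft))
    fail("minimum left-on-field",
         which(prodpos & layers$left < minleft, arr.ind = TRUE)[1, ])
  removal <- layers$burnt + layers$animal + layers$other
  if (any(prodpos & removal > params$removal_cap * p + tol))
    fail("removal cap",
         which(prodpos & removal > params$removal_cap * p + tol,
               arr.ind = TRUE)[1, ])
  invisible(TRUE)
}

#' @export
print.usage_ledger <- function(x, ...) {
  tot <- vapply(x, function(g) sum(g$values), numeric(1))
  cat(sprintf("<usage_ledger year %s, totals (Mg/yr):>\n",
              ifelse(is.na(x$production$year), "-", x$production$year)))
  print(round(tot, 2))
  invisible(x)
}
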