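#' Configuration for the synthetic world generator
#'
#' Describes a small self-consistent world with the statistical structure
#' the allocation scheme assumes: gridded per-crop grain production and
#' harvested area in a base year, country tables of grain, meat, milk and
#' GDP per capita spanning all three income bands, monthly gridded
#' agricultural burning at twice the pipeline resolution, a point fire
#' inventory with mixed vegetation classes, per-species livestock grids
#' and a fine-resolution production-system map. Yields are drawn in a
#' realistic 0.5-12 Mg/ha band so both branches of the exponential
#' harvest-index formula are exercised.
#'
#' @param seed RNG seed; the same seed and config give bit-identical
#'   worlds.
#' @param nlat,nlon grid dimensions at 0.5 deg.
#' @param n_countries number of countries (>= 4, so every income band and
#'   every max-return region class is represented).
#' @param years year range of the country tables.
#' @param base_year year of the gridded snapshot.
#' @param yield_range grain-yield band, Mg/ha.
#' @param burning_intensity agricultural burning as a fraction of
#'   residue-scale production (0 disables burning).
#' @param livestock_scale multiplier on livestock densities; raise it to
#'   push cells into residue deficit.
#' @param cropland_fraction fraction of land cells growing each crop.
#' @param ocean_fraction fraction of cells with no country (sentinel NA).
#' @param fires_per_year point fire records generated per covered year.
#' @param finn_years years covered by the point fire inventory (the
#'   gridded burning record covers all years).
#' @param system_freq,climate_freq class frequencies of the fine
#'   production-system map.
#' @return config list (class `synth_world_config`).
#' @export
synth_world_config <- function(seed = 1L, nlat = 20L, nlon = 20L,
                               n_countries = 8L, years = 1997:2021,
                               base_year = 2010L,
                               yield_range = c(0.5, 12),
                               burning_intensity = 0.10,
                               livestock_scale = 1,
                               cropland_fraction = 0.7,
                               ocean_fraction = 0.08,
                               fires_per_year = 80L,
                               finn_years = 2002:2021,
                               system_freq = c(grazing = 0.3, mixed = 0.5,
                                               intensive = 0.1, other = 0.1),
                               climate_freq = c(arid = 0.3, temperate = 0.4,
                                                tropical = 0.3)) {
  cfg <- list(seed = as.integer(seed), nlat = as.integer(nlat),
              nlon = as.integer(nlon), n_countries = as.integer(n_countries),
              years = as.integer(years), base_year = as.integer(base_year),
              yield_range = yield_range,
              burning_intensity = burning_intensity,
              livestock_scale = livestock_scale,
              cropland_fraction = cropland_fraction,
              ocean_fraction = ocean_fraction,
              fires_per_year = as.integer(fires_per_year),
              finn_years = as.integer(finn_years),
              system_freq = system_freq, climate_freq = climate_freq)
  class(cfg) <- "synth_world_config"
  cfg
}

#' Generate a synthetic world
#'
#' Builds the full input bundle for the pipeline from a
#' [synth_world_config()]. By construction the base-year entries of the
#' country tables equal the country sums of the gridded base-year fields,
#' and other years scale the base grid by smooth trends with noise.
#'
#' @param config a [synth_world_config()].
#' @return list of class `synth_world` with elements: config, mask
#'   ([country_mask()]), countries ([country_series()]), base_production
#'   and base_area (per-crop `grid_field` lists), head_counts (per-species
#'   `grid_field` list incl. the combined `sheep_goat`), systems_fine
#'   (5-arcmin [systems_grid()]), burning_monthly (per year: list of 12
#'   0.25 deg `grid_field`s), fire_records (data.frame).
#' @export
make_world <- function(config = synth_world_config()) {
  cfg <- config
  if (cfg$n_countries < 4)
    stop("need at least 4 countries (income bands + max-return regions)")
  if (length(cfg$years) == 0) stop("empty year range")
  if (!cfg$base_year %in% cfg$years) stop("base year outside year range")
  set.seed(cfg$seed)

  ax <- toy_axes(cfg$nlat, cfg$nlon)
  crops <- cereal_crops()

  ## --- countries: rectangular tiles plus a sprinkle of ocean cells
  kr <- max(1L, as.integer(floor(sqrt(cfg$n_countries))))
  kc <- as.integer(ceiling(cfg$n_countries / kr))
  tile_r <- pmin(ceiling(seq_len(cfg$nlat) / (cfg$nlat / kr)), kr)
  tile_c <- pmin(ceiling(seq_len(cfg$nlon) / (cfg$nlon / kc)), kc)
  codes <- outer(tile_r, tile_c, function(r, co) (r - 1L) * kc + co)
  codes[codes > cfg$n_countries] <- cfg$n_countries
  codes <- matrix(as.integer(codes), cfg$nlat, cfg$nlon)
  n_ocean <- round(cfg$ocean_fraction * length(codes))
  if (n_ocean > 0) {
    # never drown a country entirely
    ocean <- sample(length(codes), n_ocean)
    for (cell in ocean)
      if (sum(codes == codes[cell], na.rm = TRUE) > 1) codes[cell] <- NA
  }
  countries <- sprintf("C%02d", seq_len(cfg$n_countries))
  bands <- rep(c("poor", "middle", "rich"), length.out = cfg$n_countries)
  mr <- rep("other", cfg$n_countries)
  mr[1:3] <- c("china", "europe", "north_america_oceania")
  fcr_region <- ifelse(bands == "rich", "oecd", "south")
  mask <- country_mask(codes, ax$lat, ax$lon, countries, list(
    constant_ratio = stats::setNames(rep("default", cfg$n_countries),
                                     countries),
    fcr = stats::setNames(fcr_region, countries),
    max_return = stats::setNames(mr, countries)))
  land <- !is.na(codes)

  ## --- base-year per-crop production and area grids
  base_production <- list(); base_area <- list()
  for (cr in crops) {
    grown <- land & matrix(stats::runif(length(codes)) <
                             cfg$cropland_fraction, cfg$nlat, cfg$nlon)
    prod <- matrix(0, cfg$nlat, cfg$nlon)
    prod[grown] <- stats::rlnorm(sum(grown), meanlog = log(1000), sdlog = 0.8)
    yld <- matrix(0, cfg$nlat, cfg$nlon)
    yld[grown] <- stats::runif(sum(grown), cfg$yield_range[1],
                               cfg$yield_range[2])
    area <- matrix(0, cfg$nlat, cfg$nlon)
    area[grown] <- prod[grown] / yld[grown]
    base_production[[cr]] <- grid_field(prod, ax$lat, ax$lon,
                                        year = cfg$base_year,
                                        units = "Mg/yr")
    base_area[[cr]] <- grid_field(area, ax$lat, ax$lon,
                                  year = cfg$base_year, units = "ha")
  }

  ## --- livestock head-count grids (base-year snapshot, held fixed)
  dens <- c(cattle = 2000, sheep = 1200, goats = 1000, horses = 60,
            pigs = 800)
  head_counts <- list()
  for (sp in names(dens)) {
    h <- matrix(0, cfg$nlat, cfg$nlon)
    h[land] <- stats::runif(sum(land), 0, dens[[sp]]) * cfg$livestock_scale
    head_counts[[sp]] <- grid_field(h, ax$lat, ax$lon,
                                    year = cfg$base_year, units = "head")
  }
  head_counts$sheep_goat <- gf_like(head_counts$sheep,
                                    head_counts$sheep$values +
                                      head_counts$goats$values,
                                    units = "head")

  ## --- country annual tables (base year consistent with the grids)
  trend <- function(year) 1 + 0.01 * (year - cfg$base_year)
  rows <- list()
  add_row <- function(country, year, variable, value)
    rows[[length(rows) + 1L]] <<- data.frame(country = country, year = year,
                                             variable = variable,
                                             value = value)
  for (cr in crops) {
    bp <- country_sums(base_production[[cr]]$values, mask)
    ba <- country_sums(base_area[[cr]]$values, mask)
    for (co in countries) for (yr in cfg$years) {
      f <- if (yr == cfg$base_year) 1 else
        trend(yr) * pmax(0.1, 1 + stats::rnorm(1, 0, 0.05))
      add_row(co, yr, paste0("grain.", cr), unname(bp[co]) * f)
      fa <- if (yr == cfg$base_year) 1 else
        trend(yr) * pmax(0.1, 1 + stats::rnorm(1, 0, 0.03))
      add_row(co, yr, paste0("area.", cr), unname(ba[co]) * fa)
    }
  }
  per_head <- c(meat.cattle = 0.02, milk.cattle = 0.4,
                meat.sheep_goat = 0.008, milk.sheep_goat = 0.04)
  for (sp in c("cattle", "sheep_goat")) {
    hc <- country_sums(head_counts[[sp]]$values, mask)
    for (pr in c("meat", "milk")) {
      v <- paste0(pr, ".", sp)
      for (co in countries) for (yr in cfg$years)
        add_row(co, yr, v,
                unname(hc[co]) * per_head[[v]] * trend(yr) *
                  pmax(0.1, 1 + stats::rnorm(1, 0, 0.05)))
    }
  }
  gdp_base <- stats::setNames(numeric(cfg$n_countries), countries)
  gdp_base[bands == "poor"] <- stats::runif(sum(bands == "poor"), 500, 1000)
  gdp_base[bands == "middle"] <- stats::runif(sum(bands == "middle"),
                                              2000, 10000)
  gdp_base[bands == "rich"] <- stats::runif(sum(bands == "rich"),
                                            14000, 40000)
  for (co in countries) for (yr in cfg$years)
    add_row(co, yr, "gdp_per_capita",
            unname(gdp_base[co]) * (1 + 0.005 * (yr - cfg$base_year)) *
              (1 + stats::rnorm(1, 0, 0.01)))
  country_tab <- country_series(do.call(rbind, rows), cfg$years)

  ## --- monthly gridded agricultural burning at 0.25 deg
  fine <- toy_axes(cfg$nlat * 2L, cfg$nlon * 2L, resolution_deg = 0.25,
                   lat0 = ax$lat[1] - 0.125, lon0 = ax$lon[1] - 0.125)
  tot_prod <- Reduce(`+`, lapply(base_production, function(g) g$values))
  burning_monthly <- list()
  for (yr in cfg$years) {
    ann <- cfg$burning_intensity * tot_prod *
      matrix(stats::runif(length(tot_prod), 0.5, 1.5), cfg$nlat, cfg$nlon) *
      trend(yr)
    # split each 0.5 cell over its four 0.25 cells, then over months
    w4 <- matrix(stats::runif(4 * length(ann)), 4)
    w4 <- sweep(w4, 2, colSums(w4), "/")
    fine_ann <- matrix(0, cfg$nlat * 2L, cfg$nlon * 2L)
    k <- 0
    for (j in seq_len(cfg$nlon)) for (i in seq_len(cfg$nlat)) {
      k <- k + 1
      fine_ann[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)] <-
        matrix(w4[, k] * ann[i, j], 2, 2)
    }
    wm <- stats::runif(12); wm <- wm / sum(wm)
    burning_monthly[[as.character(yr)]] <- lapply(seq_len(12), function(m)
      grid_field(fine_ann * wm[m], fine$lat, fine$lon, year = yr,
                 units = "Mg/month"))
  }

  ## --- point fire records (later coverage window, mixed classes)
  fire_records <- data.frame()
  finn <- intersect(cfg$finn_years, cfg$years)
  if (cfg$fires_per_year > 0 && length(finn) && cfg$burning_intensity > 0) {
    land_cells <- which(land & tot_prod > 0, arr.ind = TRUE)
    for (yr in finn) {
      n <- cfg$fires_per_year
      pick <- land_cells[sample(nrow(land_cells), n, replace = TRUE), ,
                         drop = FALSE]
      cls <- sample(c("agricultural", "forest", "savanna"), n,
                    replace = TRUE, prob = c(0.7, 0.2, 0.1))
      mass <- cfg$burning_intensity * tot_prod[pick] *
        stats::runif(n, 0.5, 1.5) * trend(yr) *
        (sum(land) * 1.0 / n) * 0.7
      fire_records <- rbind(fire_records, data.frame(
        lat = ax$lat[pick[, 1]] + stats::runif(n, -0.24, 0.24),
        lon = ax$lon[pick[, 2]] + stats::runif(n, -0.24, 0.24),
        date = as.Date(sprintf("%d-01-01", yr)) +
          sample(0:364, n, replace = TRUE),
        biomass_burnt = mass,
        vegetation_class = cls))
    }
  }

  ## --- fine production-system map (6 x 6 sub-cells per 0.5 deg cell)
  ffac <- 6L
  fl <- toy_axes(cfg$nlat * ffac, cfg$nlon * ffac,
                 resolution_deg = 0.5 / ffac,
                 lat0 = ax$lat[1] - 0.25 + 0.5 / ffac / 2,
                 lon0 = ax$lon[1] - 0.25 + 0.5 / ffac / 2)
  ncell <- cfg$nlat * ffac * cfg$nlon * ffac
  sysm <- matrix(sample(seq_along(cfg$system_freq), ncell, replace = TRUE,
                        prob = cfg$system_freq),
                 cfg$nlat * ffac, cfg$nlon * ffac)
  clim <- matrix(sample(seq_along(cfg$climate_freq), ncell, replace = TRUE,
                        prob = cfg$climate_freq),
                 cfg$nlat * ffac, cfg$nlon * ffac)
  systems_fine <- systems_grid(sysm, clim, fl$lat, fl$lon)

  structure(list(config = cfg, mask = mask, countries = country_tab,
                 base_production = base_production, base_area = base_area,
                 head_counts = head_counts, systems_fine = systems_fine,
                 burning_monthly = burning_monthly,
                 fire_records = fire_records),
            class = "synth_world")
}

#' Standard fixture worlds
#'
#' `standard_world()` is the baseline test fixture: moderate livestock
#' densities, 10 % burning intensity, every income band and max-return
#' region represented. `deficit_world()` multiplies livestock densities
#' so that combined burning and animal demand exceeds 90 % of residue
#' production in a substantial share of cells, exercising the trade
#' stage. `china_surplus_world()` has low burning and low livestock
#' demand so cells of the China-tagged region run into the 60 % ceiling
#' on residues left on field.
#'
#' @param seed RNG seed.
#' @param ... further overrides passed to [synth_world_config()].
#' @return a `synth_world`.
#' @export
standard_world <- function(seed = 1L, ...) {
  make_world(synth_world_config(seed = seed, ...))
}

#' @rdname standard_world
#' @export
deficit_world <- function(seed = 1L, ...) {
  make_world(synth_world_config(seed = seed, livestock_scale = 8, ...))
}

#' @rdname standard_world
#' @export
china_surplus_world <- function(seed = 1L, ...) {
  make_world(synth_world_config(seed = seed, burning_intensity = 0.01,
                                livestock_scale = 0.1, ...))
}
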