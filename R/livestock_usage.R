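#' Feed-conversion parameters for one livestock source
#'
#' Loads the feed-conversion ratios (FCR, kg dry-matter feed per kg of
#' meat or milk protein at herd level) and crop-residue feed fractions
#' (CRFF, fraction by weight of residues in the diet) for one of the three
#' literature sources. Tables are keyed by (region, animal_type,
#' production_system, climate, product); any key column may hold `"any"`
#' as a wildcard, and lookups pick the most specific matching row, so the
#' lookup is total whenever a wildcard row exists. The `mekonnen` source
#' publishes no CRFFs, so its CRFF table is taken verbatim from the
#' `herrero` table (recorded in the `crff_source` field).
#'
#' @param source one of `"herrero"`, `"mottet"`, `"mekonnen"`.
#' @param path YAML file with `fcr:` and `crff:` row lists; defaults to
#'   the table shipped with the package for that source.
#' @return object of class `feed_params` with fields source, fcr, crff,
#'   crff_source, protein_g_kg.
#' @export
feed_params <- function(source = c("herrero", "mottet", "mekonnen"),
                        path = NULL) {
  source <- match.arg(source)
  if (is.null(path))
    path <- system.file("extdata",
                        paste0("feed_params_", source, ".yaml"),
                        package = "resalloc", mustWork = TRUE)
  raw <- yaml::read_yaml(path)
  to_df <- function(rows, valcol) {
    d <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
    names(d)[names(d) == "value"] <- valcol
    d
  }
  fcr <- to_df(raw$fcr, "fcr")
  crff_source <- source
  if (is.null(raw$crff)) {
    her <- yaml::read_yaml(system.file("extdata",
                                       "feed_params_herrero.yaml",
                                       package = "resalloc",
                                       mustWork = TRUE))
    crff <- to_df(her$crff, "crff")
    crff_source <- "herrero"
  } else crff <- to_df(raw$crff, "crff")
  stopifnot(all(fcr$fcr > 0), all(crff$crff >= 0), all(crff$crff <= 1))
  structure(list(source = source, fcr = fcr, crff = crff,
                 crff_source = crff_source,
                 protein_g_kg = c(cattle.meat = 138, sheep_goat.meat = 137,
                                  cattle.milk = 33, sheep_goat.milk = 33)),
            class = "feed_params")
}

# Most-specific-match lookup in an fcr/crff table; "any" rows are
# wildcards. Errors if no row matches at all.
lookup_feed <- function(tab, valcol, region, animal, system, climate,
                        product) {
  keys <- c(region = region, animal_type = animal,
            production_system = system, climate = climate, product = product)
  score <- rep(0L, nrow(tab))
  ok <- rep(TRUE, nrow(tab))
  for (k in names(keys)) {
    col <- tab[[k]]
    hit <- col == keys[[k]]
    ok <- ok & (hit | col == "any")
    score <- score + as.integer(hit)
  }
  if (!any(ok))
    stop("no ", valcol, " entry for (", paste(keys, collapse = ", "), ")")
  tab[[valcol]][which(ok)[which.max(score[ok])]]
}

#' Livestock production-system grid
#'
#' Categorical raster giving the dominant ruminant production system and
#' climate zone per cell. Built from a fine-resolution class map by taking
#' the modal class in each 0.5 deg cell; ties break by the fixed class
#' order grazing < mixed < intensive < other (and arid < temperate <
#' tropical).
#'
#' @param system integer matrix of codes into [system_levels()].
#' @param climate integer matrix of codes into [climate_levels()].
#' @param lat,lon cell-center axes.
#' @return object of class `systems_grid`.
#' @export
systems_grid <- function(system, climate, lat, lon) {
  stopifnot(dim(system)[1] == length(lat), dim(system)[2] == length(lon),
            all(dim(system) == dim(climate)))
  structure(list(system = system, climate = climate, lat = lat, lon = lon,
                 resolution = grid_step(lat, lon)),
            class = "systems_grid")
}

#' @rdname systems_grid
#' @export
system_levels <- function() c("grazing", "mixed", "intensive", "other")

#' @rdname systems_grid
#' @export
climate_levels <- function() c("arid", "temperate", "tropical")

#' Dominant system per 0.5 deg cell from a fine class map
#'
#' @param fine a `systems_grid` at fine resolution dividing 0.5 deg.
#' @return a `systems_grid` at 0.5 deg (modal class per cell).
#' @export
dominant_systems <- function(fine) {
  f <- 0.5 / fine$resolution
  if (abs(f - round(f)) > 1e-9) stop("resolution does not divide 0.5 deg")
  f <- as.integer(round(f))
  systems_grid(block_mode(fine$system, f), block_mode(fine$climate, f),
               block_centers(fine$lat, f), block_centers(fine$lon, f))
}

#' Apportion country meat and milk production to cells
#'
#' Splits each country's annual production of a product over its cells in
#' proportion to the cell's share of the country's animal head count, so
#' production follows where the animals are.
#'
#' @param countries a [country_series()] with `meat.<species>` /
#'   `milk.<species>` variables (Mg/yr).
#' @param head_counts named list of head-count `grid_field`s per species
#'   group (`cattle`, `sheep_goat`).
#' @param mask a [country_mask()].
#' @param year calendar year.
#' @return list with `grids`: named list of `grid_field`s keyed
#'   `<species>.<product>` (Mg/yr), and `unplaced`: country/variable pairs
#'   with production but zero mapped animals.
#' @export
apportion_production <- function(countries, head_counts, mask, year) {
  grids <- list()
  unplaced <- character(0)
  for (sp in c("cattle", "sheep_goat")) {
    heads <- head_counts[[sp]]
    if (is.null(heads)) stop("missing head counts for ", sp)
    ch <- country_sums(heads$values, mask)
    for (pr in c("meat", "milk")) {
      var <- paste0(pr, ".", sp)
      tot <- cs_value(countries, var, year)
      tot <- tot[names(tot) %in% mask$countries]
      if (any(tot < 0, na.rm = TRUE)) stop("negative production in ", var)
      tot[is.na(tot)] <- 0
      bad <- names(tot)[tot > 0 & ch[names(tot)] <= 0]
      if (length(bad))
        unplaced <- c(unplaced, paste(bad, var, sep = ":"))
      share <- ifelse(ch[names(tot)] > 0, tot / ch[names(tot)], 0)
      fac <- country_to_grid(share, mask)
      vals <- heads$values * fac
      vals[is.na(vals)] <- 0
      grids[[paste0(sp, ".", pr)]] <- gf_like(heads, vals, units = "Mg/yr",
                                              year = year)
    }
  }
  list(grids = grids, unplaced = unplaced)
}

#' Ruminant residue feed demand
#'
#' Converts gridded meat and milk production into the crop-residue mass
#' fed to ruminants: product mass x protein content x FCR gives the feed
#' dry matter, of which the CRFF is crop residue. Summed over species and
#' products per cell.
#'
#' @param production_grids named list from [apportion_production()]
#'   (`<species>.<product>` grid_fields, Mg/yr).
#' @param systems a 0.5 deg [systems_grid()].
#' @param params a [feed_params()].
#' @param mask a [country_mask()] (its `fcr` region map keys the tables).
#' @return residue feed demand `grid_field` (Mg/yr).
#' @export
residue_feed_demand <- function(production_grids, systems, params, mask) {
  tmpl <- production_grids[[1]]
  regions <- region_matrix(mask, "fcr")
  demand <- matrix(0, length(tmpl$lat), length(tmpl$lon))
  sysm <- matrix(system_levels()[systems$system],
                 nrow(demand), ncol(demand))
  clim <- matrix(climate_levels()[systems$climate],
                 nrow(demand), ncol(demand))
  key <- paste(regions, sysm, clim, sep = "|")
  key[is.na(regions)] <- NA
  for (nm in names(production_grids)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    sp <- parts[1]; pr <- parts[2]
    protein <- params$protein_g_kg[[nm]]
    pv <- production_grids[[nm]]$values
    for (k in unique(key[!is.na(key) & pv > 0])) {
      kk <- strsplit(k, "|", fixed = TRUE)[[1]]
      fcr <- lookup_feed(params$fcr, "fcr", kk[1], sp, kk[2], kk[3], pr)
      crff <- lookup_feed(params$crff, "crff", kk[1], sp, kk[2], kk[3], pr)
      sel <- !is.na(key) & key == k
      # Mg product x g/kg protein = kg protein; x FCR x CRFF = kg residue
      demand[sel] <- demand[sel] + pv[sel] * protein * fcr * crff / 1000
    }
  }
  gf_like(tmpl, demand, units = "Mg/yr")
}

#' Animal bedding straw demand
#'
#' Yearly straw bedding per cell from head counts and per-head daily
#' rates, plus the yearly straw allowance chewed by horses. Poultry uses
#' other bedding materials and contributes nothing.
#'
#' @param head_counts named list of head-count `grid_field`s; recognised
#'   species: cattle, sheep_goat (or sheep and goats separately), horses,
#'   pigs.
#' @param rates a [bedding_rates()] list.
#' @return bedding demand `grid_field` (Mg/yr).
#' @export
bedding_demand <- function(head_counts, rates = bedding_rates()) {
  map <- c(cattle = "cattle", sheep_goat = "sheep_goat",
           sheep = "sheep_goat", goats = "sheep_goat",
           horses = "horse", pigs = "pig")
  tmpl <- head_counts[[1]]
  kg <- matrix(0, length(tmpl$lat), length(tmpl$lon))
  for (nm in names(head_counts)) {
    sp <- unname(map[nm])
    if (is.na(sp)) next  # poultry and unknown species: no bedding straw
    h <- head_counts[[nm]]$values
    if (any(h < 0)) stop("negative head counts for ", nm)
    kg <- kg + h * rates$kg_per_day[[sp]] * 365
    if (sp == "horse") kg <- kg + h * rates$horse_chewing_kg_yr
  }
  gf_like(tmpl, kg / 1000, units = "Mg/yr")
}

#' Combined animal usage
#'
#' Cellwise sum of ruminant feed demand and bedding demand; the allocation
#' stage later trims this against availability.
#'
#' @param feed,bedding `grid_field`s on one grid (Mg/yr).
#' @return animal-usage `grid_field` (Mg/yr).
#' @export
animal_usage <- function(feed, bedding) {
  stopifnot_same_grid(feed, bedding)
  gf_like(feed, feed$values + bedding$values)
}
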