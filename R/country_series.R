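#' Per-country annual table
#'
#' Long-format container for country-level annual variables: grain
#' production and harvested area per crop (`grain.<crop>` Mg/yr,
#' `area.<crop>` ha), meat and milk production per species group
#' (`meat.<species>`, `milk.<species>` Mg/yr) and `gdp_per_capita`
#' (US$, 2015 prices). Every (country, variable) series is completed over
#' the declared year range; values absent from the input stay NA rather
#' than becoming silent zeros.
#'
#' @param data data.frame with columns country, year, variable, value.
#' @param years full year range the table must cover.
#' @return object of class `country_series`.
#' @export
country_series <- function(data, years) {
  stopifnot(all(c("country", "year", "variable", "value") %in% names(data)))
  if (length(years) == 0) stop("empty year range")
  if (any(!data$year %in% years)) stop("data contains years outside range")
  full <- expand.grid(country = unique(data$country),
                      year = years,
                      variable = unique(data$variable),
                      stringsAsFactors = FALSE)
  m <- merge(full, data, all.x = TRUE, sort = FALSE)
  m <- m[order(m$variable, m$country, m$year), ]
  rownames(m) <- NULL
  structure(list(data = m, years = years,
                 countries = sort(unique(m$country))),
            class = "country_series")
}

#' @export
print.country_series <- function(x, ...) {
  cat(sprintf("<country_series: %d countries, years %d-%d, %d variables>\n",
              length(x$countries), min(x$years), max(x$years),
              length(unique(x$data$variable))))
  invisible(x)
}

#' Look up one variable for one year across countries
#'
#' @param cs a `country_series`. @param variable variable name.
#' @param year calendar year.
#' @return named numeric vector (one element per country; NA if missing).
#' @export
cs_value <- function(cs, variable, year) {
  d <- cs$data[cs$data$variable == variable & cs$data$year == year, ]
  if (!nrow(d)) stop("variable not present: ", variable)
  stats::setNames(d$value, d$country)
}

#' Country mask with region lookups
#'
#' Raster of country codes aligned to the pipeline grid, plus the named
#' country-to-region maps the scheme needs: `constant_ratio` (regions of
#' the fixed residue-ratio table), `fcr` (regions of the feed-parameter
#' tables) and `max_return` (china / europe / north_america_oceania /
#' other, governing the ceiling on residues left on field). Ocean or
#' no-data cells carry NA.
#'
#' @param codes integer matrix of country indices (NA = no country).
#' @param lat,lon cell-center axes (as for [grid_field()]).
#' @param countries character vector of country names; `codes` indexes it.
#' @param region_maps named list of named character vectors
#'   (country -> region) with entries constant_ratio, fcr, max_return.
#' @return object of class `country_mask`.
#' @export
country_mask <- function(codes, lat, lon, countries, region_maps) {
  codes <- as.matrix(codes)
  stopifnot(nrow(codes) == length(lat), ncol(codes) == length(lon))
  ok <- stats::na.omit(unique(as.vector(codes)))
  if (length(ok) && (min(ok) < 1 || max(ok) > length(countries)))
    stop("codes index outside countries vector")
  for (m in c("constant_ratio", "fcr", "max_return")) {
    if (is.null(region_maps[[m]])) stop("region map missing: ", m)
    missing <- setdiff(countries, names(region_maps[[m]]))
    if (length(missing))
      stop("region map '", m, "' lacks countries: ",
           paste(missing, collapse = ", "))
  }
  structure(list(codes = codes, lat = lat, lon = lon,
                 countries = countries, region_maps = region_maps,
                 resolution = grid_step(lat, lon)),
            class = "country_mask")
}

# Logical matrix selecting one country's cells.
mask_cells <- function(mask, country) {
  idx <- match(country, mask$countries)
  !is.na(mask$codes) & mask$codes == idx
}

# Per-cell region labels (character matrix) under one of the region maps.
region_matrix <- function(mask, map_name) {
  map <- mask$region_maps[[map_name]]
  if (is.null(map)) stop("no such region map: ", map_name)
  out <- matrix(NA_character_, nrow(mask$codes), ncol(mask$codes))
  inl <- !is.na(mask$codes)
  out[inl] <- unname(map[mask$countries[mask$codes[inl]]])
  out
}

# Sum a value matrix within each country -> named vector.
country_sums <- function(values, mask) {
  inl <- !is.na(mask$codes)
  s <- rowsum(values[inl], mask$codes[inl])
  stats::setNames(as.vector(s), mask$countries[as.integer(rownames(s))])
}

# Broadcast a per-country named vector onto the grid (NA off-country).
country_to_grid <- function(values_by_country, mask) {
  out <- matrix(NA_real_, nrow(mask$codes), ncol(mask$codes))
  inl <- !is.na(mask$codes)
  out[inl] <- unname(values_by_country[mask$countries[mask$codes[inl]]])
  out
}
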