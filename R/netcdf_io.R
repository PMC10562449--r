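#' Method combination
#'
#' One member of the 18-member ensemble: a residue-production method
#' (constant / exponential / linear), a livestock feed-parameter source
#' (herrero / mottet / mekonnen) and a fire dataset (GFED4s / FINN) — or
#' the distinguished `"mean"` scheme that averages the stage inputs.
#'
#' @param production_method,livestock_source,fire_dataset combo tokens.
#' @return object of class `method_combo`.
#' @export
method_combo <- function(production_method, livestock_source, fire_dataset) {
  structure(list(
    production_method = match.arg(production_method,
                                  c("constant", "exponential", "linear")),
    livestock_source = match.arg(livestock_source,
                                 c("herrero", "mottet", "mekonnen")),
    fire_dataset = match.arg(fire_dataset, c("GFED4s", "FINN"))),
    class = "method_combo")
}

#' @rdname method_combo
#' @export
all_method_combos <- function() {
  g <- expand.grid(production_method = c("constant", "exponential", "linear"),
                   livestock_source = c("herrero", "mottet", "mekonnen"),
                   fire_dataset = c("GFED4s", "FINN"),
                   stringsAsFactors = FALSE)
  lapply(seq_len(nrow(g)), function(i)
    method_combo(g$production_method[i], g$livestock_source[i],
                 g$fire_dataset[i]))
}

#' Output filename for a combo
#'
#' `crop_residue_usage_{production}_{livestock}_{fire}.nc`, or
#' `crop_residue_usage_mean.nc` for the mean scheme.
#'
#' @param combo a [method_combo()] or the string `"mean"`.
#' @return filename string.
#' @export
combo_filename <- function(combo) {
  if (identical(combo, "mean")) return("crop_residue_usage_mean.nc")
  stopifnot(inherits(combo, "method_combo"))
  sprintf("crop_residue_usage_%s_%s_%s.nc", combo$production_method,
          combo$livestock_source, combo$fire_dataset)
}

#' @export
print.method_combo <- function(x, ...) {
  cat(sprintf("<method_combo %s / %s / %s>\n", x$production_method,
              x$livestock_source, x$fire_dataset))
  invisible(x)
}

usage_layer_names <- function() {
  c(production = "residue_production", burnt = "burnt_residues",
    animal = "animal_usage", other = "other_usage",
    left = "left_on_field")
}

#' Write a usage-ledger time series as netCDF
#'
#' One file per method combination, with dimensions (lon, lat, time) and
#' the five layers `residue_production`, `burnt_residues`,
#' `animal_usage`, `other_usage`, `left_on_field`, all in Mg/year.
#' Latitude is stored ascending with cell-center registration recorded in
#' the global attributes. Every ledger is re-validated before writing; a
#' mass-balance violation refuses the write.
#'
#' @param ledgers named list (by year) of `usage_ledger`s on one grid.
#' @param combo a [method_combo()] or `"mean"` (sets the filename).
#' @param dir output directory.
#' @param params [allocation_params()] used for validation.
#' @return invisibly, the full path written.
#' @export
write_usage_netcdf <- function(ledgers, combo, dir = ".",
                               params = allocation_params()) {
  stopifnot(length(ledgers) >= 1)
  for (led in ledgers) validate_ledger(led, params)
  tmpl <- ledgers[[1]]$production
  for (led in ledgers) stopifnot_same_grid(tmpl, led$production)
  years <- as.integer(names(ledgers))
  dlon <- ncdf4::ncdim_def("lon", "degrees_east", tmpl$lon)
  dlat <- ncdf4::ncdim_def("lat", "degrees_north", tmpl$lat)
  dtime <- ncdf4::ncdim_def("time", "years", years, unlim = TRUE)
  vars <- lapply(usage_layer_names(), function(nm)
    ncdf4::ncvar_def(nm, "Mg/year", list(dlon, dlat, dtime),
                     missval = NA_real_, prec = "double"))
  path <- file.path(dir, combo_filename(combo))
  nc <- ncdf4::nc_create(path, vars)
  on.exit(ncdf4::nc_close(nc))
  for (i in seq_along(usage_layer_names())) {
    layer <- names(usage_layer_names())[i]
    arr <- vapply(ledgers, function(led) t(led[[layer]]$values),
                  matrix(0, length(tmpl$lon), length(tmpl$lat)))
    ncdf4::ncvar_put(nc, vars[[i]], arr)
  }
  ncdf4::ncatt_put(nc, 0, "grid_registration",
                   "cell centers; latitude ascending")
  ncdf4::ncatt_put(nc, 0, "resolution_deg", tmpl$resolution)
  invisible(path)
}

#' Read a usage netCDF back into ledgers
#'
#' @param path file written by [write_usage_netcdf()].
#' @param params [allocation_params()] for re-validation.
#' @param validate re-check the ledger invariants on read.
#' @return named list (by year) of `usage_ledger`s.
#' @export
read_usage_netcdf <- function(path, params = allocation_params(),
                              validate = TRUE) {
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  lon <- as.vector(nc$dim$lon$vals)
  lat <- as.vector(nc$dim$lat$vals)
  years <- as.integer(nc$dim$time$vals)
  out <- list()
  for (k in seq_along(years)) {
    layers <- lapply(usage_layer_names(), function(nm) {
      m <- ncdf4::ncvar_get(nc, nm, start = c(1, 1, k),
                            count = c(length(lon), length(lat), 1))
      grid_field(t(m), lat, lon, year = years[k], units = "Mg/yr")
    })
    names(layers) <- names(usage_layer_names())
    led <- structure(layers, class = "usage_ledger")
    if (validate) validate_ledger(led, params)
    out[[as.character(years[k])]] <- led
  }
  out
}
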