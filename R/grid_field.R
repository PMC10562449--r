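#' Gridded annual field
#'
#' The universal raster currency of the pipeline: one value per cell of a
#' regular latitude/longitude grid for one calendar year, with declared
#' units. Rows index latitude (ascending), columns longitude (ascending);
#' cell centers sit at `lat`/`lon`. Global grids at 0.5 deg run from
#' -89.75...89.75 and -179.75...179.75; rectangular toy extents are equally
#' valid, so tests can run on e.g. 20 x 20 cells.
#'
#' @param values numeric matrix, `length(lat)` rows by `length(lon)` columns.
#' @param lat,lon cell-center coordinates in degrees, ascending, equally
#'   spaced with a common step (the resolution).
#' @param year calendar year the field refers to (NA for time-invariant).
#' @param units unit string, e.g. `"Mg/yr"`.
#' @param allow_na permit NA cells (used for masks / no-data); mass fields
#'   keep finite values and use 0 for no production.
#' @return an object of class `grid_field`.
#' @export
grid_field <- function(values, lat, lon, year = NA_integer_, units = "Mg/yr",
                       allow_na = FALSE) {
  values <- as.matrix(values)
  if (nrow(values) != length(lat) || ncol(values) != length(lon))
    stop("values must be length(lat) x length(lon)")
  res <- grid_step(lat, lon)
  if (!allow_na && any(!is.finite(values)))
    stop("grid_field values must be finite")
  structure(list(values = values, lat = as.numeric(lat), lon = as.numeric(lon),
                 resolution = res, year = year, units = units),
            class = "grid_field")
}

grid_step <- function(lat, lon) {
  steps <- c(diff(lat), diff(lon))
  if (length(steps) == 0) return(0.5)
  if (any(steps <= 0)) stop("lat/lon must be ascending")
  res <- steps[1]
  if (any(abs(steps - res) > 1e-9)) stop("grid must be regular")
  res
}

#' Cell-center axes for a global grid
#' @param resolution_deg cell width in degrees (must divide 180 evenly).
#' @return list with `lat` and `lon` center vectors.
#' @export
global_axes <- function(resolution_deg = 0.5) {
  list(lat = seq(-90 + resolution_deg / 2, 90 - resolution_deg / 2,
                 by = resolution_deg),
       lon = seq(-180 + resolution_deg / 2, 180 - resolution_deg / 2,
                 by = resolution_deg))
}

#' Toy rectangular axes anchored at a corner
#' @param nlat,nlon grid dimensions. @param resolution_deg cell width.
#' @param lat0,lon0 lower-left cell center.
#' @return list with `lat` and `lon` center vectors.
#' @export
toy_axes <- function(nlat, nlon, resolution_deg = 0.5,
                     lat0 = 0.25, lon0 = 0.25) {
  list(lat = lat0 + resolution_deg * (seq_len(nlat) - 1),
       lon = lon0 + resolution_deg * (seq_len(nlon) - 1))
}

#' @export
print.grid_field <- function(x, ...) {
  cat(sprintf("<grid_field %d x %d @ %g deg, year %s, units %s, total %g>\n",
              nrow(x$values), ncol(x$values), x$resolution,
              ifelse(is.na(x$year), "-", x$year), x$units,
              sum(x$values, na.rm = TRUE)))
  invisible(x)
}

# New field on the same grid (values replaced, metadata kept).
gf_like <- function(template, values, units = template$units,
                    year = template$year, allow_na = FALSE) {
  grid_field(values, template$lat, template$lon, year = year, units = units,
             allow_na = allow_na)
}

# TRUE if the two fields share one grid.
same_grid <- function(a, b) {
  length(a$lat) == length(b$lat) && length(a$lon) == length(b$lon) &&
    all(abs(a$lat - b$lat) < 1e-9) && all(abs(a$lon - b$lon) < 1e-9)
}

stopifnot_same_grid <- function(...) {
  fs <- list(...)
  for (i in seq_along(fs)[-1])
    if (!same_grid(fs[[1]], fs[[i]])) stop("grids do not match")
  invisible(TRUE)
}

# Block-sum a matrix by an integer factor along both axes.
block_sum <- function(mat, f) {
  if (nrow(mat) %% f != 0 || ncol(mat) %% f != 0)
    stop("matrix dimensions not divisible by aggregation factor")
  g1 <- rep(seq_len(nrow(mat) / f), each = f)
  g2 <- rep(seq_len(ncol(mat) / f), each = f)
  t(rowsum(t(rowsum(mat, g1)), g2))
}

# Modal value per block for categorical integer rasters; ties broken by the
# smallest code, so class precedence is set by code order.
block_mode <- function(mat, f) {
  if (f == 1) return(mat)
  nlat <- nrow(mat) / f; nlon <- ncol(mat) / f
  out <- matrix(NA_integer_, nlat, nlon)
  for (i in seq_len(nlat)) for (j in seq_len(nlon)) {
    blk <- mat[(i - 1) * f + seq_len(f), (j - 1) * f + seq_len(f)]
    blk <- blk[!is.na(blk)]
    if (length(blk)) {
      tab <- table(blk)
      out[i, j] <- as.integer(names(tab)[which.max(tab)][1])
    }
  }
  out
}

#' Aggregate a fine grid to 0.5 degree by summation
#'
#' Extensive quantities (masses) are summed over the fine cells making up
#' each 0.5 deg cell, so the global total is conserved exactly.
#'
#' @param fine a `grid_field` whose resolution divides 0.5 evenly
#'   (e.g. 0.25 deg or 5 arcmin).
#' @return a `grid_field` at 0.5 deg.
#' @export
aggregate_to_half_degree <- function(fine) {
  f <- 0.5 / fine$resolution
  if (abs(f - round(f)) > 1e-9)
    stop("fine resolution does not divide 0.5 degrees evenly")
  f <- as.integer(round(f))
  vals <- block_sum(fine$values, f)
  lat <- block_centers(fine$lat, f)
  lon <- block_centers(fine$lon, f)
  grid_field(vals, lat, lon, year = fine$year, units = fine$units)
}

block_centers <- function(centers, f) {
  m <- matrix(centers, nrow = f)
  colMeans(m)
}

# Map lat/lon points to (row, col) cell indices on a field's grid; points
# outside the extent give NA.
cell_index <- function(gf, lat, lon) {
  res <- gf$resolution
  i <- floor((lat - (gf$lat[1] - res / 2)) / res) + 1
  j <- floor((lon - (gf$lon[1] - res / 2)) / res) + 1
  i[i < 1 | i > length(gf$lat)] <- NA
  j[j < 1 | j > length(gf$lon)] <- NA
  list(row = as.integer(i), col = as.integer(j))
}
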