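# Shared fixtures, built once per test run.
fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = fixture_env))
    assign(name, builder(), envir = fixture_env)
  get(name, envir = fixture_env)
}

params_default <- function() fixture("params", load_params)

# Small worlds for module tests (3 years keeps them fast).
small_world <- function()
  fixture("small_world",
          function() standard_world(seed = 42, years = 2009:2011))

small_stages <- function()
  fixture("small_stages",
          function() pipeline_stages(small_world(), params_default()))

# Quick field on a toy grid.
make_field <- function(values, resolution = 0.5, year = 2010,
                       units = "Mg/yr") {
  values <- as.matrix(values)
  ax <- toy_axes(nrow(values), ncol(values), resolution_deg = resolution)
  grid_field(values, ax$lat, ax$lon, year = year, units = units)
}

# Minimal mask: one integer code matrix, default region maps.
make_mask <- function(codes, constant_ratio = NULL, fcr = NULL,
                      max_return = NULL) {
  codes <- as.matrix(codes)
  ax <- toy_axes(nrow(codes), ncol(codes))
  countries <- sprintf("C%02d", sort(unique(stats::na.omit(as.vector(codes)))))
  def <- function(x, d) if (is.null(x))
    stats::setNames(rep(d, length(countries)), countries) else x
  country_mask(codes, ax$lat, ax$lon, countries, list(
    constant_ratio = def(constant_ratio, "default"),
    fcr = def(fcr, "south"),
    max_return = def(max_return, "other")))
}

# Independent brute-force trade allocator for small grids: enumerates
# Chebyshev distances with an explicit distance matrix and nested loops.
# Same policy (rings outward, row-major deficit order, proportional
# draws) but none of the implementation's machinery.
oracle_trade <- function(prod, burnt, demand, cap = 0.9, radius = 20) {
  n <- nrow(prod); m <- ncol(prod)
  avail <- pmax(cap * prod - burnt, 0)
  local <- pmin(demand, avail)
  deficit <- demand - local
  capacity <- avail - local
  exports <- matrix(0, n, m)
  for (r in seq_len(radius)) {
    for (i in seq_len(n)) for (j in seq_len(m)) {
      if (deficit[i, j] <= 1e-12) next
      dist <- outer(abs(seq_len(n) - i), abs(seq_len(m) - j), pmax)
      ring <- which(dist == r & capacity > 0, arr.ind = TRUE)
      if (!nrow(ring)) next
      sup <- sum(capacity[ring])
      draw <- min(deficit[i, j], sup)
      for (k in seq_len(nrow(ring))) {
        take <- capacity[ring[k, 1], ring[k, 2]] * draw / sup
        capacity[ring[k, 1], ring[k, 2]] <-
          capacity[ring[k, 1], ring[k, 2]] - take
        exports[ring[k, 1], ring[k, 2]] <-
          exports[ring[k, 1], ring[k, 2]] + take
      }
      deficit[i, j] <- deficit[i, j] - draw
    }
  }
  list(animal = local + exports, unmet = deficit,
       traded = sum(exports))
}
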