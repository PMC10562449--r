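test_that("the GDP bound is 30/10 percent at the extremes, linear between", {
  expect_equal(gdp_other_use_bound(800), 0.30)
  expect_equal(gdp_other_use_bound(0), 0.30)
  expect_equal(gdp_other_use_bound(20000), 0.10)
  mid <- (1046 + 12735) / 2
  expect_equal(gdp_other_use_bound(mid), 0.20)
  # continuous at the thresholds
  expect_equal(gdp_other_use_bound(1046), 0.30)
  expect_equal(gdp_other_use_bound(12735), 0.10)
  expect_equal(gdp_other_use_bound(1046 + 1e-9), 0.30, tolerance = 1e-10)
  # monotonically non-increasing and piecewise linear
  g <- seq(0, 20000, by = 50)
  b <- gdp_other_use_bound(g)
  expect_true(all(diff(b) <= 1e-15))
  inner <- g > 1046 & g < 12735
  expect_equal(b[inner],
               0.30 + (0.10 - 0.30) * (g[inner] - 1046) / (12735 - 1046))
})

test_that("trade fills a two-cell deficit from the neighbouring exporter", {
  # cell (1,1): production 0, demand 5; cell (1,2): capacity 10
  prod <- make_field(matrix(c(0, 100 / 9), 1, 2))
  burnt <- make_field(matrix(0, 1, 2))
  dem <- make_field(matrix(c(5, 0), 1, 2))
  out <- trade_residues(prod, burnt, dem)
  expect_equal(as.vector(out$animal_usage$values), c(0, 5))
  expect_true(all(out$unmet_demand$values == 0))
  expect_equal(nrow(out$trade_log), 1)
  expect_equal(out$trade_log$mass, 5)
  expect_equal(out$trade_log$from_col, 2)
  expect_equal(out$trade_log$to_col, 1)
})

test_that("no-deficit grids trade nothing", {
  prod <- make_field(matrix(100, 3, 3))
  burnt <- make_field(matrix(10, 3, 3))
  dem <- make_field(matrix(20, 3, 3))
  out <- trade_residues(prod, burnt, dem)
  expect_equal(out$animal_usage$values, dem$values)
  expect_true(all(out$unmet_demand$values == 0))
  expect_equal(nrow(out$trade_log), 0)
})

test_that("supply beyond the trade radius stays out of reach", {
  # 1 x 25 strip: deficit at cell 1, sole capacity at cell 22 (distance 21)
  prod <- matrix(0, 1, 25); prod[1, 22] <- 100
  dem <- matrix(0, 1, 25); dem[1, 1] <- 5
  out <- trade_residues(make_field(prod), make_field(matrix(0, 1, 25)),
                        make_field(dem))
  expect_equal(out$unmet_demand$values[1, 1], 5)
  expect_equal(out$animal_usage$values[1, 1], 0)
  expect_equal(nrow(out$trade_log), 0)
  # at distance 20 the same supply is reachable
  prod2 <- matrix(0, 1, 25); prod2[1, 21] <- 100
  out2 <- trade_residues(make_field(prod2), make_field(matrix(0, 1, 25)),
                         make_field(dem))
  expect_equal(out2$unmet_demand$values[1, 1], 0)
  expect_equal(out2$animal_usage$values[1, 21], 5)
})

test_that("trade agrees with the exhaustive oracle on small grids", {
  set.seed(31)
  for (rep in 1:8) {
    n <- sample(3:6, 1); m <- sample(3:6, 1)
    prod <- matrix(rexp(n * m, 1 / 50), n, m)
    prod[runif(n * m) < 0.3] <- 0
    burnt <- pmin(matrix(rexp(n * m, 1 / 5), n, m), 0.9 * prod)
    dem <- matrix(rexp(n * m, 1 / 30), n, m)
    got <- trade_residues(make_field(prod), make_field(burnt),
                          make_field(dem))
    want <- oracle_trade(prod, burnt, dem)
    expect_equal(sum(got$trade_log$mass), want$traded, tolerance = 1e-9)
    expect_equal(got$unmet_demand$values, want$unmet, tolerance = 1e-9)
    expect_equal(got$animal_usage$values, want$animal, tolerance = 1e-9)
    # post-condition: removal cap respected everywhere
    expect_true(all(burnt + got$animal_usage$values <=
                      0.9 * prod + 1e-9))
    # trade conserves mass: demand met = mass exported
    met <- dem - pmin(dem, pmax(0.9 * prod - burnt, 0)) -
      got$unmet_demand$values
    expect_equal(sum(got$trade_log$mass), sum(met), tolerance = 1e-9)
  }
})

test_that("all trades respect the Chebyshev radius and are logged", {
  set.seed(32)
  n <- 30
  prod <- matrix(rexp(n * n, 1 / 40), n, n)
  prod[runif(n * n) < 0.5] <- 0
  dem <- matrix(rexp(n * n, 1 / 30), n, n)
  burnt <- matrix(0, n, n)
  p <- allocation_params(trade_radius_cells = 4L)
  out <- trade_residues(make_field(prod), make_field(burnt),
                        make_field(dem), p)
  log <- out$trade_log
  expect_gt(nrow(log), 0)
  d <- pmax(abs(log$from_row - log$to_row), abs(log$from_col - log$to_col))
  expect_true(all(d >= 1 & d <= 4))
  # imports equal exports by construction of the log
  expect_equal(sum(log$mass),
               sum(out$animal_usage$values) -
                 sum(pmin(dem, pmax(0.9 * prod - burnt, 0))),
               tolerance = 1e-9)
  expect_error(trade_residues(make_field(prod), make_field(burnt),
                              make_field(-dem)), "negative")
})

test_that("nearer rings are drawn before farther ones", {
  # deficit at centre; exporters at distances 1 and 3; the near one drains
  prod <- matrix(0, 7, 7)
  prod[4, 5] <- 10 / 9 * 3   # capacity 3 at distance 1
  prod[4, 7] <- 10 / 9 * 50  # plenty at distance 3
  dem <- matrix(0, 7, 7); dem[4, 4] <- 5
  out <- trade_residues(make_field(prod), make_field(matrix(0, 7, 7)),
                        make_field(dem))
  expect_equal(out$animal_usage$values[4, 5], 10 / 9 * 3 * 0.9,
               tolerance = 1e-9)  # fully drained
  expect_equal(out$animal_usage$values[4, 7], 5 - 3, tolerance = 1e-9)
})

test_that("other uses are bounded by GDP and by availability", {
  mask <- make_mask(matrix(c(1, 2), 1, 2))
  gdp <- c(C01 = 800, C02 = 20000)
  prod <- make_field(matrix(100, 1, 2))
  burnt <- make_field(matrix(0, 1, 2))
  # poor country with animal usage 80: min(30, 90 - 80) = 10
  animal <- make_field(matrix(c(80, 0), 1, 2))
  out <- assign_other_uses(prod, burnt, animal, gdp, mask)
  expect_equal(as.vector(out$values), c(10, 10))
  # rich country, nothing else removed: bound-limited at 10
  animal0 <- make_field(matrix(0, 1, 2))
  out0 <- assign_other_uses(prod, burnt, animal0, gdp, mask)
  expect_equal(as.vector(out0$values), c(30, 10))
  # zero production -> zero other use
  zero <- make_field(matrix(0, 1, 2))
  expect_true(all(assign_other_uses(zero, burnt, animal0, gdp,
                                    mask)$values == 0))
})

test_that("left on field respects the regional return ceilings", {
  mask <- make_mask(matrix(c(1, 2, 3), 1, 3),
                    max_return = c(C01 = "china", C02 = "europe",
                                   C03 = "other"))
  prod <- make_field(matrix(100, 1, 3))
  burnt <- make_field(matrix(c(10, 5, 5), 1, 3))
  animal <- make_field(matrix(c(10, 10, 0), 1, 3))
  other <- make_field(matrix(c(10, 10, 0), 1, 3))
  # raw left: 70 (china, cap 60), 75 (europe, cap 70), 95 (uncapped)
  out <- left_on_field(prod, burnt, animal, other, mask)
  expect_equal(as.vector(out$left$values), c(60, 70, 95))
  expect_equal(as.vector(out$other_adjusted$values), c(20, 15, 0))
  # mass balance preserved by the shift
  expect_equal(out$left$values + out$other_adjusted$values +
                 burnt$values + animal$values, prod$values)
  # negative remainder signals an upstream cap violation
  big <- make_field(matrix(95, 1, 3))
  expect_error(left_on_field(prod, big, animal, other, mask), "negative")
})

test_that("ledger assembly enforces the usage invariants", {
  led <- assemble_ledger(make_field(matrix(100, 2, 2)),
                         make_field(matrix(10, 2, 2)),
                         make_field(matrix(40, 2, 2)),
                         make_field(matrix(10, 2, 2)),
                         make_field(matrix(40, 2, 2)))
  expect_s3_class(led, "usage_ledger")
  # components summing to 99 rather than 100 are rejected
  expect_error(assemble_ledger(make_field(matrix(100, 2, 2)),
                               make_field(matrix(10, 2, 2)),
                               make_field(matrix(40, 2, 2)),
                               make_field(matrix(10, 2, 2)),
                               make_field(matrix(39, 2, 2))),
               "mass balance")
  # leaving only 5 percent on the field is rejected
  expect_error(assemble_ledger(make_field(matrix(100, 2, 2)),
                               make_field(matrix(20, 2, 2)),
                               make_field(matrix(40, 2, 2)),
                               make_field(matrix(35, 2, 2)),
                               make_field(matrix(5, 2, 2))),
               "minimum left|removal cap")
  # negative layers are rejected
  expect_error(assemble_ledger(make_field(matrix(100, 2, 2)),
                               make_field(matrix(10, 2, 2)),
                               make_field(matrix(40, 2, 2)),
                               make_field(matrix(60, 2, 2)),
                               make_field(matrix(-10, 2, 2))),
               "non-negative")
})

test_that("allocation parameter invariants are enforced", {
  expect_error(allocation_params(min_left_fraction = 0.2), "not")
  expect_error(allocation_params(bogus = 1), "unknown")
  p <- allocation_params(trade_radius_cells = 5L)
  expect_equal(p$trade_radius_cells, 5L)
  expect_equal(p$max_return[["china"]], 0.60)
  expect_equal(p$max_return[["europe"]], 0.70)
  expect_equal(p$max_return[["north_america_oceania"]], 0.80)
})
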