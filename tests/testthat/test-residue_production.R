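test_that("exponential residue yields match direct scalar evaluation", {
  expect_equal(residue_yield_exponential(0, "wheat"), 0)
  # frozen: 2.183 * 1 * exp(-0.127 * 1)
  expect_equal(residue_yield_exponential(1, "wheat"), 1.92264160728,
               tolerance = 1e-10)
  # above 1/b = 7.874 the plateau a/(b e) applies; frozen 2.183/(0.127 e)
  expect_equal(residue_yield_exponential(10, "wheat"), 6.32347102423,
               tolerance = 1e-10)
  expect_equal(residue_yield_exponential(8, "wheat"),
               residue_yield_exponential(100, "wheat"))
  expect_error(residue_yield_exponential(1, "soybean"), "unknown crop")
})

test_that("exponential form is continuous with its maximum at Y = 1/b", {
  for (cr in cereal_crops()) {
    p <- harvest_index_params()
    b <- p$b[p$crop == cr]
    below <- residue_yield_exponential(1 / b - 1e-9, cr)
    at <- residue_yield_exponential(1 / b, cr)
    above <- residue_yield_exponential(1 / b + 1e-9, cr)
    expect_lt(abs(at - above), 1e-12)
    expect_lt(abs(at - below), 1e-8)
    # the plateau value is the maximum over the whole range
    ys <- seq(0, 3 / b, length.out = 500)
    expect_lte(max(residue_yield_exponential(ys, cr)), at + 1e-12)
  }
})

test_that("linear residue yields follow Y(c - dY), clamped at zero", {
  expect_equal(residue_yield_linear(0, "rice"), 0)
  expect_equal(residue_yield_linear(2, "rice"), 4.24)   # 2 * (2.56 - 0.44)
  expect_equal(residue_yield_linear(15, "wheat"), 0)    # formula gives -2.1
  expect_true(all(residue_yield_linear(seq(0, 50, 0.5), "millet") >= 0))
  expect_error(residue_yield_linear(1, "soybean"), "unknown crop")
})

test_that("harvest-index defaults carry the published fitted values", {
  p <- harvest_index_params()
  maize <- p[p$crop == "maize", ]
  expect_equal(unlist(maize[c("a", "b", "c", "d")], use.names = FALSE),
               c(2.656, 0.103, 2.2, 0.13))
  other <- p[p$crop == "other_cereals", ]
  expect_equal(unlist(other[c("a", "b", "c", "d")], use.names = FALSE),
               c(1.9, 0.250, 2.7, 0.2))
  p2 <- harvest_index_params(list(wheat = list(a = 2.0)))
  expect_equal(p2$a[p2$crop == "wheat"], 2.0)
  expect_equal(p2$b[p2$crop == "wheat"], 0.127)
})

test_that("country rescaling allocates proportionally and conserves totals", {
  mask <- make_mask(matrix(c(1, 1, 2, 2), 2, 2))
  base_p <- make_field(matrix(c(25, 75, 10, 0), 2, 2))  # C01 col 1, C02 col 2
  base_a <- make_field(matrix(c(10, 30, 5, 0), 2, 2), units = "ha")
  tab <- rbind(
    data.frame(country = "C01", year = 2010,
               variable = "grain.wheat", value = 100),
    data.frame(country = "C02", year = 2010,
               variable = "grain.wheat", value = 10),
    data.frame(country = "C01", year = 2010,
               variable = "area.wheat", value = 40),
    data.frame(country = "C02", year = 2010,
               variable = "area.wheat", value = 5),
    data.frame(country = "C01", year = 2011,
               variable = "grain.wheat", value = 200),
    data.frame(country = "C02", year = 2011,
               variable = "grain.wheat", value = 30),
    data.frame(country = "C01", year = 2011,
               variable = "area.wheat", value = 40),
    data.frame(country = "C02", year = 2011,
               variable = "area.wheat", value = 5))
  cs <- country_series(tab, 2010:2011)

  # shares 0.25/0.75 of a 200 Mg total -> 50/150
  out <- scale_grain_to_country(base_p, base_a, cs, mask, "wheat", 2011)
  expect_equal(out$production$values[, 1], c(50, 150))
  # one-cell country: full total lands in the cell
  expect_equal(out$production$values[1, 2], 30)
  expect_equal(out$production$values[2, 2], 0)

  # base-year totals equal the gridded totals -> identity
  out0 <- scale_grain_to_country(base_p, base_a, cs, mask, "wheat", 2010)
  expect_equal(out0$production$values, base_p$values, tolerance = 1e-12)
  expect_equal(out0$area$values, base_a$values, tolerance = 1e-12)

  # conservation: country sums match the table wherever base coverage > 0
  for (yr in 2010:2011) {
    o <- scale_grain_to_country(base_p, base_a, cs, mask, "wheat", yr)
    sums <- resalloc:::country_sums(o$production$values, mask)
    tabv <- cs_value(cs, "grain.wheat", yr)
    expect_equal(sums[names(tabv)], tabv, tolerance = 1e-9)
  }
  expect_error(scale_grain_to_country(base_p, base_a, cs, mask, "wheat",
                                      1999), "range")
})

test_that("uncovered countries are flagged, not silently dropped", {
  mask <- make_mask(matrix(c(1, 1, 2, 2), 2, 2))
  base_p <- make_field(matrix(c(25, 75, 0, 0), 2, 2))  # C02 has no base prod
  base_a <- make_field(matrix(c(10, 30, 0, 0), 2, 2), units = "ha")
  tab <- expand.grid(country = c("C01", "C02"), year = 2010,
                     variable = c("grain.wheat", "area.wheat"),
                     stringsAsFactors = FALSE)
  tab$value <- c(100, 50, 40, 20)
  out <- scale_grain_to_country(base_p, base_a,
                                country_series(tab, 2010), mask,
                                "wheat", 2010)
  expect_identical(out$uncovered, "C02")
})

test_that("constant-ratio conversion is region and crop specific", {
  mask <- make_mask(matrix(c(1, 1, 2, 2), 2, 2),
                    constant_ratio = c(C01 = "low", C02 = "high"))
  prod <- make_field(matrix(10, 2, 2))
  ratios <- rbind(constant_residue_ratios("low"),
                  constant_residue_ratios("high"))
  ratios$ratio[ratios$region == "low" & ratios$crop == "wheat"] <- 1.0
  ratios$ratio[ratios$region == "high" & ratios$crop == "wheat"] <- 2.0
  out <- residue_from_ratio(prod, mask, "wheat", ratios)
  expect_equal(out$values[, 1], c(10, 10))
  expect_equal(out$values[, 2], c(20, 20))
  expect_equal(residue_from_ratio(make_field(matrix(0, 2, 2)), mask,
                                  "wheat", ratios)$values,
               matrix(0, 2, 2))
  expect_error(residue_from_ratio(prod, mask, "wheat",
                                  constant_residue_ratios("elsewhere")),
               "no constant ratio")
})

test_that("yield-based methods produce residue = R(yield) x area", {
  mask <- make_mask(matrix(1, 1, 2))
  prod <- make_field(matrix(c(20, 0), 1, 2))
  area <- make_field(matrix(c(10, 0), 1, 2), units = "ha")
  out <- residue_production_method("exponential", prod, area, mask, "wheat")
  expect_equal(out$values[1, 1],
               residue_yield_exponential(2, "wheat") * 10)
  expect_equal(out$values[1, 2], 0)  # zero area -> zero residue
  outl <- residue_production_method("linear", prod, area, mask, "rice")
  expect_equal(outl$values[1, 1], residue_yield_linear(2, "rice") * 10)
})

test_that("totals and method means behave linearly", {
  set.seed(21)
  fields <- lapply(cereal_crops(), function(cr)
    make_field(matrix(runif(16), 4, 4)))
  tot <- total_cereal_residue(fields)
  expect_equal(sum(tot$values),
               sum(vapply(fields, function(g) sum(g$values), numeric(1))))
  one <- total_cereal_residue(fields[1])
  expect_equal(one$values, fields[[1]]$values)

  m1 <- make_field(matrix(0, 2, 2)); m2 <- make_field(matrix(3, 2, 2))
  m3 <- make_field(matrix(6, 2, 2))
  expect_true(all(mean_production(list(m1, m2, m3))$values == 3))
  expect_error(mean_production(list(m1, m2)), "three")
  # mean within the per-cell envelope
  set.seed(22)
  ms <- lapply(1:3, function(i) make_field(matrix(runif(25), 5, 5)))
  mn <- mean_production(ms)$values
  lo <- pmin(ms[[1]]$values, ms[[2]]$values, ms[[3]]$values)
  hi <- pmax(ms[[1]]$values, ms[[2]]$values, ms[[3]]$values)
  expect_true(all(mn >= lo - 1e-12 & mn <= hi + 1e-12))
})
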