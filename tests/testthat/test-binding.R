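test_that("4PL recovers generating parameters from noiseless curves", {
  for (mid in c(706, 29.4, 37.5)) {
    dr <- simulateDoseResponse(doses = 10^seq(-1, 4, length.out = 8),
                               midpoint = mid)
    fit <- fit4PL(dr$dose, dr$response)
    expect_true(fit@converged)
    expect_equal(midpoint(fit), mid, tolerance = 1e-3)
  }
  # slopes across the practical range
  for (s in c(0.5, 1, 2, 3)) {
    dr <- simulateDoseResponse(doses = 10^seq(0, 4, length.out = 9),
                               midpoint = 100, slope = s)
    fit <- fit4PL(dr$dose, dr$response)
    expect_equal(midpoint(fit), 100, tolerance = 1e-3)
    expect_equal(fit@slope, s, tolerance = 1e-3)
  }
})

test_that("4PL midpoint is recovered within 5% under 3% noise, seeded replicates", {
  set.seed(20210415)
  errs <- replicate(40, {
    dr <- simulateDoseResponse(doses = 10^seq(-1, 3.5, length.out = 8),
                               midpoint = 29.4, cv = 0.03)
    abs(midpoint(fit4PL(dr$dose, dr$response)) - 29.4) / 29.4
  })
  expect_lt(median(errs), 0.05)
  expect_lt(mean(errs > 0.10), 0.1)
})

test_that("the half-maximal property holds: response at the midpoint is 50%", {
  dr <- simulateDoseResponse(midpoint = 50, slope = 1, top = 100, bottom = 0)
  fit <- fit4PL(dr$dose, dr$response)
  expect_equal(predict4PL(fit, midpoint(fit)), 50, tolerance = 1e-6)
  expect_equal(invert4PL(fit, 50), midpoint(fit), tolerance = 1e-6)
})

test_that("4PL rejects degenerate inputs", {
  expect_error(fit4PL(c(1, 10, 100, 0), rep(50, 4)), "4 distinct non-zero")
  expect_error(fit4PL(c(1, 10, 100, 1000), rep(50, 4)), "degenerate")
})

test_that("LOD follows the blank-minus-2SD rule and is monotone in the blank SD", {
  dr <- simulateDoseResponse(doses = 10^seq(-1, 4, length.out = 8),
                             midpoint = 29.9)
  fit <- fit4PL(dr$dose, dr$response)

  # B0 replicates engineered to exact mean 100 and a chosen SD
  b0At <- function(s) {
    z <- scale(seq_len(10))[, 1]
    100 + s * z / sd(z)
  }

  # SD chosen so the rule lands on the 3.9 pg/assay detection limit
  sdFor39 <- 50 * (1 - 1 / (1 + 3.9 / 29.9))
  res <- lodDose(fit, b0At(sdFor39))
  expect_true(res$defined)
  expect_equal(res$lod, 3.9, tolerance = 1e-3)

  lods <- vapply(c(2, 4, 6, 8), function(s) lodDose(fit, b0At(s))$lod,
                 numeric(1))
  expect_true(all(diff(lods) > 0))

  # zero-variance blanks: the threshold sits at the top asymptote, so the
  # LOD degenerates to the dose where the curve first leaves B0 (0 in the
  # limit) or is flagged undefined when the threshold is not bracketed
  res0 <- lodDose(fit, rep(100, 10))
  expect_true(is.na(res0$lod) || res0$lod < 1e-4)

  expect_error(lodDose(fit, 100), "at least 2")
})

test_that("cross-reactivity is the IC50 ratio in percent", {
  expect_equal(crossReactivity(100, 100), 100)
  expect_equal(crossReactivity(50, 100), 50)
  expect_equal(crossReactivity(706, 90513), 0.78, tolerance = 1e-2)
  expect_error(crossReactivity(-1, 10), "positive")
})

test_that("unit conversions reproduce the worked assay example", {
  u <- convertUnits(10)
  expect_equal(u$pgPerMl, 66.7, tolerance = 1e-3)
  expect_equal(u$pmolPerL, 184, tolerance = 1e-3)

  lod <- convertUnits(10.2)
  expect_equal(lod$serumNgPerMl, 2.04)
  expect_equal(round(lod$serumNgPerMl), 2)

  zero <- convertUnits(0)
  expect_true(all(zero[1, ] == 0))

  # linearity and the pg/mL <-> pmol/L round trip
  u2 <- convertUnits(c(1, 2, 4))
  expect_equal(u2$pgPerMl[3] / u2$pgPerMl[1], 4)
  expect_equal(u2$pmolPerL * 362.46 / 1000, u2$pgPerMl)

  expect_error(assayConfig(totalVolumeUl = -1), "positive")
  expect_error(assayConfig(standardVolumeUl = 200), "cannot exceed")
})

test_that("Scatchard regression recovers the association constant", {
  sc <- simulateScatchard(ka = 3.6e8)
  res <- scatchardKa(sc$bound, sc$free)
  expect_true(res$valid)
  expect_equal(res$ka, 3.6e8, tolerance = 1e-6)
  expect_equal(res$sites, 1e-9, tolerance = 1e-6)

  # noisy recovery at the high-affinity end, seeded replicates
  set.seed(99)
  errs <- replicate(40, {
    sc <- simulateScatchard(ka = 1.1e10, cv = 0.02)
    abs(scatchardKa(sc$bound, sc$free)$ka - 1.1e10) / 1.1e10
  })
  expect_lt(median(errs), 0.10)

  # bound/free constant in bound -> invalid
  flat <- scatchardKa(bound = c(1e-10, 2e-10, 3e-10),
                      free = c(1e-9, 2e-9, 3e-9))
  expect_false(flat$valid)
  expect_true(is.na(flat$ka))
  expect_error(scatchardKa(1:2 * 1e-10, 1:2 * 1e-9), "at least 3")
  expect_error(scatchardKa(c(-1, 1, 2), c(1, 1, 1)), "positive")
})

test_that("fold improvement reproduces the headline ratios and display rounding", {
  f31 <- foldImprovement(1.1e10, 3.6e8)
  expect_equal(as.numeric(f31), 30.56, tolerance = 1e-3)
  expect_identical(attr(f31, "display"), 31)

  f17 <- foldImprovement(0.62e10, 3.6e8)
  expect_equal(as.numeric(f17), 17.2, tolerance = 1e-2)
  expect_identical(attr(f17, "display"), 17)

  # midpoint sensitivity gain of the best mutants vs the parent
  f24 <- foldImprovement(706, 29.4)
  expect_identical(attr(f24, "display"), 24)
  expect_identical(attr(foldImprovement(706, 29.9), "display"), 24)

  expect_equal(as.numeric(foldImprovement(2, 2)), 1)
  # halves round away from zero
  expect_identical(attr(foldImprovement(2.5, 1), "display"), 3)
  expect_error(foldImprovement(0, 1), "positive")
})
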