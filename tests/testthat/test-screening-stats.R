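test_that("closed-form coverage matches the screening-campaign arithmetic", {
  # 4,700 uniform picks over the 1,536-member substitution library leave
  # about 72 members unobserved in expectation
  cv <- coverage(4700, k = 1536)
  expect_equal(cv@expectedMissing, 1536 * (1 - 1 / 1536)^4700)
  expect_equal(cv@expectedMissing, 72.0, tolerance = 1e-3)
  expect_equal(cv@expectedDistinct / 1536, 0.953, tolerance = 1e-3)

  one <- coverage(10, k = 1)
  expect_equal(one@expectedMissing, 0)
  expect_equal(one@pFull, 1)

  zero <- coverage(0, k = 7)
  expect_equal(zero@expectedMissing, 7)
  expect_equal(zero@pFull, 0)
})

test_that("coverage is monotone in the number of draws", {
  k <- 50
  ns <- c(0, 10, 50, 120, 300, 800)
  reports <- lapply(ns, coverage, k = k)
  distinct <- vapply(reports, function(r) r@expectedDistinct, numeric(1))
  pfull <- vapply(reports, function(r) r@pFull, numeric(1))
  expect_true(all(diff(distinct) >= 0))
  expect_true(all(diff(pfull) >= -1e-12))
  expect_true(all(distinct <= pmin(ns, k) + 1e-9))
})

test_that("exact inclusion-exclusion and the Poisson approximation agree for small k", {
  for (k in c(3, 8, 15)) {
    n <- 12 * k
    exact <- coverage(n, k = k)
    expect_identical(exact@method, "inclusion-exclusion")
    approx <- coverage(n, k = k, kExact = 0L)
    expect_identical(approx@method, "poisson")
    expect_equal(approx@pFull, exact@pFull, tolerance = 0.05)
  }
})

test_that("closed forms agree with the seeded Monte-Carlo oracle within 3 SE", {
  set.seed(11)
  for (k in c(25, 400)) {
    n <- 4 * k
    mc <- coverageMonteCarlo(n, k = k, replicates = 4000)
    cv <- coverage(n, k = k)
    expect_lt(abs(cv@expectedMissing - mc$meanMissing),
              3 * mc$seMissing + 1e-6)
  }
})

test_that("codon-multiplicity weighting lowers expected coverage versus uniform", {
  # weight dispersion can only reduce the expected number of distinct
  # variants observed (Jensen), checked on the single-insertion library
  w <- variantMultiplicities(libraryBSpec(1))
  w <- w / sum(w)
  n <- 50
  weighted <- coverage(n, weights = unname(w))
  uniform <- coverage(n, k = length(w))
  expect_lt(weighted@expectedDistinct, uniform@expectedDistinct)

  mc <- coverageMonteCarlo(n, weights = unname(w), replicates = 3000, seed = 7)
  expect_lt(abs(weighted@expectedMissing - mc$meanMissing),
            3 * mc$seMissing + 1e-6)
})

test_that("draws-for-coverage inverts pFull and scales super-linearly in k", {
  expect_identical(drawsForFullCoverage(0.99, k = 1), 1L)

  n20 <- drawsForFullCoverage(0.95, k = 20)
  expect_gte(coverage(n20, k = 20)@pFull, 0.95)
  expect_lt(coverage(n20 - 1, k = 20)@pFull, 0.95)

  ns <- vapply(c(10, 20, 40), function(k)
    as.numeric(drawsForFullCoverage(0.9, k = k)), numeric(1))
  expect_gt(ns[2], 2 * ns[1])
  expect_gt(ns[3], 2 * ns[2])

  # coupon-collector scale for the substitution library
  n1536 <- drawsForFullCoverage(0.95, k = 1536)
  expect_equal(n1536, 15800, tolerance = 0.02)
  expect_error(drawsForFullCoverage(1.2, k = 5), "between 0 and 1")
})

test_that("threshold hits use strict inequality and deterministic ordering", {
  rlu <- c(2000, 450000, 100000, 120000, 3000, 450000)
  hits <- thresholdHits(rlu, threshold = 1e5)
  expect_identical(hits$well, c(2L, 6L, 4L))  # ties by ascending index
  expect_identical(hits$rlu, c(450000, 450000, 120000))
  expect_identical(nrow(thresholdHits(numeric(0))), 0L)
  expect_identical(nrow(thresholdHits(rep(2000, 10))), 0L)
  expect_error(thresholdHits(c(-1, 5)), "non-negative")
})

test_that("functional fraction follows the NNS stop arithmetic", {
  expect_identical(functionalFraction(0), 1)
  expect_equal(functionalFraction(1), 31 / 32)
  expect_equal(functionalFraction(6), (31 / 32)^6)
  expect_equal(functionalFraction(6), 0.8265, tolerance = 1e-4)
  expect_error(functionalFraction(-1), "non-negative")
})

test_that("weight validation catches unnormalised and invalid inputs", {
  expect_error(coverage(10, weights = c(0.5, 0.6)), "sum to 1")
  expect_error(coverage(10, weights = c(-0.5, 1.5)), "positive")
  expect_error(coverage(-1, k = 5), "non-negative")
  expect_error(coverage(10), "supply either")
})
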