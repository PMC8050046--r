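# Coupon-collector coverage statistics for colony-screening campaigns and
# signal-threshold bookkeeping of plate readouts. Colony picks are modelled
# as i.i.d. multinomial draws over the library's variant abundances.

.checkWeights <- function(weights, k) {
  if (!is.null(weights)) {
    if (any(!is.finite(weights)) || any(weights <= 0))
      stop("variant weights must be positive and finite")
    if (abs(sum(weights) - 1) > 1e-8)
      stop(sprintf("variant weights must sum to 1 (got %.10g)", sum(weights)))
    return(as.numeric(weights))
  }
  if (is.null(k) || k < 1 || k != round(k))
    stop("supply either normalized 'weights' or an integer 'k' for uniform abundances")
  rep(1 / k, k)
}

# exact P(all k variants seen) by inclusion-exclusion over subsets;
# feasible for k <= kExact (2^k terms, vectorised by iterative doubling)
.pFullExact <- function(weights, n) {
  sums <- 0
  sign <- 1
  for (w in weights) {
    sums <- c(sums, sums + w)
    sign <- c(sign, -sign)
  }
  p <- sum(sign * pmax(1 - sums, 0)^n)
  min(max(p, 0), 1)
}

# Poissonized / independence approximation: treat per-variant observation
# events as independent
.pFullPoisson <- function(weights, n) {
  exp(sum(log1p(-(1 - weights)^n)))
}

#' Expected screening coverage of a variant library
#'
#' For a library of `k` variants with relative abundances `weights`, sampled
#' as `nDraws` i.i.d. colony picks, computes the expected number of variants
#' missed (closed form `sum((1 - w_i)^nDraws)`), the expected number of
#' distinct variants observed, and the probability of observing all `k`
#' variants. `pFull` is exact (inclusion-exclusion) for `k <= kExact` and
#' uses the independence (Poissonization) approximation otherwise; the
#' report records which method was used. An optional seeded Monte-Carlo
#' cross-check is available via [coverageMonteCarlo()].
#'
#' @param nDraws Number of colonies sampled (non-negative).
#' @param weights Positive abundances summing to 1, one per variant; or
#'   `NULL` with `k` for the uniform model.
#' @param k Number of variants (uniform model shortcut).
#' @param kExact Largest k for which `pFull` is computed exactly.
#' @return A [CoverageReport-class].
#' @examples
#' coverage(4700, k = 1536)  # ~72 of 1,536 members expected missing
#' coverage(10, k = 4)
#' @export
coverage <- function(nDraws, weights = NULL, k = NULL, kExact = 20L) {
  if (nDraws < 0) stop("nDraws must be non-negative")
  w <- .checkWeights(weights, k)
  kk <- length(w)
  missing <- sum((1 - w)^nDraws)
  if (nDraws < kk) {
    pFull <- 0
    method <- "exact"
  } else if (kk <= kExact) {
    pFull <- .pFullExact(w, nDraws)
    method <- "inclusion-exclusion"
  } else {
    pFull <- .pFullPoisson(w, nDraws)
    method <- "poisson"
  }
  new("CoverageReport", nDraws = as.numeric(nDraws), k = as.numeric(kk),
      expectedDistinct = kk - missing, expectedMissing = missing,
      pFull = pFull, method = method)
}

#' Monte-Carlo coverage simulation
#'
#' Simulates `replicates` screening campaigns of `nDraws` multinomial picks
#' and reports the mean and standard error of the number of distinct
#' variants observed and the fraction of campaigns achieving full coverage.
#' Used as the stochastic cross-check of the closed-form [coverage()].
#'
#' @inheritParams coverage
#' @param replicates Number of simulated campaigns.
#' @param seed RNG seed (set for reproducibility).
#' @return A list with `meanDistinct`, `seDistinct`, `meanMissing`,
#'   `seMissing`, `pFull` and `replicates`.
#' @examples
#' coverageMonteCarlo(100, k = 20, replicates = 500, seed = 1)
#' @export
coverageMonteCarlo <- function(nDraws, weights = NULL, k = NULL,
                               replicates = 1e4, seed = NULL) {
  w <- .checkWeights(weights, k)
  if (!is.null(seed)) set.seed(seed)
  # draw in blocks to bound memory at ~k x blockSize integers
  blockSize <- max(1L, min(replicates, floor(2e7 / length(w))))
  done <- 0L
  distinct <- numeric(replicates)
  while (done < replicates) {
    nb <- min(blockSize, replicates - done)
    m <- rmultinom(nb, nDraws, w)
    distinct[done + seq_len(nb)] <- colSums(m > 0L)
    done <- done + nb
  }
  list(meanDistinct = mean(distinct),
       seDistinct = sd(distinct) / sqrt(replicates),
       meanMissing = length(w) - mean(distinct),
       seMissing = sd(distinct) / sqrt(replicates),
       pFull = mean(distinct == length(w)),
       replicates = replicates)
}

#' Minimal number of draws for full coverage at a target probability
#'
#' Smallest `n` with `P(all variants observed in n draws) >= pTarget`, found
#' by doubling then bisection on the monotone `pFull(n)` of [coverage()].
#'
#' @inheritParams coverage
#' @param pTarget Target probability in (0, 1).
#' @return The minimal integer number of draws.
#' @examples
#' drawsForFullCoverage(0.99, k = 1)    # 1
#' drawsForFullCoverage(0.95, k = 20)
#' @export
drawsForFullCoverage <- function(pTarget, weights = NULL, k = NULL,
                                 kExact = 20L) {
  if (pTarget <= 0 || pTarget >= 1)
    stop("pTarget must lie strictly between 0 and 1")
  w <- .checkWeights(weights, k)
  pAt <- function(n) coverage(n, weights = w, kExact = kExact)@pFull
  lo <- length(w)
  hi <- max(2L * lo, 2L)
  while (pAt(hi) < pTarget) {
    lo <- hi
    hi <- hi * 2L
    if (hi > 2^40) stop("no feasible draw count found below 2^40")
  }
  while (hi - lo > 1L) {
    mid <- floor((lo + hi) / 2)
    if (pAt(mid) >= pTarget) hi <- mid else lo <- mid
  }
  if (pAt(lo) >= pTarget) lo else hi
}

#' Wells above a luminescence threshold
#'
#' Selects wells whose readout is strictly above `threshold` (the screening
#' rule "> 100,000 RLU"), sorted by descending signal with deterministic
#' ties broken by well index.
#'
#' @param rlu Numeric vector of per-well luminescence values.
#' @param threshold Threshold in the same units (default 1e5 RLU).
#' @param wells Optional well identifiers (default positional indices).
#' @return A data frame with columns `well` and `rlu`, one row per hit,
#'   ordered by descending `rlu`. Zero rows when nothing exceeds the
#'   threshold.
#' @examples
#' thresholdHits(c(2000, 450000, 120000), threshold = 1e5)
#' @export
thresholdHits <- function(rlu, threshold = 1e5, wells = seq_along(rlu)) {
  if (threshold < 0) stop("threshold must be non-negative")
  if (any(rlu < 0, na.rm = TRUE)) stop("RLU values must be non-negative")
  stopifnot(length(wells) == length(rlu))
  keep <- which(!is.na(rlu) & rlu > threshold)
  keep <- keep[order(-rlu[keep], keep)]
  data.frame(well = wells[keep], rlu = rlu[keep],
             stringsAsFactors = FALSE, row.names = NULL)
}
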