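# Seeded synthetic-data generators emulating the screening and assay data
# the analysis functions consume: plate luminescence readouts, competitive
# dose-response tables and Scatchard bound/free tables. All generators are
# pure functions of their arguments and the seed.

# normal truncated at zero by inverse-CDF sampling (luminescence cannot be
# negative while background SDs are of the order of the mean)
.rtruncnorm0 <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  pLow <- pnorm(0, mean, sd)
  qnorm(pLow + runif(n) * (1 - pLow), mean, sd)
}

#' Simulate a CAP screening plate readout
#'
#' Generates per-well luminescence for one arrayed screening plate: 94
#' colony wells plus 2 background wells by default, background drawn from a
#' normal truncated at zero, with a chosen number of planted high-signal
#' positive clones. Deterministic under `seed`.
#'
#' The default background (mean 2758, SD 1909 RLU) reproduces the
#' substitution-library plate statistics; other library pools ran at
#' 3329 +/- 3211, 507 +/- 928 and 679 +/- 2500 RLU.
#'
#' @param nColonyWells Number of colony wells (default 94).
#' @param nBackgroundWells Number of no-colony background wells (default 2).
#' @param backgroundMean,backgroundSd Background RLU statistics.
#' @param positives Number of planted positive clones (default 0).
#' @param positiveSignal Mean signal of planted positives (default 5e5 RLU).
#' @param positiveCv Coefficient of variation of positive signals
#'   (default 0.1).
#' @param seed RNG seed.
#' @return A data frame with columns `well`, `type` (`"colony"` or
#'   `"background"`) and `rlu`; positives are planted in the first
#'   `positives` colony wells.
#' @examples
#' p <- simulatePlate(positives = 3, seed = 1)
#' thresholdHits(p$rlu, 1e5, wells = p$well)
#' @export
simulatePlate <- function(nColonyWells = 94, nBackgroundWells = 2,
                          backgroundMean = 2758, backgroundSd = 1909,
                          positives = 0, positiveSignal = 5e5,
                          positiveCv = 0.1, seed = NULL) {
  stopifnot(positives <= nColonyWells, positives >= 0)
  if (!is.null(seed)) set.seed(seed)
  n <- nColonyWells + nBackgroundWells
  rlu <- .rtruncnorm0(n, backgroundMean, backgroundSd)
  if (positives > 0) {
    sig <- .rtruncnorm0(positives, positiveSignal,
                        positiveCv * positiveSignal)
    rlu[seq_len(positives)] <- sig
  }
  data.frame(
    well = sprintf("W%02d", seq_len(n)),
    type = c(rep("colony", nColonyWells),
             rep("background", nBackgroundWells)),
    rlu = rlu, stringsAsFactors = FALSE)
}

#' Simulate a competitive-ELISA dose-response table
#'
#' Generates B/B0 % responses from a 4PL curve with multiplicative Gaussian
#' noise at a configured coefficient of variation, plus a block of zero-dose
#' (B0) replicates for the LOD rule. Four replicates per dose and ten B0
#' replicates by default, matching common intra-assay practice.
#'
#' @param doses Non-zero dose grid, pg/assay (default 8 log-spaced doses
#'   spanning 1 to 1e4).
#' @param midpoint,slope,top,bottom Generating 4PL parameters (B/B0 %).
#' @param cv Coefficient of variation of the multiplicative noise
#'   (default 0: noiseless).
#' @param replicates Replicates per non-zero dose (default 4).
#' @param nB0 Zero-dose replicates (default 10).
#' @param b0Sd Standard deviation of the zero-dose responses around `top`
#'   (B/B0 % units; default `cv * top`).
#' @param seed RNG seed.
#' @return A data frame with columns `dose`, `response`, `replicate`.
#' @examples
#' dr <- simulateDoseResponse(midpoint = 706)
#' midpoint(fit4PL(dr$dose, dr$response))  # 706 (noiseless)
#' @export
simulateDoseResponse <- function(doses = 10^seq(0, 4, length.out = 8),
                                 midpoint = 706, slope = 1, top = 100,
                                 bottom = 0, cv = 0, replicates = 4,
                                 nB0 = 10, b0Sd = cv * top, seed = NULL) {
  stopifnot(all(doses > 0), midpoint > 0, top > bottom, cv >= 0)
  if (!is.null(seed)) set.seed(seed)
  d <- rep(doses, each = replicates)
  mu <- bottom + (top - bottom) / (1 + (d / midpoint)^slope)
  resp <- mu * (1 + if (cv > 0) rnorm(length(mu), 0, cv) else 0)
  b0 <- top + if (b0Sd > 0) rnorm(nB0, 0, b0Sd) else numeric(nB0)
  data.frame(
    dose = c(rep(0, nB0), d),
    response = c(b0, resp),
    replicate = c(seq_len(nB0), rep(seq_len(replicates), length(doses))))
}

#' Simulate a Scatchard bound/free table
#'
#' Generates single-site mass-action binding data: for a grid of free
#' tracer concentrations around `1/ka`, the bound concentration is
#' `sites * ka * free / (1 + ka * free)`, with optional multiplicative
#' Gaussian noise on the bound values.
#'
#' @param ka Association constant, M^-1.
#' @param sites Total binding-site concentration, M (default 1e-9).
#' @param nPoints Number of points (default 6).
#' @param span Log10 span of the free-concentration grid centred on `1/ka`
#'   (default 1, i.e. one decade either side).
#' @param cv Coefficient of variation of the noise on bound (default 0).
#' @param seed RNG seed.
#' @return A data frame with columns `bound` and `free` (molar).
#' @examples
#' sc <- simulateScatchard(ka = 3.6e8)
#' scatchardKa(sc$bound, sc$free)$ka  # 3.6e8 (noiseless)
#' @export
simulateScatchard <- function(ka, sites = 1e-9, nPoints = 6, span = 1,
                              cv = 0, seed = NULL) {
  stopifnot(ka > 0, sites > 0, nPoints >= 3)
  if (!is.null(seed)) set.seed(seed)
  free <- 10^seq(log10(1 / ka) - span, log10(1 / ka) + span,
                 length.out = nPoints)
  bound <- sites * ka * free / (1 + ka * free)
  if (cv > 0) bound <- bound * (1 + rnorm(nPoints, 0, cv))
  data.frame(bound = bound, free = free)
}
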