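# Competitive-ELISA and Scatchard arithmetic used to rank affinity-matured
# mutants: 4PL midpoint fitting, LOD by the blank-minus-2SD rule,
# cross-reactivity, assay unit conversions, Scatchard K_a and fold change.

#' Normalise raw bound signals to B/B0 percent
#'
#' Divides each signal by the mean zero-dose (B0) signal after subtracting a
#' constant background, and scales to percent.
#'
#' @param dose Dose vector (0 marks the B0 wells).
#' @param signal Raw bound signal (absorbance or RLU).
#' @param background Constant background to subtract (default 0; the assays
#'   modelled here keep background below 5% of B0).
#' @return Numeric vector of B/B0 percentages.
#' @export
normalizeToB0 <- function(dose, signal, background = 0) {
  stopifnot(length(dose) == length(signal))
  b0 <- signal[dose == 0] - background
  if (length(b0) == 0L) stop("at least one zero-dose (B0) well is required")
  100 * (signal - background) / mean(b0)
}

.fourPL <- function(logDose, top, bottom, slope, logMid) {
  bottom + (top - bottom) / (1 + exp(slope * (logDose - logMid)))
}

#' Fit a four-parameter logistic competitive dose-response curve
#'
#' Least-squares fit of
#' `B/B0 = bottom + (top - bottom) / (1 + (dose/midpoint)^slope)`
#' to the non-zero doses, parameterised on log-dose for conditioning and
#' solved with Levenberg-Marquardt damped least squares (maximum 500
#' iterations, relative tolerance 1e-10). Initialisation is quantile-based:
#' top = max response, bottom = min response, midpoint = dose whose mean
#' response is nearest the half-range, slope = 1. The fit is deterministic
#' given the data.
#'
#' @param dose Dose vector, pg/assay; zero-dose rows are ignored by the fit
#'   (they define B0 and the LOD rule, see [lodDose()]).
#' @param response Response vector, B/B0 % (use [normalizeToB0()] on raw
#'   signals first).
#' @return A [FourPLFit-class]; a fit that failed to converge is returned
#'   with `converged = FALSE` rather than as an error.
#' @examples
#' d <- rep(10^seq(0, 4, length.out = 8), each = 2)
#' r <- 100 / (1 + d / 706)
#' midpoint(fit4PL(d, r))  # 706
#' @export
fit4PL <- function(dose, response) {
  stopifnot(length(dose) == length(response))
  keep <- dose > 0 & is.finite(response)
  d <- dose[keep]
  r <- response[keep]
  if (length(unique(d)) < 4L)
    stop("at least 4 distinct non-zero doses are required for a 4PL fit")
  if (diff(range(r)) < .Machine$double.eps^0.5)
    stop("degenerate data: all responses are equal")
  x <- log(d)
  top0 <- max(r)
  bottom0 <- min(r)
  half <- (top0 + bottom0) / 2
  meanByDose <- tapply(r, x, mean)
  logMid0 <- as.numeric(names(meanByDose))[which.min(abs(meanByDose - half))]
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = list(top = top0, bottom = bottom0, slope = 1, logMid = logMid0),
      fn = function(p) r - .fourPL(x, p$top, p$bottom, p$slope, p$logMid),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-10,
                                           ptol = 1e-10)),
    error = function(e) NULL)
  if (is.null(fit)) {
    # flagged non-convergence: report the initial guess as a degenerate fit
    return(new("FourPLFit", top = top0, bottom = bottom0,
               midpoint = exp(logMid0), slope = 1, converged = FALSE,
               residualSd = NA_real_, nObs = length(r)))
  }
  cf <- unlist(fit$par)
  conv <- fit$info %in% 1:3  # LM convergence codes (ftol/ptol/both)
  # a negative slope means the optimiser flipped orientation; renormalise to
  # the descending-competitive convention (slope > 0)
  slope <- unname(cf["slope"])
  top <- unname(cf["top"])
  bottom <- unname(cf["bottom"])
  if (slope < 0) {
    slope <- -slope
    tmp <- top; top <- bottom; bottom <- tmp
  }
  new("FourPLFit", top = top, bottom = bottom,
      midpoint = exp(unname(cf["logMid"])), slope = slope,
      converged = isTRUE(conv),
      residualSd = sqrt(fit$deviance / max(1, length(r) - 4)),
      nObs = length(r))
}

#' Predict and invert a fitted 4PL curve
#'
#' `predict4PL()` evaluates the fitted curve at given doses; `invert4PL()`
#' returns the dose producing a given response (defined only strictly
#' between the asymptotes).
#'
#' @param fit A [FourPLFit-class].
#' @param dose Dose vector (positive).
#' @param response Response value(s), B/B0 %.
#' @return Numeric vector.
#' @examples
#' d <- rep(10^seq(0, 4, length.out = 8), each = 2)
#' f <- fit4PL(d, 100 / (1 + d / 706))
#' predict4PL(f, 706)   # 50
#' invert4PL(f, 50)     # 706
#' @export
predict4PL <- function(fit, dose) {
  stopifnot(is(fit, "FourPLFit"))
  .fourPL(log(dose), fit@top, fit@bottom, fit@slope, log(fit@midpoint))
}

#' @rdname predict4PL
#' @export
invert4PL <- function(fit, response) {
  stopifnot(is(fit, "FourPLFit"))
  out <- rep(NA_real_, length(response))
  ok <- response > fit@bottom & response < fit@top
  ratio <- (fit@top - fit@bottom) / (response[ok] - fit@bottom) - 1
  out[ok] <- fit@midpoint * ratio^(1 / fit@slope)
  out
}

#' Limit of detection by the blank-minus-2SD rule
#'
#' The LOD is the dose whose fitted bound signal equals two standard
#' deviations below the mean of the zero-dose (B0) replicates, obtained by
#' inverting the fitted 4PL curve at that threshold.
#'
#' @param fit A [FourPLFit-class] fitted on B/B0 % responses.
#' @param b0 Vector of zero-dose replicate responses in the same units
#'   (at least 2).
#' @return A list with `lod` (dose, `NA` when undefined), `threshold`
#'   (mean - 2 SD of `b0`) and `defined` (logical; `FALSE` when the
#'   threshold falls outside the fitted response range).
#' @examples
#' d <- rep(10^seq(-1, 4, length.out = 8), each = 2)
#' f <- fit4PL(d, 100 / (1 + d / 29.9))
#' lodDose(f, b0 = c(97, 99, 100, 101, 103))
#' @export
lodDose <- function(fit, b0) {
  stopifnot(is(fit, "FourPLFit"))
  if (length(b0) < 2L)
    stop("at least 2 zero-dose replicates are required for the LOD rule")
  thr <- mean(b0) - 2 * sd(b0)
  dose <- invert4PL(fit, thr)
  list(lod = dose, threshold = thr, defined = is.finite(dose))
}

#' Cross-reactivity of an analog relative to the analyte
#'
#' The IC50-ratio definition: `100 * midpoint(analyte) / midpoint(analog)`.
#' An analog needing a larger dose for the same displacement cross-reacts
#' less.
#'
#' @param midpointAnalyte,midpointAnalog Positive midpoints (IC50) in the
#'   same dose units.
#' @return Percentage cross-reactivity.
#' @examples
#' crossReactivity(706, 90513)  # ~0.78 %
#' @export
crossReactivity <- function(midpointAnalyte, midpointAnalog) {
  if (any(midpointAnalyte <= 0) || any(midpointAnalog <= 0))
    stop("midpoints must be positive")
  100 * midpointAnalyte / midpointAnalog
}

#' Assay configuration for unit conversions
#'
#' @param totalVolumeUl Final incubation volume per well (default 150).
#' @param standardVolumeUl Volume of the analyte standard added (default 50).
#' @param dilutionFactor Specimen dilution factor for serum-equivalent
#'   results (default 10).
#' @param molarMass Analyte molar mass in g/mol (default 362.46, cortisol).
#' @return A validated list of class `"assayConfig"`.
#' @export
assayConfig <- function(totalVolumeUl = 150, standardVolumeUl = 50,
                        dilutionFactor = 10, molarMass = 362.46) {
  if (totalVolumeUl <= 0 || standardVolumeUl <= 0 || molarMass <= 0 ||
      dilutionFactor <= 0)
    stop("assay volumes, dilution factor and molar mass must be positive")
  if (standardVolumeUl > totalVolumeUl)
    stop("standard volume cannot exceed the total incubation volume")
  structure(list(totalVolumeUl = totalVolumeUl,
                 standardVolumeUl = standardVolumeUl,
                 dilutionFactor = dilutionFactor,
                 molarMass = molarMass), class = "assayConfig")
}

#' Convert a per-assay analyte amount to concentration units
#'
#' A dose of `x` pg/assay means `x` pg in the final incubation volume. Two
#' volume bases coexist deliberately: the in-well concentration uses the
#' total incubation volume, while the serum-equivalent concentration refers
#' the amount back to the standard aliquot and multiplies by the specimen
#' dilution factor.
#'
#' @param amountPg Analyte amount in pg/assay (vectorised).
#' @param config An [assayConfig()].
#' @return A data frame with columns `pgPerAssay`, `pgPerMl` (in-well),
#'   `pmolPerL` (in-well) and `serumNgPerMl` (serum-equivalent).
#' @examples
#' convertUnits(10)     # 66.7 pg/mL, 184 pmol/L in a 150 uL well
#' convertUnits(10.2)   # LOD of ~2 ng/mL serum equivalent at 10x dilution
#' @export
convertUnits <- function(amountPg, config = assayConfig()) {
  stopifnot(inherits(config, "assayConfig"))
  pgPerMl <- amountPg / (config$totalVolumeUl / 1000)
  pmolPerL <- pgPerMl / config$molarMass * 1000
  serumNgPerMl <- amountPg / (config$standardVolumeUl / 1000) *
    config$dilutionFactor / 1000
  data.frame(pgPerAssay = amountPg, pgPerMl = pgPerMl, pmolPerL = pmolPerL,
             serumNgPerMl = serumNgPerMl)
}

#' Scatchard estimate of the equilibrium association constant
#'
#' Ordinary least squares of `bound/free` on `bound`; for single-site
#' binding the slope is `-K_a` and the x-intercept the binding-site
#' concentration.
#'
#' @param bound,free Tracer concentrations in consistent molar units, at
#'   least 3 points, all positive.
#' @return A list with `ka` (M^-1; `NA` when invalid), `valid` (logical;
#'   `FALSE` for a non-negative slope), `slope`, `intercept` and `sites`
#'   (estimated site concentration, `NA` when invalid).
#' @examples
#' f <- 10^seq(-9.5, -7.5, length.out = 6)
#' b <- 1e-9 * 3.6e8 * f / (1 + 3.6e8 * f)
#' scatchardKa(b, f)$ka  # 3.6e8
#' @export
scatchardKa <- function(bound, free) {
  stopifnot(length(bound) == length(free))
  if (length(bound) < 3L)
    stop("Scatchard analysis requires at least 3 points")
  if (any(bound <= 0) || any(free <= 0))
    stop("bound and free concentrations must be positive")
  fit <- lm(I(bound / free) ~ bound)
  slope <- unname(coef(fit)[2])
  intercept <- unname(coef(fit)[1])
  # a slope is only meaningfully negative if it moves bound/free by more
  # than numerical noise across the observed bound range
  span <- abs(slope) * diff(range(bound))
  valid <- is.finite(slope) && slope < 0 &&
    span > 1e-9 * mean(abs(bound / free))
  list(ka = if (valid) -slope else NA_real_,
       valid = valid, slope = slope, intercept = intercept,
       sites = if (valid) intercept / -slope else NA_real_)
}

#' Affinity fold improvement over a reference
#'
#' Ratio of association constants, with the conventional display form
#' rounded to the nearest integer (halves away from zero).
#'
#' @param kaMutant,kaReference Positive association constants (M^-1).
#' @return The ratio, with attribute `display` holding the integer fold.
#' @examples
#' foldImprovement(1.1e10, 3.6e8)   # 30.6, displays as 31-fold
#' foldImprovement(0.62e10, 3.6e8)  # 17.2, displays as 17-fold
#' @export
foldImprovement <- function(kaMutant, kaReference) {
  if (any(kaMutant <= 0) || any(kaReference <= 0))
    stop("association constants must be positive")
  ratio <- kaMutant / kaReference
  structure(ratio, display = .roundHalfAway(ratio))
}

# round half away from zero (base round() rounds half to even)
.roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)
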