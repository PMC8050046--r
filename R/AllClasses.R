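#' @import methods
#' @importFrom stats coef lm pnorm qnorm residuals rnorm runif sd setNames rmultinom
#' @importFrom utils head write.csv
NULL

# One-letter codes for the 20 proteinogenic amino acids; "*" is the internal
# stop token and is never a member of this set.
.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' CodonExpansion: a degenerate codon expanded to concrete triplets
#'
#' Holds the full enumeration of a single IUPAC-degenerate codon: every
#' concrete DNA triplet it denotes and the amino-acid profile obtained by
#' translating each triplet with the standard genetic code. Stop codons are
#' tracked under the distinguished token `"*"`.
#'
#' @slot codon The degenerate codon, three uppercase IUPAC symbols.
#' @slot codons Character vector of concrete triplets over A/C/G/T.
#' @slot residueProfile Named integer vector mapping one-letter amino acid
#'   (plus `"*"` for stop) to the number of concrete codons encoding it.
#'
#' @seealso [expandCodon()]
#' @exportClass CodonExpansion
setClass("CodonExpansion",
  representation(
    codon = "character",
    codons = "character",
    residueProfile = "integer"
  )
)

setValidity("CodonExpansion", function(object) {
  msg <- character()
  if (length(object@codon) != 1L || nchar(object@codon) != 3L)
    msg <- c(msg, "'codon' must be a single 3-character string")
  if (sum(object@residueProfile) != length(object@codons))
    msg <- c(msg, "residue profile multiplicities must sum to the codon count")
  if (anyDuplicated(object@codons))
    msg <- c(msg, "concrete codons must be distinct")
  if (length(msg)) msg else TRUE
})

#' LibrarySpec: an ordered mutagenesis library design
#'
#' Describes a mutagenesis window as an ordered list of position
#' specifications (fixed residue, degenerate substitution set, or a block of
#' inserted randomised codons) plus the concrete 5' and 3' flanking sequences
#' that place the window in its cloning context.
#'
#' Each element of `positions` is a list with fields `label` (integer
#' position label, 1-based), `mode` (`"fixed"`, `"substitution"` or
#' `"insertion_block"`), `residues` (target amino-acid set), `codon` (the
#' assigned degenerate codon, or the randomisation scheme codon for an
#' insertion block) and `insertionLength` (number of inserted randomised
#' codons; 0 unless mode is `"insertion_block"`).
#'
#' @slot name Library identifier.
#' @slot positions List of per-position design entries (see Details).
#' @slot fivePrimeFlank,threePrimeFlank Concrete nucleotide strings.
#'
#' @seealso [librarySpec()], [libraryDiversity()], [assemblePrimer()]
#' @exportClass LibrarySpec
setClass("LibrarySpec",
  representation(
    name = "character",
    positions = "list",
    fivePrimeFlank = "character",
    threePrimeFlank = "character"
  )
)

setValidity("LibrarySpec", function(object) {
  msg <- character()
  labs <- vapply(object@positions, function(p) as.numeric(p$label), numeric(1))
  if (is.unsorted(labs, strictly = TRUE))
    msg <- c(msg, "position labels must be strictly ascending")
  modes <- vapply(object@positions, function(p) p$mode, character(1))
  if (!all(modes %in% c("fixed", "substitution", "insertion_block")))
    msg <- c(msg, "unknown position mode")
  if (sum(modes == "insertion_block") > 1L)
    msg <- c(msg, "at most one insertion block is allowed")
  for (p in object@positions) {
    ex <- tryCatch(expandCodon(p$codon), error = function(e) NULL)
    if (is.null(ex)) {
      msg <- c(msg, sprintf("position %s: invalid codon '%s'", p$label, p$codon))
      next
    }
    res <- codonResidues(ex)
    if (p$mode == "fixed") {
      if (length(p$residues) != 1L || length(ex@codons) != 1L)
        msg <- c(msg, sprintf("position %s: fixed mode needs one residue and a concrete codon", p$label))
      else if (!identical(res, sort(p$residues)))
        msg <- c(msg, sprintf("position %s: codon does not encode the fixed residue", p$label))
    } else if (p$mode == "substitution") {
      if (!setequal(res, p$residues) || stopCount(ex) > 0L)
        msg <- c(msg, sprintf(
          "position %s: substitution codon must encode exactly {%s} with no stops",
          p$label, paste(sort(p$residues), collapse = ",")))
    } else { # insertion_block
      if (is.null(p$insertionLength) || p$insertionLength < 1L || p$insertionLength > 6L)
        msg <- c(msg, sprintf("position %s: insertion length must be in 1..6", p$label))
    }
  }
  flanks <- c(object@fivePrimeFlank, object@threePrimeFlank)
  if (any(grepl("[^ACGT]", flanks)))
    msg <- c(msg, "flanking sequences must be concrete (A/C/G/T only)")
  if (length(msg)) msg else TRUE
})

#' DiversityReport: protein- and DNA-level library diversity
#'
#' @slot proteinDiversity Count of distinct stop-free protein variants.
#' @slot nucleotideDiversity Count of distinct DNA variants.
#' @slot stopFraction Fraction of DNA variants carrying at least one stop
#'   codon.
#'
#' @seealso [libraryDiversity()]
#' @exportClass DiversityReport
setClass("DiversityReport",
  representation(
    proteinDiversity = "numeric",
    nucleotideDiversity = "numeric",
    stopFraction = "numeric"
  )
)

setValidity("DiversityReport", function(object) {
  msg <- character()
  if (object@proteinDiversity > object@nucleotideDiversity)
    msg <- c(msg, "protein diversity cannot exceed nucleotide diversity")
  if (object@stopFraction < 0 || object@stopFraction >= 1)
    msg <- c(msg, "stop fraction must lie in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' CoverageReport: expected screening coverage of a library
#'
#' Summarises how much of a k-variant library a finite random colony pick is
#' expected to observe, under i.i.d. multinomial sampling with the given
#' variant abundances.
#'
#' @slot nDraws Number of colonies sampled.
#' @slot k Number of distinct variants in the library.
#' @slot expectedDistinct Expected number of distinct variants observed.
#' @slot expectedMissing `k - expectedDistinct`, computed in closed form as
#'   the sum of `(1 - w_i)^n` over variants.
#' @slot pFull Probability that all `k` variants are observed.
#' @slot method How `pFull` was computed: `"inclusion-exclusion"` (exact,
#'   small k) or `"poisson"` (independence approximation).
#'
#' @seealso [coverage()]
#' @exportClass CoverageReport
setClass("CoverageReport",
  representation(
    nDraws = "numeric",
    k = "numeric",
    expectedDistinct = "numeric",
    expectedMissing = "numeric",
    pFull = "numeric",
    method = "character"
  )
)

setValidity("CoverageReport", function(object) {
  msg <- character()
  if (object@expectedDistinct > min(object@nDraws, object@k) + 1e-9)
    msg <- c(msg, "expected distinct cannot exceed min(draws, k)")
  if (object@pFull < -1e-12 || object@pFull > 1 + 1e-12)
    msg <- c(msg, "pFull must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' FrameworkSegments: Kabat FR1-FR4 of an antibody variable domain
#'
#' The four framework-region segments of a heavy-chain variable domain under
#' the Kabat delimitation used here: FR1 spans positions 1-30, FR2 14
#' residues, FR3 32 residues and FR4 11 residues, 87 positions in total.
#' Gaps are written `"-"` and count as mismatches in identity calculations.
#'
#' @slot fr1,fr2,fr3,fr4 Amino-acid strings of lengths 30, 14, 32 and 11.
#'
#' @seealso [frameworkSegments()], [percentIdentity()]
#' @exportClass FrameworkSegments
setClass("FrameworkSegments",
  representation(fr1 = "character", fr2 = "character",
                 fr3 = "character", fr4 = "character")
)

.FR_LENGTHS <- c(fr1 = 30L, fr2 = 14L, fr3 = 32L, fr4 = 11L)

setValidity("FrameworkSegments", function(object) {
  msg <- character()
  for (s in names(.FR_LENGTHS)) {
    x <- slot(object, s)
    if (length(x) != 1L || nchar(x) != .FR_LENGTHS[[s]])
      msg <- c(msg, sprintf("%s must be a single string of length %d",
                            s, .FR_LENGTHS[[s]]))
    else if (grepl(sprintf("[^%s-]", paste(.AA20, collapse = "")), x))
      msg <- c(msg, sprintf("%s contains characters outside the amino-acid alphabet", s))
  }
  if (length(msg)) msg else TRUE
})

#' SubgroupProfile: consensus framework of a Kabat subgroup
#'
#' A named framework profile, typically the most-common-amino-acid consensus
#' of a Kabat variable-domain subgroup, against which query frameworks are
#' scored for subgroup assignment.
#'
#' @slot name Subgroup label, e.g. `"II(B)"`.
#' @slot segments A [FrameworkSegments-class] of consensus residues.
#'
#' @seealso [assignSubgroup()]
#' @exportClass SubgroupProfile
setClass("SubgroupProfile",
  representation(name = "character", segments = "FrameworkSegments")
)

#' FrequencyTable: per-position amino-acid frequencies of an alignment
#'
#' @slot freq Numeric matrix, residues x positions; each column sums to 1
#'   over the residues observed at that position (gaps excluded from the
#'   denominator). Columns of all-gap positions are all zero and flagged.
#' @slot nSequences Number of sequences compiled.
#' @slot allGap Logical vector flagging positions with no non-gap residue.
#'
#' @seealso [frequencyTable()], [mostCommon()]
#' @exportClass FrequencyTable
setClass("FrequencyTable",
  representation(freq = "matrix", nSequences = "integer", allGap = "logical")
)

#' FourPLFit: four-parameter logistic fit of a competitive dose-response
#'
#' Parameters of the 4PL model
#' `B/B0 = bottom + (top - bottom) / (1 + (dose / midpoint)^slope)`
#' fitted on log-dose, together with convergence diagnostics.
#'
#' @slot top,bottom Upper and lower response asymptotes (B/B0 %).
#' @slot midpoint Dose giving the half-maximal response (IC50), in the dose
#'   units of the input (pg/assay throughout this package).
#' @slot slope Hill slope (positive for a descending competitive curve as
#'   parameterised here).
#' @slot converged Logical; `FALSE` flags a fit that hit the iteration limit.
#' @slot residualSd Residual standard deviation of the fit.
#' @slot nObs Number of non-zero-dose observations used.
#'
#' @seealso [fit4PL()], [predict4PL()], [invert4PL()]
#' @exportClass FourPLFit
setClass("FourPLFit",
  representation(
    top = "numeric", bottom = "numeric", midpoint = "numeric",
    slope = "numeric", converged = "logical", residualSd = "numeric",
    nObs = "integer"
  )
)

setValidity("FourPLFit", function(object) {
  msg <- character()
  if (object@midpoint <= 0) msg <- c(msg, "midpoint must be positive")
  if (object@top <= object@bottom) msg <- c(msg, "top must exceed bottom")
  if (length(msg)) msg else TRUE
})

# ---- show methods -----------------------------------------------------------

setMethod("show", "CodonExpansion", function(object) {
  cat("CodonExpansion:", object@codon, "->", length(object@codons),
      "concrete codon(s)\n")
  prof <- object@residueProfile
  cat("  residues:", paste(sprintf("%s:%d", names(prof), prof), collapse = " "),
      "\n")
})

setMethod("show", "LibrarySpec", function(object) {
  modes <- vapply(object@positions, function(p) p$mode, character(1))
  cat(sprintf("LibrarySpec '%s': %d positions (%d fixed, %d substitution, %d insertion block)\n",
              object@name, length(object@positions),
              sum(modes == "fixed"), sum(modes == "substitution"),
              sum(modes == "insertion_block")))
  cat(sprintf("  flanks: 5'[%d nt] / 3'[%d nt]\n",
              nchar(object@fivePrimeFlank), nchar(object@threePrimeFlank)))
})

setMethod("show", "DiversityReport", function(object) {
  cat(sprintf("DiversityReport: %s protein variants (stop-free), %s DNA variants, stop fraction %.4g\n",
              format(object@proteinDiversity, big.mark = ","),
              format(object@nucleotideDiversity, big.mark = ","),
              object@stopFraction))
})

setMethod("show", "CoverageReport", function(object) {
  cat(sprintf("CoverageReport: n = %g draws over k = %g variants\n",
              object@nDraws, object@k))
  cat(sprintf("  expected distinct %.2f, expected missing %.2f, P(full) = %.4g [%s]\n",
              object@expectedDistinct, object@expectedMissing,
              object@pFull, object@method))
})

setMethod("show", "FrameworkSegments", function(object) {
  cat("FrameworkSegments (Kabat, 87 positions):\n")
  cat("  FR1:", object@fr1, "\n  FR2:", object@fr2, "\n")
  cat("  FR3:", object@fr3, "\n  FR4:", object@fr4, "\n")
})

setMethod("show", "SubgroupProfile", function(object) {
  cat("SubgroupProfile:", object@name, "\n")
  show(object@segments)
})

setMethod("show", "FrequencyTable", function(object) {
  cat(sprintf("FrequencyTable: %d positions compiled from %d sequence(s)\n",
              ncol(object@freq), object@nSequences))
})

setMethod("show", "FourPLFit", function(object) {
  cat(sprintf("FourPLFit: midpoint %.4g, slope %.3g, top %.3g, bottom %.3g%s\n",
              object@midpoint, object@slope, object@top, object@bottom,
              if (object@converged) "" else " [NOT CONVERGED]"))
})

# ---- accessors --------------------------------------------------------------

#' Accessors for AbLibKit result objects
#'
#' Small generic accessors for the S4 containers: `codonResidues()` returns
#' the sorted set of amino acids a codon expansion encodes (stops excluded),
#' `stopCount()` its stop-codon multiplicity, `residueProfile()` the full
#' profile, `proteinDiversity()`, `nucleotideDiversity()` and
#' `stopFraction()` the fields of a [DiversityReport-class], and `midpoint()`
#' the IC50 of a [FourPLFit-class].
#'
#' @param x An AbLibKit S4 object.
#' @return The requested field; see each method.
#' @name accessors
#' @aliases codonResidues stopCount residueProfile proteinDiversity
#'   nucleotideDiversity stopFraction midpoint
#' @examples
#' ex <- expandCodon("NNS")
#' codonResidues(ex)
#' stopCount(ex)
NULL

#' @rdname accessors
#' @export
setGeneric("codonResidues", function(x) standardGeneric("codonResidues"))
#' @rdname accessors
#' @export
setMethod("codonResidues", "CodonExpansion", function(x) {
  sort(setdiff(names(x@residueProfile), "*"))
})

#' @rdname accessors
#' @export
setGeneric("stopCount", function(x) standardGeneric("stopCount"))
#' @rdname accessors
#' @export
setMethod("stopCount", "CodonExpansion", function(x) {
  n <- x@residueProfile["*"]
  if (is.na(n)) 0L else unname(n)
})

#' @rdname accessors
#' @export
setGeneric("residueProfile", function(x) standardGeneric("residueProfile"))
#' @rdname accessors
#' @export
setMethod("residueProfile", "CodonExpansion", function(x) x@residueProfile)

#' @rdname accessors
#' @export
setGeneric("proteinDiversity", function(x) standardGeneric("proteinDiversity"))
#' @rdname accessors
#' @export
setMethod("proteinDiversity", "DiversityReport", function(x) x@proteinDiversity)

#' @rdname accessors
#' @export
setGeneric("nucleotideDiversity", function(x) standardGeneric("nucleotideDiversity"))
#' @rdname accessors
#' @export
setMethod("nucleotideDiversity", "DiversityReport", function(x) x@nucleotideDiversity)

#' @rdname accessors
#' @export
setGeneric("stopFraction", function(x) standardGeneric("stopFraction"))
#' @rdname accessors
#' @export
setMethod("stopFraction", "DiversityReport", function(x) x@stopFraction)

#' @rdname accessors
#' @export
setGeneric("midpoint", function(x) standardGeneric("midpoint"))
#' @rdname accessors
#' @export
setMethod("midpoint", "FourPLFit", function(x) x@midpoint)

#' Tabular view of a codon expansion
#'
#' @param x A [CodonExpansion-class].
#' @param row.names,optional Ignored; present for the generic signature.
#' @param ... Ignored.
#' @return A data frame with columns `codon` (concrete triplet) and
#'   `amino_acid`, one row per concrete codon, suitable for CSV export.
#' @export
as.data.frame.CodonExpansion <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
  data.frame(codon = x@codons,
             amino_acid = unname(.geneticCode()[x@codons]),
             stringsAsFactors = FALSE)
}
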