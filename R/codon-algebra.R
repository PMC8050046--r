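# Exact algebra of IUPAC-degenerate codons. The genetic code and the IUPAC
# ambiguity map come from Biostrings; everything on top (expansion,
# profiles, set comparisons) is enumerated exactly, never sampled.

.geneticCode <- function() Biostrings::GENETIC_CODE

.iupacBases <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- strsplit(Biostrings::IUPAC_CODE_MAP, "")
    cache
  }
})

#' Normalise and validate a degenerate codon string
#'
#' Uppercases, converts RNA `U` to `T`, and checks that the result is exactly
#' three valid IUPAC nucleotide symbols.
#'
#' @param codon A single string.
#' @return The normalised three-letter codon.
#' @examples
#' checkCodon("nns")
#' checkCodon("aug")
#' @export
checkCodon <- function(codon) {
  if (!is.character(codon) || length(codon) != 1L || is.na(codon))
    stop("codon must be a single string")
  codon <- chartr("u", "t", tolower(codon))
  codon <- toupper(codon)
  if (nchar(codon) != 3L)
    stop(sprintf("codon must have exactly 3 symbols, got %d ('%s')",
                 nchar(codon), codon))
  syms <- strsplit(codon, "")[[1]]
  bad <- !(syms %in% names(.iupacBases()))
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("invalid IUPAC symbol '%s' at position %d of codon '%s'",
                 syms[i], i, codon))
  }
  codon
}

#' Expand a degenerate codon to its concrete triplets and residue profile
#'
#' Enumerates every concrete DNA triplet denoted by a three-symbol IUPAC
#' codon and translates each through the standard genetic code (translation
#' table 1). The expansion size is always the product of the per-symbol base
#' counts. Stops appear in the profile under the token `"*"`.
#'
#' @param codon A degenerate codon string (IUPAC symbols; `U` and lowercase
#'   accepted and normalised).
#' @return A [CodonExpansion-class].
#' @examples
#' expandCodon("VWA")            # the 6-residue position-5 menu E,I,K,L,Q,V
#' codonResidues(expandCodon("NNS"))
#' stopCount(expandCodon("NNS")) # NNS admits exactly one stop, TAG
#' @export
expandCodon <- local({
  cache <- new.env(parent = emptyenv())
  function(codon) {
    codon <- checkCodon(codon)
    if (!is.null(hit <- cache[[codon]])) return(hit)
    syms <- strsplit(codon, "")[[1]]
    bases <- .iupacBases()
    b1 <- bases[[syms[1]]]
    b2 <- bases[[syms[2]]]
    b3 <- bases[[syms[3]]]
    # nested rep over alphabetical base sets yields sorted triplets directly
    triplets <- paste0(rep(b1, each = length(b2) * length(b3)),
                       rep(rep(b2, each = length(b3)), length(b1)),
                       rep(b3, length(b1) * length(b2)))
    aa <- unname(.geneticCode()[triplets])
    counts <- rle(sort(aa))
    out <- new("CodonExpansion",
               codon = codon,
               codons = triplets,
               residueProfile = setNames(counts$lengths, counts$values))
    cache[[codon]] <- out
    out
  }
})

#' Does a degenerate codon encode exactly a target residue set?
#'
#' Tests whether the residue set of `codon` equals `target` with zero stop
#' codons, and reports how it deviates when it does not.
#'
#' @param codon A degenerate codon string.
#' @param target Non-empty character vector of one-letter amino-acid codes
#'   (subset of the 20 proteinogenic residues).
#' @return A list with elements `exact` (logical), `extras` (residues encoded
#'   but not targeted), `missing` (targets not encoded) and `stopCount`
#'   (multiplicity of stop codons in the expansion).
#' @examples
#' encodesExactly("VWA", c("E", "I", "K", "L", "Q", "V"))
#' encodesExactly("NNS", "A")
#' @export
encodesExactly <- function(codon, target) {
  target <- unique(toupper(target))
  if (length(target) == 0L)
    stop("target residue set must be non-empty")
  if (!all(target %in% .AA20))
    stop(sprintf("target contains non-amino-acid codes: %s",
                 paste(setdiff(target, .AA20), collapse = ", ")))
  ex <- expandCodon(codon)
  res <- codonResidues(ex)
  extras <- sort(setdiff(res, target))
  missing <- sort(setdiff(target, res))
  stops <- stopCount(ex)
  list(exact = length(extras) == 0L && length(missing) == 0L && stops == 0L,
       extras = extras, missing = missing, stopCount = stops)
}

# All 15^3 degenerate codons, in alphabetical symbol order.
.allDegenerateCodons <- function() {
  s <- sort(names(.iupacBases()))
  g <- expand.grid(s, s, s, stringsAsFactors = FALSE)
  sort(paste0(g[[1]], g[[2]], g[[3]]))
}
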