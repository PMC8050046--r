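# Construction, parsing, enumeration and diversity accounting of
# substitution (library A style) and NNS-insertion (library B style)
# mutagenesis libraries.

#' Built-in primer sequences of the reference V_H-FR1 designs
#'
#' `libraryAPrimer()` returns the 91-mer degenerate oligonucleotide encoding
#' the substitution library over V_H positions 1-10 (eight degenerate
#' positions, 1,536 theoretical members). `libraryBPrimer(n)` returns the
#' insertion-library oligonucleotide carrying `n` NNS codons inserted
#' between positions 6 and 7 of the fixed QVQLQQ context.
#'
#' Both oligonucleotides are written 5' to 3' as synthesised and read in the
#' sense frame of V_H. [primerReverseComplement()] gives the antisense
#' strand explicitly.
#'
#' @param n Number of inserted NNS codons (0-6; 0 gives the insertion-free
#'   context).
#' @return A nucleotide string.
#' @examples
#' nchar(libraryAPrimer())  # 91
#' libraryBPrimer(2)
#' @export
libraryAPrimer <- function() {
  paste0("ATTGTTATTACTCGCGGCCCAACCGGCCATGGCC",
         "SAGRTCMAACTGVWASAGYCTGGGSSTGRA",
         "CTTGTGAAGCCTGGGGCTTCAGTGAAA")
}

#' @rdname libraryAPrimer
#' @export
libraryBPrimer <- function(n) {
  stopifnot(length(n) == 1L, n >= 0, n <= 6, n == round(n))
  paste0("ATTGTTATTACTCGCGGCCCAACCGGCCATGGCC",
         "CAGGTCCAACTGCAGCAG",
         strrep("NNS", n),
         "CCTGGGGCTGAACTTGTGAAGC")
}

#' Reverse-complement a (possibly degenerate) primer
#'
#' @param primer A nucleotide string in IUPAC symbols.
#' @return The reverse complement, degeneracy-aware (via Biostrings).
#' @examples
#' primerReverseComplement("CCATGGCCNNS")
#' @export
primerReverseComplement <- function(primer) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(primer)))
}

# ---- position constructors --------------------------------------------------

.position <- function(label, mode, residues, codon, insertionLength = 0L) {
  list(label = as.integer(label), mode = mode,
       residues = sort(unique(toupper(residues))),
       codon = checkCodon(codon),
       insertionLength = as.integer(insertionLength))
}

#' Construct per-position design entries for a LibrarySpec
#'
#' `fixedPosition()` pins a position to one residue with a concrete codon;
#' `substitutionPosition()` assigns a degenerate codon whose residue set is
#' the substitution menu (derived from the codon; must be stop-free);
#' `insertionBlock()` inserts `n` copies of a randomisation scheme codon
#' (NNS by default) after the given position label.
#'
#' @param label Integer position label (Kabat numbering, 1-based).
#' @param codon Codon string; concrete for `fixedPosition`, degenerate for
#'   `substitutionPosition`, the per-codon randomisation scheme for
#'   `insertionBlock`.
#' @param n Number of inserted randomised codons (1-6).
#' @return A position entry list for [librarySpec()].
#' @examples
#' substitutionPosition(5, "VWA")   # menu E,I,K,L,Q,V
#' insertionBlock(6, 3)             # (NNS)3 after position 6
#' @export
fixedPosition <- function(label, codon) {
  ex <- expandCodon(codon)
  if (length(ex@codons) != 1L)
    stop(sprintf("fixed position %s requires a concrete codon, got '%s'",
                 label, codon))
  aa <- codonResidues(ex)
  if (length(aa) == 0L)
    stop(sprintf("fixed position %s codon '%s' is a stop codon", label, codon))
  .position(label, "fixed", aa, codon)
}

#' @rdname fixedPosition
#' @export
substitutionPosition <- function(label, codon) {
  ex <- expandCodon(codon)
  if (stopCount(ex) > 0L)
    stop(sprintf("substitution codon '%s' at position %s admits %d stop codon(s)",
                 codon, label, stopCount(ex)))
  .position(label, "substitution", codonResidues(ex), codon)
}

#' @rdname fixedPosition
#' @export
insertionBlock <- function(label, n, codon = "NNS") {
  ex <- expandCodon(codon)
  .position(label, "insertion_block", codonResidues(ex), codon, n)
}

#' Construct a mutagenesis library specification
#'
#' @param name Library identifier.
#' @param positions List of position entries from [fixedPosition()],
#'   [substitutionPosition()] and [insertionBlock()], in ascending label
#'   order.
#' @param fivePrimeFlank,threePrimeFlank Concrete flanking nucleotide
#'   strings (cloning context); may be empty.
#' @return A validated [LibrarySpec-class].
#' @examples
#' sp <- librarySpec("toy", list(
#'   substitutionPosition(1, "SAG"),
#'   fixedPosition(2, "CTG")))
#' libraryDiversity(sp)
#' @export
librarySpec <- function(name, positions, fivePrimeFlank = "",
                        threePrimeFlank = "") {
  new("LibrarySpec", name = name, positions = positions,
      fivePrimeFlank = toupper(fivePrimeFlank),
      threePrimeFlank = toupper(threePrimeFlank))
}

# ---- parsing ----------------------------------------------------------------

#' Read a degenerate codon window out of a primer
#'
#' Reads `nCodons` codons in frame starting at a 0-based nucleotide offset
#' and expands each one. Constant codons are reported as fixed singletons.
#'
#' @param primer Nucleotide string in IUPAC symbols.
#' @param windowStart 0-based nucleotide offset of the first codon.
#' @param nCodons Number of codons to read.
#' @return A data frame with one row per codon: `index`, `codon`,
#'   `nResidues` (distinct amino acids encoded), `residues`
#'   (comma-separated), `nCodons` (expansion size), `stops` and `fixed`.
#' @examples
#' parseDegenerateWindow(libraryAPrimer(), 34, 10)
#' @export
parseDegenerateWindow <- function(primer, windowStart, nCodons) {
  stopifnot(length(primer) == 1L, windowStart >= 0, nCodons >= 1)
  primer <- toupper(chartr("Uu", "TT", primer))
  syms <- strsplit(primer, "")[[1]]
  bad <- !(syms %in% names(.iupacBases()))
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("invalid IUPAC symbol '%s' at position %d of primer",
                 syms[i], i))
  }
  end <- windowStart + 3L * nCodons
  if (end > nchar(primer))
    stop(sprintf("window [%d, %d) overruns primer of length %d",
                 windowStart, end, nchar(primer)))
  starts <- windowStart + 3L * (seq_len(nCodons) - 1L) + 1L
  codons <- substring(primer, starts, starts + 2L)
  rows <- lapply(seq_along(codons), function(i) {
    ex <- expandCodon(codons[i])
    res <- codonResidues(ex)
    data.frame(index = i, codon = codons[i], nResidues = length(res),
               residues = paste(res, collapse = ","),
               nCodons = length(ex@codons), stops = stopCount(ex),
               fixed = length(ex@codons) == 1L,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Build a LibrarySpec by parsing a primer window
#'
#' Splits a primer into a 5' flank, an in-frame design window and a 3'
#' flank, classifying each window codon as fixed or substitution. The flanks
#' must be concrete; the window carries all the degeneracy.
#'
#' @inheritParams parseDegenerateWindow
#' @param name Library identifier.
#' @param firstLabel Label of the first window position (default 1).
#' @return A [LibrarySpec-class] that reassembles to `primer` via
#'   [assemblePrimer()].
#' @examples
#' sp <- specFromPrimer("libA", libraryAPrimer(), 34, 10)
#' proteinDiversity(libraryDiversity(sp))  # 1536
#' @export
specFromPrimer <- function(name, primer, windowStart, nCodons,
                           firstLabel = 1L) {
  parsed <- parseDegenerateWindow(primer, windowStart, nCodons)
  primer <- toupper(chartr("Uu", "TT", primer))
  positions <- lapply(seq_len(nrow(parsed)), function(i) {
    lab <- firstLabel + i - 1L
    if (parsed$fixed[i]) fixedPosition(lab, parsed$codon[i])
    else substitutionPosition(lab, parsed$codon[i])
  })
  librarySpec(name, positions,
              fivePrimeFlank = substr(primer, 1L, windowStart),
              threePrimeFlank = substr(primer, windowStart + 3L * nCodons + 1L,
                                       nchar(primer)))
}

#' Reference library specifications of the V_H-FR1 mutagenesis designs
#'
#' `libraryASpec()` parses the built-in substitution primer into the
#' ten-position design (positions 1-10, eight substitution menus, L4 and G8
#' fixed). `libraryBSpec(n)` builds the insertion design: the fixed QVQLQQ
#' context (positions 1-6) with `n` NNS codons inserted after position 6.
#'
#' @param n Number of inserted NNS codons (1-6).
#' @return A [LibrarySpec-class].
#' @examples
#' libraryASpec()
#' proteinDiversity(libraryDiversity(libraryBSpec(3)))  # 20^3
#' @export
libraryASpec <- function() {
  specFromPrimer("libA", libraryAPrimer(), 34L, 10L)
}

#' @rdname libraryASpec
#' @export
libraryBSpec <- function(n) {
  stopifnot(n >= 1, n <= 6)
  context <- c("CAG", "GTC", "CAA", "CTG", "CAG", "CAG")
  positions <- c(
    lapply(1:6, function(i) fixedPosition(i, context[i])),
    list(insertionBlock(6L + 1L, n))  # block sits after position 6
  )
  # the block's label only orders it after the context; use 7 as next slot
  librarySpec(sprintf("libB-n%d", n), positions,
              fivePrimeFlank = "ATTGTTATTACTCGCGGCCCAACCGGCCATGGCC",
              threePrimeFlank = "CCTGGGGCTGAACTTGTGAAGC")
}

#' Pooled sublibrary specifications of the insertion design
#'
#' The insertion design is transformed as three pools: `slB-1-3` (one-, two-
#' and three-residue insertions), `slB-4/5` and `slB-6`. Diversities of a
#' pool add across its members.
#'
#' @param which One of `"slB-1-3"`, `"slB-4/5"`, `"slB-6"`.
#' @return A list of [LibrarySpec-class] objects.
#' @examples
#' proteinDiversity(libraryDiversity(libraryBPool("slB-1-3")))  # 8420
#' @export
libraryBPool <- function(which = c("slB-1-3", "slB-4/5", "slB-6")) {
  which <- match.arg(which)
  ns <- switch(which, "slB-1-3" = 1:3, "slB-4/5" = 4:5, "slB-6" = 6L)
  lapply(ns, libraryBSpec)
}

# ---- reverse codon design ---------------------------------------------------

#' Design the minimal degenerate codon for a target residue set
#'
#' Searches all 15^3 = 3,375 degenerate codons for the best encoding of a
#' target amino-acid set, under the lexicographic objective: (1) covers
#' every target residue, (2) fewest off-target residues, (3) fewest stop
#' codons, (4) fewest concrete codons, (5) alphabetically first codon.
#' An exact design is one whose residue set equals the target with zero
#' stops.
#'
#' @param target Non-empty character vector of one-letter amino-acid codes.
#' @return A list with `codon` (the winning degenerate codon), `exact`
#'   (logical), `extras`, `missing` (always empty: full cover is enforced),
#'   `stopCount` and `nCodons` (expansion size of the winner).
#' @examples
#' designCodonForSet(c("E", "I", "K", "L", "Q", "V"))  # exact, e.g. VWA
#' designCodonForSet("M")                              # ATG
#' designCodonForSet(c("D", "E", "H"))                 # no exact cover exists
#' @export
designCodonForSet <- function(target) {
  target <- unique(toupper(target))
  if (length(target) == 0L)
    stop("target residue set must be non-empty")
  if (!all(target %in% .AA20))
    stop(sprintf("target contains non-amino-acid codes: %s",
                 paste(setdiff(target, .AA20), collapse = ", ")))
  tab <- .degenerateCodonTable()
  targetMask <- sum(2^(match(target, .AA20) - 1))
  covers <- bitwAnd(tab$mask, targetMask) == targetMask
  if (!any(covers)) stop("internal: no covering codon found")  # NNN always covers
  nExtra <- tab$nResidues[covers] - length(target)
  ord <- order(nExtra, tab$stops[covers], tab$nCodons[covers],
               tab$codon[covers], method = "radix")[1]
  idx <- which(covers)[ord]
  ex <- expandCodon(tab$codon[idx])
  extras <- sort(setdiff(codonResidues(ex), target))
  list(codon = tab$codon[idx],
       exact = length(extras) == 0L && tab$stops[idx] == 0L,
       extras = extras, missing = character(0),
       stopCount = tab$stops[idx], nCodons = tab$nCodons[idx])
}

# residue-set bitmasks, stop counts and expansion sizes for all 15^3
# degenerate codons; built once per session
.degenerateCodonTable <- local({
  tab <- NULL
  function() {
    if (!is.null(tab)) return(tab)
    bases <- .iupacBases()
    baseIdx <- lapply(bases, function(b) match(b, c("A", "C", "G", "T")) - 1L)
    gc <- .geneticCode()
    concrete <- paste0(rep(c("A", "C", "G", "T"), each = 16),
                       rep(rep(c("A", "C", "G", "T"), each = 4), 4),
                       rep(c("A", "C", "G", "T"), 16))
    aaIdx <- match(unname(gc[concrete]), c(.AA20, "*"))  # 21 = stop
    aaBit <- ifelse(aaIdx <= 20, 2^(aaIdx - 1), 0)
    isStop <- aaIdx == 21L
    syms <- sort(names(bases))
    # symbol x base membership, then codon x concrete-triplet membership by
    # row/column indexing (3,375 x 64 logical)
    M <- t(vapply(syms, function(s)
      c("A", "C", "G", "T") %in% bases[[s]], logical(4)))
    g <- expand.grid(c3 = seq_along(syms), c2 = seq_along(syms),
                     c1 = seq_along(syms))
    codons <- paste0(syms[g$c1], syms[g$c2], syms[g$c3])
    b1 <- rep(1:4, each = 16)
    b2 <- rep(rep(1:4, each = 4), 4)
    b3 <- rep(1:4, 16)
    member <- M[g$c1, b1] & M[g$c2, b2] & M[g$c3, b3]
    present <- vapply(1:20, function(k)
      as.vector(member %*% (aaIdx == k)) > 0, logical(nrow(member)))
    ord <- order(codons, method = "radix")
    tab <<- data.frame(
      codon = codons[ord],
      mask = as.integer(present %*% 2^(0:19))[ord],
      stops = as.integer(member %*% isStop)[ord],
      nCodons = rowSums(member)[ord],
      nResidues = rowSums(present)[ord],
      stringsAsFactors = FALSE)
    tab
  }
})

# ---- diversity --------------------------------------------------------------

.specCounts <- function(spec) {
  # per-position counts needed for diversity arithmetic
  rows <- lapply(spec@positions, function(p) {
    ex <- expandCodon(p$codon)
    nAA <- length(codonResidues(ex))
    nDNA <- length(ex@codons)
    nStopFree <- nDNA - stopCount(ex)
    reps <- if (p$mode == "insertion_block") p$insertionLength else 1L
    data.frame(nAA = nAA, nDNA = nDNA, nStopFree = nStopFree, reps = reps)
  })
  do.call(rbind, rows)
}

#' Theoretical diversity of a mutagenesis library
#'
#' Computes the protein-level diversity (distinct stop-free protein
#' variants: the product over positions of the residue-set size, with an
#' insertion block of `n` NNS codons contributing `20^n`), the
#' nucleotide-level diversity (product of codon-expansion sizes) and the
#' exact fraction of DNA variants carrying at least one stop codon. For a
#' list of specs (a pooled library) the diversities add and the stop
#' fraction is the pooled DNA-weighted fraction.
#'
#' @param spec A [LibrarySpec-class] or a list of them (a pool).
#' @return A [DiversityReport-class].
#' @examples
#' libraryDiversity(libraryASpec())              # 1,536 members, no stops
#' libraryDiversity(libraryBPool("slB-1-3"))     # 8,420 members
#' @export
libraryDiversity <- function(spec) {
  if (is.list(spec)) {
    reps <- lapply(spec, libraryDiversity)
    prot <- sum(vapply(reps, proteinDiversity, numeric(1)))
    dna <- sum(vapply(reps, nucleotideDiversity, numeric(1)))
    stopDNA <- sum(vapply(reps, function(r)
      stopFraction(r) * nucleotideDiversity(r), numeric(1)))
    return(new("DiversityReport", proteinDiversity = prot,
               nucleotideDiversity = dna, stopFraction = stopDNA / dna))
  }
  stopifnot(is(spec, "LibrarySpec"))
  ct <- .specCounts(spec)
  prot <- prod(ct$nAA^ct$reps)
  dna <- prod(ct$nDNA^ct$reps)
  stopFree <- prod(ct$nStopFree^ct$reps)
  new("DiversityReport", proteinDiversity = prot, nucleotideDiversity = dna,
      stopFraction = 1 - stopFree / dna)
}

#' Stop-free fraction of an NNS randomisation
#'
#' Fraction of DNA variants free of stop codons when `n` NNS codons are
#' randomised: `(31/32)^n` (NNS admits exactly one stop, TAG, among its 32
#' codons).
#'
#' @param n Number of NNS codons (non-negative integer).
#' @return A probability.
#' @examples
#' functionalFraction(0)  # 1
#' functionalFraction(6)  # ~0.827
#' @export
functionalFraction <- function(n) {
  if (any(n < 0) || any(n != round(n)))
    stop("n must be a non-negative integer")
  (31 / 32)^n
}

# ---- enumeration ------------------------------------------------------------

.positionResidues <- function(spec) {
  # ordered list of residue menus, insertion blocks unrolled
  out <- list()
  for (p in spec@positions) {
    menu <- sort(codonResidues(expandCodon(p$codon)))
    reps <- if (p$mode == "insertion_block") p$insertionLength else 1L
    out <- c(out, rep(list(menu), reps))
  }
  out
}

#' Enumerate the distinct stop-free protein variants of a library
#'
#' Yields every distinct stop-free protein variant of a spec exactly once,
#' in lexicographic order. Enumeration refuses to run when the theoretical
#' diversity exceeds `cap` (default 1e6), reporting the diversity instead.
#'
#' @param spec A [LibrarySpec-class].
#' @param cap Maximum number of variants to enumerate.
#' @param withMultiplicity If `TRUE`, return a named numeric vector of DNA
#'   codon multiplicities per variant instead of a bare character vector.
#' @return Character vector of protein variants (or named multiplicity
#'   vector).
#' @examples
#' v <- enumerateProteinVariants(libraryASpec())
#' length(v)                  # 1536
#' "QVQLQQPGAE" %in% v        # the parental decamer is a member
#' @export
enumerateProteinVariants <- function(spec, cap = 1e6,
                                     withMultiplicity = FALSE) {
  stopifnot(is(spec, "LibrarySpec"))
  div <- proteinDiversity(libraryDiversity(spec))
  if (div > cap)
    stop(sprintf(
      "library diversity %s exceeds the enumeration cap %s; raise 'cap' to force",
      format(div, big.mark = ","), format(cap, big.mark = ",")))
  menus <- .positionResidues(spec)
  g <- expand.grid(rev(menus), stringsAsFactors = FALSE)
  variants <- do.call(paste0, rev(g))
  variants <- sort(unique(variants))
  if (!withMultiplicity) return(variants)
  mult <- variantMultiplicities(spec)
  mult[variants]
}

#' Per-variant codon multiplicities of a library
#'
#' For each distinct stop-free protein variant, the number of DNA variants
#' encoding it (the product over positions of the per-residue codon
#' multiplicity). Dividing by the nucleotide diversity gives the expected
#' abundance of each variant in an unbiased transformation.
#'
#' @inheritParams enumerateProteinVariants
#' @return Named numeric vector, names are variants, values multiplicities.
#' @examples
#' w <- variantMultiplicities(libraryBSpec(1))
#' w["QVQLQQL"] / sum(w)  # abundance of the single-L insertion variant
#' @export
variantMultiplicities <- function(spec, cap = 1e6) {
  stopifnot(is(spec, "LibrarySpec"))
  div <- proteinDiversity(libraryDiversity(spec))
  if (div > cap)
    stop(sprintf("library diversity %s exceeds the cap %s",
                 format(div, big.mark = ","), format(cap, big.mark = ",")))
  menus <- list()
  for (p in spec@positions) {
    ex <- expandCodon(p$codon)
    prof <- ex@residueProfile
    prof <- prof[names(prof) != "*"]
    reps <- if (p$mode == "insertion_block") p$insertionLength else 1L
    menus <- c(menus, rep(list(prof), reps))
  }
  acc <- setNames(1, "")
  for (m in menus) {
    vals <- as.vector(outer(as.numeric(m), acc))
    nms <- as.vector(outer(names(m), names(acc), function(a, b) paste0(b, a)))
    acc <- setNames(vals, nms)
  }
  acc[sort(names(acc))]
}

# ---- assembly ---------------------------------------------------------------

#' Assemble the oligonucleotide realising a library specification
#'
#' Concatenates the 5' flank, the per-position codons in order (an insertion
#' block contributes its scheme codon repeated `insertionLength` times) and
#' the 3' flank. Round-trips with [specFromPrimer()].
#'
#' @param spec A [LibrarySpec-class].
#' @return A nucleotide string (IUPAC symbols at degenerate positions).
#' @examples
#' identical(assemblePrimer(libraryASpec()), libraryAPrimer())  # TRUE
#' @export
assemblePrimer <- function(spec) {
  stopifnot(is(spec, "LibrarySpec"))
  window <- vapply(spec@positions, function(p) {
    reps <- if (p$mode == "insertion_block") p$insertionLength else 1L
    strrep(p$codon, reps)
  }, character(1))
  paste0(spec@fivePrimeFlank, paste(window, collapse = ""),
         spec@threePrimeFlank)
}

# ---- JSON / FASTA IO --------------------------------------------------------

#' Read and write library specifications as JSON
#'
#' The JSON layout mirrors the spec structure: `name`, `five_prime_flank`,
#' `three_prime_flank` and a `positions` array of objects with `label`,
#' `mode`, `codon` and (for insertion blocks) `insertion_length`.
#'
#' @param path File path.
#' @param spec A [LibrarySpec-class].
#' @return `readLibrarySpec` returns a [LibrarySpec-class];
#'   `writeLibrarySpec` returns `path` invisibly.
#' @export
readLibrarySpec <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  positions <- lapply(j$positions, function(p) {
    switch(p$mode,
      fixed = fixedPosition(p$label, p$codon),
      substitution = substitutionPosition(p$label, p$codon),
      insertion_block = insertionBlock(p$label, p$insertion_length,
                                       codon = p$codon),
      stop(sprintf("unknown mode '%s'", p$mode)))
  })
  librarySpec(j$name, positions,
              fivePrimeFlank = j$five_prime_flank %||% "",
              threePrimeFlank = j$three_prime_flank %||% "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname readLibrarySpec
#' @export
writeLibrarySpec <- function(spec, path) {
  stopifnot(is(spec, "LibrarySpec"))
  positions <- lapply(spec@positions, function(p) {
    out <- list(label = p$label, mode = p$mode, codon = p$codon,
                residues = paste(p$residues, collapse = ""))
    if (p$mode == "insertion_block") out$insertion_length <- p$insertionLength
    out
  })
  jsonlite::write_json(
    list(name = spec@name, five_prime_flank = spec@fivePrimeFlank,
         three_prime_flank = spec@threePrimeFlank, positions = positions),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Write enumerated protein variants to FASTA
#'
#' @param variants Character vector of protein variants (as produced by
#'   [enumerateProteinVariants()]).
#' @param path Output FASTA path.
#' @param prefix Record-name prefix; records are named `prefix_000001` etc.
#' @return `path`, invisibly.
#' @export
writeVariantsFasta <- function(variants, path, prefix = "variant") {
  aa <- Biostrings::AAStringSet(variants)
  names(aa) <- sprintf("%s_%06d", prefix, seq_along(variants))
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}
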