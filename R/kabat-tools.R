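# Framework-region analytics on Kabat-delimited antibody variable-domain
# sequences: identity over the 87 framework positions, subgroup assignment
# by maximum identity, and per-position residue frequency tables.

#' Construct Kabat framework segments
#'
#' @param fr1,fr2,fr3,fr4 Amino-acid strings of lengths 30, 14, 32 and 11
#'   (87 positions in total). Gaps are written `"-"`.
#' @return A validated [FrameworkSegments-class].
#' @examples
#' fs <- frameworkSegments(strrep("Q", 30), strrep("A", 14),
#'                         strrep("G", 32), strrep("S", 11))
#' percentIdentity(fs, fs)
#' @export
frameworkSegments <- function(fr1, fr2, fr3, fr4) {
  new("FrameworkSegments", fr1 = toupper(fr1), fr2 = toupper(fr2),
      fr3 = toupper(fr3), fr4 = toupper(fr4))
}

#' @rdname subgroupProfile
#' @export
subgroupProfile <- function(name, segments) {
  new("SubgroupProfile", name = name, segments = segments)
}

#' SubgroupProfile constructor
#'
#' Builds a named subgroup consensus profile from framework segments; see
#' [SubgroupProfile-class].
#'
#' @param name Subgroup label.
#' @param segments A [FrameworkSegments-class].
#' @return A [SubgroupProfile-class].
#' @name subgroupProfile
NULL

.frChars <- function(x) {
  unlist(strsplit(c(x@fr1, x@fr2, x@fr3, x@fr4), ""), use.names = FALSE)
}

#' Framework identity over the 87 Kabat positions
#'
#' Percentage of identical residues over the concatenated FR1-FR4 segments.
#' The denominator is always 87; gap positions count as mismatches (a gap
#' never matches anything, including another gap on the same side only when
#' both are gaps — two aligned gaps are still counted as a mismatch, since
#' a gap carries no residue identity).
#'
#' @param query,reference [FrameworkSegments-class] objects.
#' @param digits Decimals for the returned display value (default 1, the
#'   conventional reporting precision); the exact fraction is attached as
#'   attribute `"exact"`.
#' @return Percentage identity (numeric scalar, rounded to `digits`), with
#'   attributes `exact` (unrounded) and `matches` (integer match count).
#' @examples
#' a <- frameworkSegments(strrep("Q", 30), strrep("A", 14),
#'                        strrep("G", 32), strrep("S", 11))
#' percentIdentity(a, a)  # 100
#' @export
percentIdentity <- function(query, reference, digits = 1) {
  stopifnot(is(query, "FrameworkSegments"), is(reference, "FrameworkSegments"))
  q <- .frChars(query)
  r <- .frChars(reference)
  matches <- sum(q == r & q != "-")
  exact <- 100 * matches / 87
  structure(round(exact, digits), exact = exact, matches = matches)
}

#' Assign a framework to its closest Kabat subgroup
#'
#' Scores a query framework against each subgroup consensus profile with
#' [percentIdentity()] and returns the best, with deterministic ties broken
#' by alphabetical profile name (ties are flagged).
#'
#' @param query A [FrameworkSegments-class].
#' @param profiles Non-empty list of [SubgroupProfile-class] objects.
#' @return A list with `best` (the winning [SubgroupProfile-class]),
#'   `identity` (its percent identity), `tie` (logical) and `ranking` (data
#'   frame of all profiles sorted by descending identity, then name).
#' @export
assignSubgroup <- function(query, profiles) {
  if (length(profiles) == 0L)
    stop("at least one subgroup profile is required")
  nm <- vapply(profiles, function(p) p@name, character(1))
  id <- vapply(profiles, function(p)
    as.numeric(attr(percentIdentity(query, p@segments), "exact")), numeric(1))
  ord <- order(-id, nm)
  ranking <- data.frame(subgroup = nm[ord], identity = round(id[ord], 1),
                        stringsAsFactors = FALSE, row.names = NULL)
  top <- ord[1]
  tie <- sum(abs(id - id[top]) < 1e-12) > 1L
  list(best = profiles[[top]], identity = round(id[top], 1), tie = tie,
       ranking = ranking)
}

#' Per-position amino-acid frequencies of an aligned sequence set
#'
#' Column-wise residue counts of an equal-length alignment, normalised by
#' the number of non-gap observations at each position. All-gap columns get
#' an all-zero distribution and are flagged.
#'
#' @param sequences Character vector of aligned amino-acid strings (equal
#'   lengths, gaps as `"-"`).
#' @return A [FrequencyTable-class].
#' @examples
#' ft <- frequencyTable(c("QVQL", "QIQL", "QVQL", "QVKL"))
#' ft@freq["V", 2]  # 0.75
#' mostCommon(ft)
#' @export
frequencyTable <- function(sequences) {
  if (length(sequences) == 0L) stop("at least one sequence is required")
  sequences <- toupper(sequences)
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L)
    stop("sequences must all have the same aligned length")
  m <- do.call(rbind, strsplit(sequences, ""))
  bad <- setdiff(unique(as.vector(m)), c(.AA20, "-"))
  if (length(bad))
    stop(sprintf("unknown residue code(s): %s", paste(bad, collapse = ", ")))
  freq <- matrix(0, nrow = length(.AA20), ncol = ncol(m),
                 dimnames = list(.AA20, seq_len(ncol(m))))
  allGap <- logical(ncol(m))
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    col <- col[col != "-"]
    if (length(col) == 0L) {
      allGap[j] <- TRUE
      next
    }
    tab <- table(factor(col, levels = .AA20))
    freq[, j] <- as.numeric(tab) / length(col)
  }
  new("FrequencyTable", freq = freq, nSequences = length(sequences),
      allGap = allGap)
}

#' Most common residue per position
#'
#' Modal residue of each column of a [FrequencyTable-class]; ties are broken
#' alphabetically and flagged in the `tie` attribute. All-gap positions
#' yield `NA`.
#'
#' @param table A [FrequencyTable-class].
#' @return Character vector of modal residues (with `NA` for all-gap
#'   positions) carrying attributes `frequency` and `tie`.
#' @export
mostCommon <- function(table) {
  stopifnot(is(table, "FrequencyTable"))
  f <- table@freq
  res <- character(ncol(f))
  frq <- numeric(ncol(f))
  tie <- logical(ncol(f))
  for (j in seq_len(ncol(f))) {
    if (table@allGap[j]) {
      res[j] <- NA_character_
      frq[j] <- NA_real_
      next
    }
    mx <- max(f[, j])
    winners <- rownames(f)[abs(f[, j] - mx) < 1e-12]
    res[j] <- sort(winners)[1]  # alphabetical tie-break
    frq[j] <- mx
    tie[j] <- length(winners) > 1L
  }
  structure(res, frequency = frq, tie = tie)
}

#' Read an aligned amino-acid FASTA
#'
#' Thin wrapper over [Biostrings::readAAStringSet()] returning a named
#' character vector ready for [frequencyTable()].
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
readAlignedFasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  setNames(as.character(aa), names(aa))
}

#' Export a frequency table as CSV
#'
#' Long-format CSV with columns `position`, `residue`, `frequency`,
#' listing only residues observed at each position.
#'
#' @param table A [FrequencyTable-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeFrequencyCsv <- function(table, path) {
  stopifnot(is(table, "FrequencyTable"))
  f <- table@freq
  rows <- do.call(rbind, lapply(seq_len(ncol(f)), function(j) {
    keep <- f[, j] > 0
    if (!any(keep)) return(NULL)
    data.frame(position = j, residue = rownames(f)[keep],
               frequency = f[keep, j], stringsAsFactors = FALSE)
  }))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
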