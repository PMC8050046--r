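# Independent brute-force oracles, self-contained (own IUPAC map, standard
# genetic code taken straight from Biostrings' published table) so they do
# not share code paths with the package internals they check.

oracleIupac <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

oracleGeneticCode <- Biostrings::GENETIC_CODE

# every concrete triplet of a degenerate codon, by plain nested expansion
oracleExpand <- function(codon) {
  s <- strsplit(toupper(codon), "")[[1]]
  out <- character(0)
  for (a in oracleIupac[[s[1]]])
    for (b in oracleIupac[[s[2]]])
      for (c in oracleIupac[[s[3]]])
        out <- c(out, paste0(a, b, c))
  sort(out)
}

oracleResidues <- function(codon) {
  aa <- oracleGeneticCode[oracleExpand(codon)]
  sort(unique(aa[aa != "*"]))
}

# framework segments with exactly nMismatch mismatches against a base
# profile, mutated at deterministic FR3 positions
mutatedSegments <- function(base, nMismatch) {
  chars <- strsplit(base@fr3, "")[[1]]
  for (i in seq_len(nMismatch)) {
    chars[i] <- if (chars[i] == "A") "G" else "A"
  }
  frameworkSegments(base@fr1, base@fr2, paste(chars, collapse = ""), base@fr4)
}

referenceFramework <- function() {
  frameworkSegments(
    "QVQLQQPGAELVKPGASVKLSCKASGYTFT",
    "WVKQRPGQGLEWIG",
    "KATLTADKSSSTAYMQLSSLTSEDSAVYYCAR",
    "WGQGTTVTVSS")
}
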