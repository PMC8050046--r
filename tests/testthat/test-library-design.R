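test_that("the built-in substitution primer parses to the designed residue menus", {
  parsed <- parseDegenerateWindow(libraryAPrimer(), 34, 10)
  expect_identical(parsed$nResidues, c(2L, 2L, 2L, 1L, 6L, 2L, 2L, 1L, 4L, 2L))
  expect_identical(parsed$codon,
                   c("SAG", "RTC", "MAA", "CTG", "VWA", "SAG", "YCT", "GGG",
                     "SST", "GRA"))
  expect_true(all(parsed$stops == 0L))
  expect_identical(parsed$residues[5], "E,I,K,L,Q,V")
})

test_that("the insertion-free context parses to six fixed codons QVQLQQ", {
  parsed <- parseDegenerateWindow(libraryBPrimer(0), 34, 6)
  expect_true(all(parsed$fixed))
  expect_identical(parsed$residues, c("Q", "V", "Q", "L", "Q", "Q"))
})

test_that("an all-concrete window yields only fixed singletons", {
  parsed <- parseDegenerateWindow("ATGGCTTAA", 0, 3)
  expect_true(all(parsed$fixed))
  expect_identical(parsed$nResidues, c(1L, 1L, 0L))  # TAA is a stop
})

test_that("window parsing rejects overruns and bad symbols", {
  expect_error(parseDegenerateWindow("ATGGCT", 0, 3), "overruns")
  expect_error(parseDegenerateWindow("ATXGCT", 0, 2), "invalid IUPAC")
})

test_that("reverse codon design finds exact stop-free covers and minimal near-covers", {
  d <- designCodonForSet(c("E", "I", "K", "L", "Q", "V"))
  expect_true(d$exact)
  expect_identical(d$stopCount, 0L)
  expect_setequal(oracleResidues(d$codon), c("E", "I", "K", "L", "Q", "V"))

  expect_identical(designCodonForSet("M")$codon, "ATG")

  # oracle: no degenerate codon has residue set exactly {D, E, H}
  exactExists <- FALSE
  for (a in names(oracleIupac)) for (b in names(oracleIupac))
    for (c in names(oracleIupac)) {
      if (setequal(oracleResidues(paste0(a, b, c)), c("D", "E", "H"))) {
        exactExists <- TRUE
      }
    }
  expect_false(exactExists)

  d2 <- designCodonForSet(c("D", "E", "H"))
  expect_false(d2$exact)
  expect_identical(d2$extras, "Q")          # Q is unavoidable
  expect_identical(d2$stopCount, 0L)
  expect_true(all(c("D", "E", "H") %in% oracleResidues(d2$codon)))
  expect_error(designCodonForSet(character(0)), "non-empty")
})

test_that("diversity reproduces the designed library sizes", {
  dv <- libraryDiversity(libraryASpec())
  expect_equal(proteinDiversity(dv), 1536)
  expect_equal(nucleotideDiversity(dv), 1536)
  expect_equal(stopFraction(dv), 0)

  expect_equal(proteinDiversity(libraryDiversity(libraryBPool("slB-1-3"))),
               8420)
  expect_equal(proteinDiversity(libraryDiversity(libraryBPool("slB-4/5"))),
               3360000)
  b6 <- libraryDiversity(libraryBPool("slB-6"))
  expect_equal(proteinDiversity(b6), 6.4e7)
  expect_equal(stopFraction(b6), 1 - (31 / 32)^6)
})

test_that("enumeration agrees with the diversity count and contains known members", {
  v <- enumerateProteinVariants(libraryASpec())
  expect_length(v, 1536)
  expect_identical(anyDuplicated(v), 0L)
  expect_true(all(nchar(v) == 10))
  expect_true(all(c("QVQLQQPGAE", "EIQLKQSGPE", "EIQLEQSGRE") %in% v))
  expect_true(all(substr(v, 1, 1) %in% c("E", "Q")))
  expect_true(all(substr(v, 2, 2) %in% c("I", "V")))
  expect_true(all(substr(v, 3, 3) %in% c("K", "Q")))
  expect_true(all(substr(v, 4, 4) == "L"))
  expect_false(is.unsorted(v))

  for (n in 1:3) {
    sp <- libraryBSpec(n)
    expect_length(enumerateProteinVariants(sp),
                  proteinDiversity(libraryDiversity(sp)))
  }
  expect_error(enumerateProteinVariants(libraryBSpec(6)), "exceeds")
})

test_that("variant multiplicities sum to the stop-free DNA diversity", {
  for (n in 1:2) {
    sp <- libraryBSpec(n)
    w <- variantMultiplicities(sp)
    expect_equal(sum(w), 31^n)  # stop-free DNA variants of (NNS)^n
    expect_length(w, 20^n)
  }
  # one codon per residue at every position -> all multiplicities 1
  wA <- variantMultiplicities(libraryASpec())
  expect_true(all(wA == 1))
})

test_that("assemble and parse are mutually inverse on the printed primers", {
  spA <- libraryASpec()
  expect_identical(assemblePrimer(spA), libraryAPrimer())
  reparsed <- specFromPrimer("libA", assemblePrimer(spA), 34, 10)
  expect_identical(assemblePrimer(reparsed), libraryAPrimer())

  for (n in c(1L, 3L, 6L)) {
    expect_identical(assemblePrimer(libraryBSpec(n)), libraryBPrimer(n))
  }

  bare <- librarySpec("bare", list(substitutionPosition(1, "SAG")))
  expect_identical(assemblePrimer(bare), "SAG")
})

test_that("library specs survive a JSON round trip", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLibrarySpec(libraryBSpec(2), path)
  back <- readLibrarySpec(path)
  expect_identical(assemblePrimer(back), libraryBPrimer(2))
  path2 <- withr::local_tempfile(fileext = ".json")
  writeLibrarySpec(libraryASpec(), path2)
  expect_identical(assemblePrimer(readLibrarySpec(path2)), libraryAPrimer())
})

test_that("spec validation rejects inconsistent designs", {
  expect_error(substitutionPosition(1, "NNS"), "stop codon")
  expect_error(fixedPosition(1, "RTC"), "concrete codon")
  expect_error(librarySpec("bad", list(substitutionPosition(2, "SAG"),
                                       substitutionPosition(1, "RTC"))),
               "ascending")
  expect_error(librarySpec("bad", list(insertionBlock(1, 2),
                                       insertionBlock(2, 3))),
               "insertion block")
  expect_error(librarySpec("bad", list(fixedPosition(1, "ATG")),
                           fivePrimeFlank = "ANT"), "concrete")
})

test_that("enumerated variants export as FASTA and read back", {
  path <- withr::local_tempfile(fileext = ".fasta")
  v <- enumerateProteinVariants(libraryBSpec(1))
  writeVariantsFasta(v, path)
  back <- readAlignedFasta(path)
  expect_identical(unname(back), v)
})
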