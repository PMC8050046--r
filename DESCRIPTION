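Package: AbLibKit
Title: Design and Evaluation of Degenerate-Codon Antibody Mutagenesis Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for designing and evaluating site-directed mutagenesis
    libraries of antibody fragments built from degenerate oligonucleotides.
    Provides an exact algebra of IUPAC-degenerate codons (expansion,
    translation, amino-acid profiles, reverse design of minimal codons for
    target residue sets), construction and diversity accounting of
    substitution and NNS-insertion libraries, coupon-collector coverage
    statistics for colony screening campaigns, Kabat framework-region
    frequency and subgroup-identity analytics, and the competitive-ELISA
    (four-parameter logistic midpoint, limit of detection, cross-reactivity,
    unit conversion) and Scatchard affinity arithmetic used to rank
    affinity-matured mutants. Seeded synthetic-data generators emulate plate
    readouts, dose-response curves and saturation-binding data so that every
    analysis path can be exercised without instrument files.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
biocViews: Software, SequenceMatching, Proteomics, ImmunoOncology
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
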