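---
title: "Designed mutagenesis libraries: codon algebra, screening coverage and binding arithmetic"
author: "AbLibKit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designed mutagenesis libraries: codon algebra, screening coverage and binding arithmetic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(AbLibKit)
```

# The problem

In vitro affinity maturation of antibody fragments replaces panning-based
selection of error-prone PCR libraries with small, *designed* libraries whose
every member is known in advance. The designs modelled here target the
N-terminal stretch of the heavy-chain framework region 1 (V~H~-FR1, Kabat
positions 1–30) of a hapten-binding scFv:

* a **substitution library** in which eight of the first ten V~H~ positions
  carry a degenerate codon encoding a small menu of residues (the menus are
  chosen by shuffling the most-common amino acids of the Kabat subgroups at
  each position), and
* an **insertion library** in which 1–6 NNS codons are inserted between
  positions 6 and 7, each NNS admitting all 20 amino acids plus the single
  TAG stop.

Everything the package computes flows from four questions a library designer
must answer: *what does a degenerate codon encode*, *how many members does a
design have*, *how many colonies must be screened to see them all*, and *how
do the recovered mutants rank* (midpoint, LOD, cross-reactivity, Scatchard
K~a~).

# Codon algebra

A degenerate codon is three IUPAC symbols; its expansion is the Cartesian
product of the per-symbol base sets, translated through the standard genetic
code (translation table 1 — the designs are expressed in *E. coli* from mouse
V genes, so no alternative tables are offered). The expansion size is exactly
the product of the per-symbol base counts, which the test suite checks
against a brute-force oracle over random codons.

```{r}
expandCodon("VWA")    # the six-residue menu at position 5
residueProfile(expandCodon("NNS"))
```

Stops are carried as a distinguished `"*"` token and never counted as amino
acids. RNA `U` and lowercase input are normalised; invalid symbols are
rejected with the offending character and position named.

`designCodonForSet()` inverts the expansion: it searches all 15³ = 3,375
degenerate codons for the best encoding of a target residue set under a
lexicographic objective — full cover first, then fewest off-target residues,
fewest stops, fewest concrete codons, alphabetical tie-break. The search is
backed by a bitmask table of all 3,375 residue sets built once per session,
so it costs milliseconds. Not every set has an exact cover:

```{r}
designCodonForSet(c("D", "E", "H"))  # Q is unavoidable
```

# Library specifications and diversity

A `LibrarySpec` is an ordered list of positions (fixed, substitution, or one
insertion block) plus concrete flanks. The two reference designs ship as
`libraryASpec()` (parsed from the built-in 91-mer degenerate primer) and
`libraryBSpec(n)`; `assemblePrimer()` and `specFromPrimer()` are mutual
inverses, byte-exact on the built-in primers.

Protein diversity counts **stop-free** protein variants only: the insertion
arithmetic (20 + 400 + 8,000 = 8,420 for the pooled 1–3-residue insertions)
treats each NNS as 20 residues and ignores TAG-containing members.
Stop-containing DNA variants are quantified separately as `stopFraction`
(1 − (31/32)ⁿ for *n* NNS codons), because they dilute a transformed library
without contributing members. Pooled sublibraries are modelled as lists of
specs whose diversities add, with equimolar pooling assumed — the protocol
mixes ligation products without stated ratios, so no other weighting is
defensible.

```{r}
libraryDiversity(libraryASpec())
libraryDiversity(libraryBPool("slB-1-3"))
```

`enumerateProteinVariants()` materialises the members in lexicographic order
and refuses above a cap (default 10⁶) so that a (NNS)₆ design (6.4 × 10⁷
members) cannot be enumerated by accident; the cap is overridable.
`variantMultiplicities()` returns per-variant codon multiplicities, the
abundance model implied by an unbiased transformation of the degenerate DNA.

# Screening coverage

Colony picking is modelled as i.i.d. multinomial sampling: picks are random
colonies from plates, and clonal growth bias is deliberately not modelled (a
documented limitation — nothing in the screening protocol quantifies it).
Under that model the expected number of unobserved variants after `n` picks
is the closed form Σᵢ (1 − wᵢ)ⁿ, exact for any weights. For the probability
of *full* coverage the package uses exact inclusion–exclusion for k ≤ 20
variants and the Poissonized independence approximation above that. The
subset-sum enumeration doubles in size per variant, and beyond ~20 variants
the alternating sum both costs too much and loses digits to cancellation,
while the Poisson approximation is already accurate in that regime; the
report records which method produced its `pFull`. A seeded multinomial
Monte-Carlo (`coverageMonteCarlo()`) cross-checks the closed forms in the
test suite at 10⁴ replicates.

```{r}
coverage(4700, k = 1536)
```

Note the honest answer embedded in that report: screening 4,700 colonies
over 1,536 equally-abundant members is *expected* to miss about 72 of them —
"might cover all the members" is optimistic under i.i.d. sampling, and
`drawsForFullCoverage(0.95, k = 1536)` puts 95%-confident full coverage near
16,000 picks (coupon-collector scale k·ln k plus tail).

Hit bookkeeping uses strict inequality at the threshold (`> 100,000 RLU`)
with deterministic descending-signal ordering, ties broken by well index.

# Kabat framework analytics

The module consumes pre-delimited framework segments — FR1/FR2/FR3/FR4 of
30/14/32/11 residues, 87 positions in total. Full Kabat numbering of raw
sequences (insertion codes like 52a) is a large, separate concern and is out
of scope; the analytics operate on Kabat-numbered data as given. Identity is
always computed over the fixed 87-position denominator, with gaps counting
as mismatches, so that 4 mismatches report 83/87 = 95.4%. Subgroup
assignment is the arg-max of identity over consensus profiles with
alphabetical tie-breaks (flagged); frequency tables normalise per column
over non-gap observations and `mostCommon()` extracts the modal residue —
the most-common-amino-acid logic used to choose substitution menus.

# Binding characterization

Competitive-ELISA curves are fitted with the four-parameter logistic
`B/B0 = bottom + (top − bottom) / (1 + (dose/midpoint)^slope)`,
parameterised on log-dose for conditioning and solved by Levenberg–Marquardt
damped least squares (maximum 500 iterations, relative tolerance 10⁻¹⁰,
quantile-based initialisation: top = max response, bottom = min, midpoint =
dose nearest the half-range, slope = 1). The optimiser is called directly on
the residual function rather than through a model-object wrapper, because
zero-residual (noiseless) data — the package's own recovery tests — make
model-matrix construction degenerate even though the optimum is clean. A fit
that stalls is returned flagged `converged = FALSE`, never silently. Top and
bottom are free parameters: the assays keep background below 5% of B0, and
constraining bottom to zero would bias midpoints when they do not.

The LOD rule is mean(B0) − 2·SD(B0), inverted through the fitted curve;
it is undefined (flagged) when the threshold falls outside the asymptotes,
which is also the correct degenerate answer for zero-variance blanks.
Cross-reactivity is the IC50 ratio `100 × midpoint(analyte) /
midpoint(analog)`.

Unit conversion keeps two volume bases on purpose, because assay reporting
uses both: the in-well concentration refers the pg/assay amount to the
150 µL final incubation (10.0 pg/assay → 66.7 pg/mL → 184 pmol/L at
362.46 g/mol), while the serum-equivalent concentration refers it to the
50 µL standard aliquot times the ten-fold specimen dilution (10.2 pg/assay
→ ≈ 2 ng/mL serum).

Scatchard analysis regresses bound/free on bound; K~a~ = −slope for
single-site binding, with a non-negative (or numerically flat) slope flagged
invalid rather than returned. Tracer depletion corrections are not applied —
the simple linear form is the method being reproduced. Fold improvement is
the K~a~ ratio, displayed rounded half-away-from-zero (1.1 × 10¹⁰ / 3.6 × 10⁸
→ 30.6 → "31-fold"). Both candidate parent midpoints give the same display
fold (706/29.4 = 24.0, 706/29.9 = 23.6 → 24), so the ambiguity is moot at
display precision.

# Synthetic data generators

The generators exist so every analysis path can be exercised without
instrument files, and they emulate the *structure* of the real campaigns:

* `simulatePlate()` — 94 colony wells + 2 background wells per plate,
  background drawn from a normal truncated at zero (reported background SDs
  are of the order of the mean, so an untruncated normal would produce
  negative luminescence; the truncation is a modelling choice, not a claim
  about the instrument), with planted high-signal positives.
* `simulateDoseResponse()` — 4PL responses with multiplicative Gaussian
  noise at a configured CV, 4 replicates per dose and 10 zero-dose
  replicates by default.
* `simulateScatchard()` — single-site mass-action bound/free points on a
  log grid spanning a decade either side of 1/K~a~ at a 10⁻⁹ M site
  concentration.

All are pure functions of their arguments and seed. What passing tests on
these fixtures show is that the *arithmetic* is right — recovery of
generating parameters, exact diversity counts, closed-form/Monte-Carlo
agreement. What they cannot show is robustness to the features real data
have and the generators do not: clonal growth bias and plate-to-plate
background drift in screening, heteroscedastic and correlated ELISA errors,
tracer depletion in the binding assay.

# Problem sizes and numerical choices

The test suite runs its stochastic checks at deliberately modest sizes —
Monte-Carlo coverage at 10⁴ replicates for k up to 1,536, parameter-recovery
ensembles of 40 seeded replicates — which are the sizes at which the
standard errors are already far below the tolerances being asserted.
Enumeration-based checks stop at 10⁵ variants; beyond that the closed-form
diversity is the only practical route, which is exactly why it exists.
Display rounding is one decimal for percentages and pg/assay values and
nearest integer for folds; all internal arithmetic is double precision with
exact values retained (identity fractions carry their exact value as an
attribute).

# Known limitations

* Coverage assumes i.i.d. picks; real campaigns have plate effects.
* The insertion-pool abundance model assumes equimolar sublibrary pooling.
* Framework analytics require pre-aligned, pre-delimited segments; no
  numbering algorithm, and no Chothia/IMGT delimitation variants.
* The 4PL fit reports but does not model heteroscedasticity.
* Scatchard estimation ignores tracer depletion.
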