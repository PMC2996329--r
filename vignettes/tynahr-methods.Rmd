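---
title: "Methods: repeat homology profiling and clone-assay outcome estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: repeat homology profiling and clone-assay outcome estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tynahr)
```

## The problem

Dispersed repeat families — in budding yeast, the Ty1/Ty2 LTR
retrotransposons (~5.9 kb full length, ~50 full-length copies) and their
~330 bp solo LTRs (~300 copies) — provide homologous substrates at
non-allelic positions. A double-strand break (DSB) near such repeats can be
repaired by non-allelic homologous recombination (NAHR), producing
deletions, isochromosomes, chromosome rings and translocations. Two
quantitative questions drive the analyses in this package:

1. **Which repeat pairs are competent NAHR partners?** Recombination needs a
   minimal efficient processing segment (MEPS) of uninterrupted identity,
   roughly 250 bp in yeast. This is a question about *pairwise homology
   structure*, not just average identity: two 95%-identical sequences can
   share either many short perfect blocks or a few long ones, with very
   different recombination potential.
2. **How often does each repair outcome actually occur?** A nonselective
   clone assay phenotypes every post-DSB clone for three heterozygous
   markers, classifies cut clones into genetic classes (I: repair retaining
   both arms, II: repair losing the distal marker, III: chromosome loss),
   and sizes a random subset of repair clones by pulsed-field gel
   electrophoresis to identify the rearrangement type. Turning those counts
   into outcome frequencies with honest uncertainties is the estimator half
   of the package.

## Homology metrics

For every unordered element pair the package computes three complementary
metrics (`pairwise_matrix()`):

* **Overall identity (%)** — optimal global (Needleman–Wunsch) affine-gap
  alignment with gap open 10, gap extension 0.5;
  identity = 100 × (identical columns) / (all alignment columns, gaps
  included). The global substitution scores are not part of the published
  parameterization; the defaults (+5/−4, the standard DNA full matrix of the
  classic global aligners) are explicit in `alignment_params()` and
  configurable. A `denominator = "shorter"` variant exists for sensitivity
  analysis.
* **Longest block of 100% identity (nt)** — the package's reference
  semantics is the *exact* longest common substring by dynamic programming
  (`longest_perfect_block()`, Rcpp core): an exact-match run is by
  definition the longest possible contiguous block of matching nucleotides.
  The historical route — scanning the aligned columns of local alignment
  hits for the longest match run — is provided as `block_from_hits()`; it is
  provably ≤ the exact value and equals it whenever the best local alignment
  covers the longest shared block (tests assert both). `N` never matches
  anything, including another `N`.
* **Local identity (bit score)** — Smith–Waterman local alignment under
  BLAST-style scoring (match +1, mismatch −3, affine gaps costing 1 + L),
  rescaled to bits with the Karlin–Altschul formula
  `(λS − ln K)/ln 2`. Inputs are a few kb, so an exhaustive DP replaces
  seeded heuristics. The default constants (λ = 1.374, K = 0.711) are the
  ungapped values for +1/−3 and approximate a gapped search's statistics;
  because rescaling by positive constants never changes an ordering, donor
  rankings are identical under raw scores (tested), which are constant-free.

**Strand handling.** The published analysis does not state whether
oppositely oriented elements were reverse complemented before comparison,
yet an oppositely oriented element ranks highly in the published donor
lists, implying orientation-insensitive comparison. The default is therefore
`strand_mode = "best_of_both"` (compare forward and reverse-complement,
keep the larger value and record which won); `forward_only` is available.

**Determinism.** Arguments to the global aligner are ordered canonically
before alignment, so every metric is exactly symmetric; catalogs sort
elements by (chromosome, start, id); rankings break ties lexicographically
by donor id. Reruns are bit-identical.

## MEPS binning and summaries

Block lengths are binned into half-open 250 bp intervals,
`bin = floor(length/250)`, so 249 falls in bin 0 and 250 in bin 1; the MEPS
fraction counts pairs with block **≥ 250** (inclusive, matching the
at-or-above convention of the source analysis). Because the threshold is a
bin boundary, recomputing the fraction from the binned heat-map table gives
the same count (tested). Family identity statistics default to the
*population* SD (the convention behind the published mean ± SD identity
values is unstated; the choice is switchable). Donor rankings restrict
candidates by family compatibility: full-length recipients rank against the
other full-length elements, LTR recipients against the other LTRs.

## The outcome estimator

The pipeline order is fixed and order matters (a test asserts that
normalize-then-subtract disagrees on inputs whose raw percentages do not sum
to 100):

1. **Raw class percentages.** For induced cultures the denominator is the
   number of *cut* (HygS) clones — the published worked example divides
   85.7% by the HygS count, although the prose says "out of the total number
   of clones scored"; the worked example wins and a `denominator` switch
   preserves the literal reading. For uninduced cultures the package divides
   by all scored clones: background events are rare, and dividing them by
   the tiny uninduced HygS count would make the subtraction in step 2
   meaningless. The rare fourth phenotype class (< 1% of clones) is excluded
   before any percentage is formed.
2. **Background subtraction.** Uninduced percentages are subtracted
   element-wise; cultures with > 50% HygS clones before induction are
   rejected outright. Negative differences (sampling noise) clamp to 0 with
   a warning — the source is silent here, and a negative class frequency has
   no interpretation.
3. **Normalization.** Class I + II + III is rescaled to 100%.
4. **Plug weighting.** frequency(type) = class% × (plugs of type / plugs in
   class), summed over the classes in which the type is eligible (an
   explicit `(class, type)` row in the plug survey, even with count 0,
   declares eligibility — purebred allelic repair legitimately feeds from
   both classes). Class III is reported directly as chromosome loss. A type
   estimated at 0 while its class has nonzero percentage is reported as a
   bound: value 0, flag set, and the assigned-count upper bound
   class% × 1/n attached. Summaries count bounds as 0, which is the only
   convention that reproduces the published copy-number sums.
5. **Uncertainty.** The weighted binomial SEM: initial = √(pq/n) with
   p = plugs of type / plugs in class and n = plugs in class; final =
   initial × class%. Edge rules, all on the "assign count 1" principle:
   if *all* plugs are the type, recompute with n−1 of n (assume the next
   plug would not be the type); if *no* plug is the type, with 1 of n
   (assume it would be; upper bound); a zero-percent class weights the SEM
   to 0 (flagged); with no plugs at all the formula degenerates and 0 is
   reported, flagged as a bound. Cross-class outcomes add their per-class
   final SEMs. Chromosome loss uses SD/√n across replicate inductions
   (sample SD; convention unstated in the source, documented here).

This machinery reproduces, from reconstructed integer counts, every
frequency *and* every SEM cell of the purebred wild-type row at one-decimal
precision, including the cross-class allelic SEM and the zero-count "other"
SEM (see `test-outcome_estimator.R`).

**What the SEM is and is not.** The method deliberately uses the smallest
available n (the plug counts) "to be most stringent". When the plug fraction
is interior (0 < p < 1), the plug-sampling term dominates the estimator's
true sampling variance and the bespoke SEM tracks the empirical SD of
estimates within a factor of 1.5 (tested by simulation). At the degenerate
all-of-class edge (e.g. 18 of 18 class-I plugs are deletions) the plug
fraction contributes no variance at all and the assigned-count SEM is
deliberately conservative — simulations show mean SEM ≥ empirical SD there,
and the tests assert exactly that rather than pretending the calibration
band applies.

## Derived summaries

* `bdr_total()`: internal deletions + isochromosomes + rings +
  translocations — all rearrangements initiated from break-distal repeat
  recipients — rounded to integer percent (76% hybrid vs 17% purebred for a
  DSB in unique DNA).
* `categorize_copy_number()`: *change* = inter-Ty deletion + translocation +
  ring + isochromosome + other + loss; *no change* = intra-Ty deletion + Ty
  gene conversion + allelic. Bounds count 0. This reproduces the published
  97% (DSB in unique DNA, hybrid) vs 19% (DSB inside the Ty cluster,
  hybrid) contrast.

## The synthetic-data generator: its world and its limits

`evolve_family()` draws one random ancestor and mutates each copy
independently: substitutions are uniform over the three alternative bases
(no transition/transversion bias — none is specified by the system being
emulated), sites are chosen uniformly or, in clustered mode, confined to
cluster windows drawn once per family so that copies stay identical between
windows. Clustering preserves the expected substitution count, so
uniform-vs-clustered comparisons isolate block-length structure at matched
overall identity — the package's testable version of the observation that
clustered mismatches leave long recombinogenic stretches. Defaults (5.9 kb
ancestor, 50 copies, d = 0.02 per copy) put pairwise identity near the
mid-90s observed within the real full-length family; under independent
mutation the expected pairwise identity is `(1−d)² + d²/3`
(`expected_pairwise_identity()`), which the generator matches by Monte
Carlo. Optional indels (geometric lengths) exercise the gapped-alignment
paths.

What the generator does **not** emulate: insertion-site preferences,
recombination between family members, selection, GC-content structure, or
the real family's phylogeny (star topology only). A green test therefore
establishes correctness of the *pipeline arithmetic and algorithms* on data
with known truth — not that the biological catalog has any particular
property.

`simulate_clone_assay()` draws induced clones multinomially from a truth
vector over outcome types, maps outcomes to genetic classes (hybrid
convention by default: deletions/gene conversion → class I; isochromosome,
ring, translocation, other and allelic → class II; loss → class III — the
hybrid allelic product changes chromosome size and loses the distal marker),
gives each uninduced clone a background event with a configurable
probability drawn from the same truth (the simplest model of promoter
leakiness), and subsamples plugs per class without replacement. Class counts
sum exactly to the induced clone number; everything is bit-reproducible
under a seed. `recovery_experiment()` wraps simulate → estimate and reports
bias, empirical SD, mean bespoke SEM and Monte-Carlo SE per outcome; at the
published hybrid design (955 clones, 18/52 plugs) the internal-deletion
frequency is recovered without detectable bias.

## Numerical conventions

* Internal coordinates 0-based half-open everywhere; GFF3 (1-based
  inclusive) converted at the I/O boundary; minus-strand elements stored as
  the element's own 5'→3' sequence.
* Internal computation at full precision; table cells print at one decimal,
  summary percents round to integers — matching the precision of the tables
  they mirror. Unrounded values ride along as attributes and in manifests.
* Population SD for family identity, sample SD for loss replicates (both
  documented defaults where the source is silent; the first is switchable).
* DP tie-breaking is delegated to a single deterministic aligner
  implementation plus canonical argument ordering, so equal-scoring
  alignments never produce run-to-run differences in any reported metric.

## Reproducing genome-scale numbers (optional workflow)

The published genome-wide statistics (mean Ty1–Ty1 identity 95.7 ± 2.4%,
73% of full-length pairs ≥ 250 bp, 1% of LTR pairs, specific donor ranks)
require the deposited catalog: the SGD non-ORF repeat set (January 5, 2010
snapshot) plus the resequenced cluster accessions, with the documented
corrections applied via `correction_list()`. Given those FASTA/annotation
inputs, the workflow is `load_catalog()` → `apply_corrections()` →
`pairwise_matrix()` over `{TY1, TY2}` and `{LTR}` → `meps_fraction()`,
`family_identity_stats()`, `rank_donors()` — the same functions the tests
exercise on synthetic data. Because both the exact catalog snapshot and the
aligner's unpublished substitution matrix are external unknowns, these
reproductions belong to exploratory analysis, not the test suite; both
strand modes and both identity denominators should be tried.

## Known limitations

* Bit scores use ungapped Karlin–Altschul constants for a gapped scoring
  scheme; use raw scores when absolute calibration matters.
* `local_hits()` returns the single best local alignment; sub-optimal
  non-overlapping hits are not enumerated (block lengths come from the exact
  DP instead, which dominates the hit-scanning heuristic by construction).
* The estimator consumes classified plug counts; it does not infer
  rearrangement types from gels or genotypes.
* The "< x" bound convention reproduces the assigned-count rule; it does not
  claim to match every published bound cell (the published bounds are not
  all consistent with any single formula).
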