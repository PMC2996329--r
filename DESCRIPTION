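Package: tynahr
Title: Repeat-Family Homology Profiling and NAHR Clone-Assay Outcome
    Estimation
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying non-allelic homologous recombination (NAHR)
    between dispersed repeat families such as the yeast Ty1/Ty2
    retrotransposons.  Provides an annotated repeat-catalog container with
    coordinate-convention handling and catalog corrections; all-vs-all
    pairwise homology profiling (global percent identity under
    Needleman-Wunsch affine-gap alignment, exact longest block of
    uninterrupted identity, Smith-Waterman local scores rescaled to
    Karlin-Altschul bit scores); MEPS-style binning of block lengths,
    family identity statistics and recipient-to-donor rankings; a
    nonselective clone-assay outcome-frequency estimator with background
    subtraction, plug-weighted repair-type frequencies and a weighted
    binomial standard error with documented edge-case rules; and seeded
    synthetic-data generators (repeat families evolved from a common
    ancestor, multinomial clone assays) so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
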