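Package: sispec
Title: Mutational Bias and GC-Favoring Fixation Forces at Short Intronic Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the mutational bias (kappa = u/v) and the scaled
    strength of a GC-favoring fixation force (gamma = 4*Ne*s, as expected
    under GC-biased gene conversion) at putatively neutral short intronic
    sites, from population polymorphism (class-specific unfolded site
    frequency spectra) and from between-species divergence (lineage-specific
    weak-to-strong and strong-to-weak substitution counts).  Provides
    extraction of short-intron sites from genome annotation, intersection of
    homologous sites through whole-genome-alignment columns, GC-content
    quintile binning with intron-level bootstrap confidence intervals,
    two-outgroup probabilistic ancestral-allele inference under the Kimura
    two-parameter model, Poisson likelihood models of the unfolded spectrum
    with demographic-distortion and polarization-error nuisance parameters,
    a nonstationary three-taxon substitution model with expected Markov
    counting of labelled substitutions, the closed-form equilibrium algebra
    linking kappa, gamma, GC content and substitution-rate ratios, and a
    synthetic-data generator with known ground truth so the whole chain is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
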