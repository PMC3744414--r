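Package: dimorphix
Title: Transcriptome Masculinization and Feminization Across a Sexual-Dimorphism Continuum
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for sex-biased gene expression across a three-morph
    sexual-dimorphism continuum (female, subordinate male, dominant male).
    Classifies genes as male- or female-biased by pairwise negative-binomial
    testing with fold-change thresholds, quantifies demasculinization and
    feminization of the intermediate morph by paired rank tests, bias-decoupling
    regressions, Spearman morph correlations and presence Venn partitions, and
    ships the study-design validity controls: compositional renormalization after
    removing male-biased reads, a resampling null against regression toward the
    mean, and androgen motif-proximity tests. Category-level dN/dS is aggregated
    by site-weighted sums with bootstrap confidence intervals, and global
    structure is summarized by bootstrapped hierarchical clustering and factor
    analysis. A negative-binomial simulator generates count matrices, binding-site
    intervals and divergence records with known ground truth for parameter-recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    Matrix,
    ape,
    rtracklayer,
    GenomicRanges
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
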