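Package: panelmetrics
Title: Analytical Performance Metrics for Oncopanel Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimators for the analytical validation of targeted cancer
    sequencing panels (oncopanels) against characterized reference samples:
    VAF-stratified sensitivity with clustered bootstrap confidence intervals,
    three complementary false-positive-rate estimators (known-negative loci,
    low-VAF calls in a diploid normal, and mixture-sample exclusivity), a
    non-symmetric intra-/cross-laboratory reproducibility measure on the Phred
    scale, genomic sub-region construction (consensus targeted region and
    high-confidence coding region partitions), and a two-component tumor
    mutational burden coefficient-of-variation model combining technical
    run-to-run variability with the intrinsic variability of projecting
    exome-level TMB onto a small panel. A synthetic study generator emulates
    the multi-laboratory replicate design, admixture and spike-in reference
    samples, and a TCGA-like mutation catalog so every estimator can be tested
    against known generative parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
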