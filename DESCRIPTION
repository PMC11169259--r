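Package: temporalsweep
Title: Temporal Selection Scans and Compensatory Coadaptation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects recent selective sweeps from temporally sampled
    population resequencing data. Implements windowed nucleotide diversity,
    Weir-Cockerham F_ST and diversity log-ratio outlier scanning with region
    merging and gene overlap; leave-one-out iterative resampling to score the
    robustness of candidate genes; extended haplotype homozygosity statistics
    (EHH, iHS, XP-EHH) on phased haplotypes for independent validation;
    per-SNP Fisher exact case/control association and linkage-disequilibrium
    r-squared with decay curves; and gene-set overlap and functional-term
    enrichment against differentially expressed gene lists. A built-in forward
    Wright-Fisher simulator with a planted hard sweep generates phased cohorts
    sampled at multiple time points for calibration and parameter-recovery
    testing.
License: MIT
Encoding: UTF-8
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
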