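Package: dropletcn
Title: Copy-Number Determination for Segmental Duplications from Droplet
    Digital PCR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for duplexed droplet digital PCR (ddPCR)
    copy-number assays targeting segmental duplications, built around the
    nebulin (NEB) triplicate region where an eight-exon block is repeated
    three times per allele (normal diploid copy number 6).  Reads
    QuantaSoft-style droplet amplitude exports, assigns droplets to the
    four two-channel fluorescence groups with automatic or manual
    thresholds, converts cluster counts to Poisson copies-per-partition
    and a copy-number estimate against a diploid reference gene, applies
    run-level quality filters, computes intra- and inter-assay replicate
    variability (%CV), classifies integer copy numbers as benign or
    pathogenic, and quantifies concordance with array-CGH calls through
    Pearson correlation, linear regression, and (weighted) Cohen's kappa.
    Also implements log2-ratio re-normalization of array-CGH probes over
    the triplicate region and a synthetic droplet simulator with known
    ground truth (rain, no-template controls, tandem-copy linkage) so the
    whole pipeline is testable without laboratory data.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    e1071,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
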