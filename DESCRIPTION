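Package: trexkit
Title: Targeted RNase H-Mediated Extraction (TREX) Proteomics Workflow
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis workflow for targeted RNase H-mediated extraction (TREX)
    of RNA-binding proteins. Designs non-overlapping tiling antisense DNA
    oligonucleotides against a target RNA and screens them for off-target
    matches, parses MaxQuant-style protein quantification tables, performs
    Perseus-style differential release statistics (minimum-valid filtering,
    Gaussian downshift imputation, S0-moderated two-sample tests with
    permutation-based FDR and volcano significance boundaries), estimates
    relative RNA affinities from iBAQ abundances, integrates per-region
    enrichment results into clustered t-score profiles with region-specificity
    calls, runs depletion and specificity QC (2^-dCT qPCR summaries and a
    quantile-based transcriptome outlier test), and tests category
    over-representation by Fisher's exact test. A synthetic-data module
    generates TREX-like experiments with planted ground truth so every stage
    is testable without external downloads.
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
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    Biostrings,
    cluster,
    fgsea,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
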