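Package: cpgsight
Title: CpG-Resolution Promoter Methylation and Regulatory Integration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of promoter DNA methylation at CpG resolution for
    multi-transcript loci assayed by bisulfite pyrosequencing, qPCR and
    quantitative methylation-specific PCR (qMSP). Computes per-CpG relative
    methylation indices and critical-CpG flags, classifies expression by
    delta-Ct tertiles, correlates methylation with expression, clusters
    transcript profiles, scans promoter sequences against JASPAR position
    frequency matrices with exact dynamic-programming p-values, integrates
    transcription-factor binding sites with CpG dinucleotides, and calls
    qMSP methylation against an unmethylated-control background. Includes
    a synthetic-data generator emulating pyrosequencing, qPCR and qMSP
    measurements with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    ape,
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
    withr
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
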