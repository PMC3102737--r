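Package: methylpass
Title: Longitudinal Differential Methylation Analysis of iPSC Reprogramming
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Threshold-based differential methylation analysis of Infinium-style
    beta-value matrices across cell-line passages, built around the dynamics of
    induced pluripotent stem cell (iPSC) reprogramming. Calls differentially
    methylated regions (DMRs) at a fixed beta difference threshold, partitions
    probes into the seven ESC/iPSC/parent overlap categories, extracts stem
    cell-specific and stem cell-required DMRs, decomposes per-line differences
    from the ESC average into parent-inherited versus aberrant sites, tracks
    appearance and disappearance of DMR cohorts across passages, screens
    imprinted loci, and ships a stochastic simulator of passage-wise de novo
    hyper-methylation and convergence toward the ESC profile with ground-truth
    event logs for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
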