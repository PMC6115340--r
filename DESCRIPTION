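Package: coexsum
Title: Cross-Tissue Co-Expression Ranking, Promoter Motif Scanning and
    Membrane Line-Profile Colocalization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering co-expression modules around a query gene
    across multiple tissues by summing per-tissue correlation coefficients
    (the R_sum statistic), with trimmed-mean-of-M-values (TMM) count
    normalization, degenerate promoter-motif scanning (CArG, MCAT, GATA, GRE)
    in signed transcription-start-site coordinates, and two-channel membrane
    line-profile colocalization analysis. Includes synthetic-data generators
    with planted ground truth for every stage: latent-factor expression
    panels, negative-binomial count matrices with library-size and
    composition bias, promoters with planted motifs, and interdigitating
    two-domain membrane traces with a tunable channel-overlap parameter.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    jsonlite,
    generics,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    e1071,
    edgeR,
    optparse,
    withr
Config/testthat/edition: 3
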