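Package: promcap
Title: Information Transmission Through Gene Promoter Channels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Treats a gene promoter as a noisy communication channel and
    quantifies, in bits, how much information about the amplitude or
    frequency of a transcription factor's nuclear dynamics is transmitted
    to single-cell gene expression. Provides trace processing for
    single-cell fluorescence time courses, channel-capacity estimation
    from dose-response distributions (Blahut-Arimoto maximisation with
    jackknife undersampling correction and a bin-count sweep), joint
    two-reporter capacity via the chain rule, dual-reporter decomposition
    of expression noise into intrinsic and extrinsic components, a
    gamma-deflation algorithm that infers the intrinsic (extrinsic-noise
    corrected) channel capacity, and an exact stochastic (Gillespie)
    simulator of gene-expression models with per-cell extrinsic parameter
    variation used to validate the intrinsic-capacity algorithm in silico.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    utils,
    dplyr,
    fitdistrplus,
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
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
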