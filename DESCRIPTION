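Package: platefit
Title: Growth-Curve Fitness Analysis for Heterologous Complementation
    Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fits the fixed-shape Richards growth model to microplate OD600
    time series to extract the maximum specific growth rate (mu_max) and the
    time to inflection (TTI), aggregates per-well fits into per-experiment
    lineage summaries with relative fitness against a within-plate control,
    and relates those fitness proxies to sequence covariates: uncorrected
    p-distance and maximum-likelihood JTT-corrected divergence between
    aligned proteins, and the Codon Adaptation Index of coding sequences
    against the E. coli high-expression reference set. Includes a synthetic
    plate and sequence simulator with known ground truth so the whole
    pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    phangorn,
    seqinr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
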