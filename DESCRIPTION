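Package: fourbase
Title: Four-Base DMS-MaP Analysis of RNA Structure Probing Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis toolkit for four-base dimethyl sulfate (DMS) mutational
    profiling (MaP) experiments. Implements mutation-signature filtering that
    separates structurally informative N1-methylguanine signals from
    N7-methylguanine noise, nucleotide-specific reactivity normalization,
    the Expected Structural Information (ESI) metric based on double-gamma
    mixture likelihoods, single-molecule PAIR co-modification analysis of
    3-nt windows, and pseudo-energy likelihood fitting for structure
    modeling engines. Includes a synthetic read simulator emulating
    per-nucleotide Bernoulli adduct chemistry so the whole pipeline is
    testable without sequencing data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    purrr,
    rlang,
    readr,
    ggplot2,
    jsonlite,
    stats,
    utils,
    generics
Suggests:
    testthat (>= 3.0.0),
    pROC,
    fitdistrplus,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
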