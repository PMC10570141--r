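Package: ademtrack
Title: Longitudinal Microglial Aging Analysis: Trend Genes, Staging and
    Turnover
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for longitudinal transcriptomic analysis of microglial
    aging. Provides a negative-binomial differential-expression engine for
    ordered age series, a monotone-trend classifier for age-dependent
    microglia (ADEM) genes based on neighbor-timepoint comparisons, PCA
    stage segmentation of aging trajectories with gradual-versus-switch
    shape classification, expression-matched gene-set signature scoring
    and set-concordance statistics, and a forced-turnover quantification
    suite (cumulative divisions from depletion-repopulation densities,
    relative telomere length from qPCR, Sholl-based morphology and the
    senescence index, Y-maze alternation rate). A synthetic-data module
    generates all inputs with known ground truth so every stage of the
    pipeline is testable without external data.
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
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    edgeR,
    fgsea,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
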