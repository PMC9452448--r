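Package: psacurves
Title: Decision-Uncertainty Curves and Plots for Probabilistic Sensitivity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for representing parameter uncertainty in cost-effectiveness
    analyses that compare many strategies. Operates on probabilistic sensitivity
    analysis (PSA) output (a cost and an effect per strategy per iteration) and
    computes the cost-effectiveness acceptability curve (CEAC) and frontier
    (CEAF), expected loss curves (ELC), the expected value of perfect
    information (EVPI), net-benefit and incremental-benefit densities and
    cumulative curves, stochastic dominance plots, the return-risk space,
    cumulative rankograms, a relaxed CEAC with rank, absolute and relative
    relaxation schemes, and a heat map that joins the CEAC and ELC in a single
    figure. Includes a synthetic-PSA generator with tunable between-strategy
    correlation, CSV readers and writers for wide and long PSA layouts, ggplot2
    plotting methods, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
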