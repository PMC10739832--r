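Package: floa
Title: Functional Limits of Agreement for Curve-Valued Method Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assesses agreement between two methods that measure curve-valued
    responses (for example joint-angle curves from marker-based and markerless
    motion capture) using 95% functional limits of agreement.  Difference
    curves from hierarchical designs (subjects, sessions, replicates) are
    modelled with a nonparametric linear mixed-effects model whose fixed and
    random effects are expanded in cubic B-spline bases, or in a
    Karhunen-Loeve eigenbasis of the sample covariance that permits a diagonal
    random-effects covariance, with ARMA-correlated within-curve errors
    estimated by restricted maximum likelihood.  Includes an adjusted
    R-squared knot-selection rule, BLUPs, residual autocorrelation and
    difference-versus-average diagnostics, a synthetic data generator that
    emulates the motion-capture study design, and tidyverse-style interfaces
    with broom tidiers and ggplot2 autoplot methods.
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
    purrr,
    readr,
    rlang,
    splines,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    lme4,
    nlme,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
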