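Package: relbel
Title: Relative Belief Inference with Guaranteed A Priori Coverage
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Evidence-based Bayesian region construction from the principle of
    evidence: relative belief ratios over a discretized parameter of interest,
    plausible and credible regions that are never improper, and Monte Carlo
    measurement of the a priori biases (bias against and bias in favor) whose
    control yields guaranteed Bayesian confidence and accuracy. Includes prior
    elicitation by quantile-matching bisection, prior-data conflict checks,
    and complete treatments of Fieller's ratio-of-means problem and of
    constrained-mean normal and constrained-rate Poisson models.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
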