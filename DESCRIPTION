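Package: steinvc
Title: Bayesian Data Selection with the Stein Volume Criterion
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for Bayesian data selection and model selection with the
    Stein volume criterion, a generalized marginal likelihood that replaces the
    log likelihood with a normalized kernelized Stein discrepancy (NKSD) and
    replaces the background model by a volume correction on its effective
    parameter dimension. Provides kernels with Stein-operator derivatives,
    U-statistic NKSD estimation, exact/Laplace/BIC/variational score backends,
    minimum Stein discrepancy fitting, foreground model families (Gaussian
    exponential family, probabilistic PCA, a continuous-relaxation spin glass
    for gene regulation), leave-one-out data selection scans, fast approximate
    optimum transfer across candidate foregrounds, stochastic subset search,
    and seeded synthetic benchmark generators.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
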