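Package: clrgee
Title: Cluster-Robust Variance Estimation for Conditional Logistic
    Regression with Correlated Use-Availability Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how clustering rules affect generalized
    estimating equation (GEE) inference in conditional logistic
    regression (CLR), the model behind habitat-selection and
    step-selection analyses of animal telemetry data.  Implements the
    CLR score equations under an independence working structure with
    naive (model-based) and cluster-robust sandwich variance
    estimators, a generator of temporally autocorrelated matched
    case-control data with inter-individual heterogeneity (AR(1)
    coefficient paths and cluster-level random intercepts and slopes),
    destructive-sampling and unbalancing schemes for re-clustering the
    data, and a Monte Carlo harness that benchmarks both variance
    estimators against the empirical sampling variance of the
    coefficient estimates.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
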