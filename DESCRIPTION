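Package: amad
Title: Two-Stage Adaptive Multi-Arm Designs with Covariate Adjustment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and inference for two-stage adaptive multi-arm trial
    designs with interim treatment selection and baseline covariate adjustment.
    Generates subject-level trial data from per-arm joint multivariate-normal
    covariate/outcome models, applies pre-specified selection rules to
    covariate-adjusted interim statistics, controls the familywise error rate
    in the strong sense via closed testing with stage-wise Dunnett p-values
    combined by the weighted inverse-normal (or Fisher) combination test, and
    computes naive stage-wise, overall, and conditionally unbiased (UMVCUE)
    treatment-effect estimators. A replication engine summarises operating
    characteristics (selection frequencies, power, error rates, bias and MSE)
    over scenario grids.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    parallel,
    mvtnorm,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
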