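Package: mamsmc
Title: Monte Carlo Design of Multi-Arm Multi-Stage Trials with Unknown Variance
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Design and evaluation of multi-arm multi-stage (MAMS) clinical
    trials with normally distributed endpoints when the response variance is
    unknown. Trials comparing K experimental arms against a shared control over
    up to J stages are simulated under t-test statistics with a pooled variance
    estimate, giving Monte Carlo estimates of the familywise error-rate,
    pairwise power and expected sample size. Known-variance z-test designs are
    evaluated exactly by multivariate normal integration, stopping boundaries
    can be adjusted by quantile substitution, and group size and boundaries can
    be optimised jointly by a cross-entropy search under a penalised
    expected-sample-size objective, using common random numbers across
    candidate designs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    graphics,
    utils,
    mvtnorm,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
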