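Package: circmove
Title: Circular Auto-Regressive Movement Models for Animal Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits and simulates discrete-time movement models for regularly
    sampled 2-D trajectories in which the direction of heading follows a
    circular auto-regression: the previous heading is attracted toward a focal
    direction (or focal point) through a smooth tan-half-angle circle map, and
    the step-to-step error follows a von Mises, wrapped Cauchy, or
    four-parameter asymmetric (Kato-Jones) circular distribution, the latter
    capturing wind-skewed headings. A coupled Gaussian auto-regression models
    speeds as a function of heading, previous speed, and angular velocity.
    Provides conditional maximum-likelihood fitting with multi-start
    quasi-Newton optimisation, AIC model selection across model families and
    constrained variants, residual lag-1 autocorrelation screening for
    time-unit selection, parametric-bootstrap goodness-of-fit tests (heading
    distribution envelopes and final-location probability), bootstrap
    distributions of maximum-likelihood estimates, and trajectory simulation
    including synthetic fixture scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
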