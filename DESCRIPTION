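Package: dtipower
Title: Monte Carlo Power Analysis for Longitudinal Diffusion Tensor
    Imaging Studies
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Design tools for two-group longitudinal studies that track a
    scalar imaging biomarker, built for fractional anisotropy (FA) of the
    corticospinal tract in amyotrophic lateral sclerosis. Estimates
    test-retest reliability (two-way mixed-effects, single-rater,
    absolute-agreement intraclass correlation with confidence intervals)
    and the standard error of measurement; simulates subject-specific
    linear FA trajectories with Gaussian random effects and per-scan
    measurement error; estimates statistical power of the two-group
    change-score comparison by Monte Carlo simulation; and searches
    minimal per-group sample sizes, including the trade-off between
    repeated scans per session and required sample size. A command-line
    interface exposes every analysis for scripted use.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    optparse,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
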