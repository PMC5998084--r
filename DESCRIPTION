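Package: nppgrowth
Title: Multilevel Growth Models and Trend Analysis for Grassland Net
    Primary Productivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing change in grassland net primary
    productivity (NPP) observed on a panel of small watersheds nested in
    counties.  Provides a from-scratch Gaussian linear mixed-model
    estimator for two nested random-effect levels (profiled ML/REML via
    sparse penalized least squares), a three-level growth-model ladder
    (null, unconditional, and stepwise conditional models) with
    intraclass-correlation variance decomposition, per-pixel linear trend
    estimation with F-test significance grading, additive accounting of
    NPP change under land-use conversion, and a synthetic multilevel
    panel/grid generator with known ground truth for parameter-recovery
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    lme4,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
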