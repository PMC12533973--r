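Package: emboflow
Title: Thromboembolus Transport in a Heart-to-Brain Arterial Network Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Reduced-order in silico modelling of thromboembolus
    source-to-destination transport from carotid stenosis and cardiogenic
    sources to the cerebral arteries. Builds a synthetic single-inlet,
    eleven-outlet heart-to-brain arterial network with a complete Circle of
    Willis, applies NASCET-parameterized bilateral carotid stenoses, solves
    pulsatile network hemodynamics with tuned outlet resistance boundary
    conditions, reconstructs an analytic in-vessel velocity field, and
    integrates individual emboli with a modified Maxey-Riley equation
    including shear-gradient lift and lubricated wall collisions. Includes
    Monte Carlo experiment orchestration and the distribution analytics
    (outlet number fractions, hemispheric splits, contralateral fractions,
    non-parametric tests) used to study contralateral embolic events.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    pracma,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr,
    optparse
Config/testthat/edition: 3
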