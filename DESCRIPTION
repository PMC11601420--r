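Package: eadsim
Title: Stochastic Calcium-Spark Model of Early Afterdepolarizations in
    Cardiac Myocytes and Tissue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a phenomenological rabbit ventricular myocyte in which
    calcium release is carried by a stochastically recruited population of
    calcium sparks at junctional ryanodine-receptor clusters, coupled to a
    ten-state Markov model of the L-type calcium channel with calcium-induced
    inactivation.  Early afterdepolarizations (EADs) are induced by reducing
    the calcium-dependent component of L-type channel inactivation.  Provides
    the deterministic (infinite-cluster) limit of the spark model, a 1D/2D
    monodomain tissue solver with operator splitting, action-potential-duration
    (APD) measurement and pacing protocols (steady-state, dynamic sweep with
    hysteresis, S1S2 restitution), and a nonlinear APD restitution-map toolkit
    (cubic-spline maps, iteration with a conduction-block rule, second-iterate
    fixed-point analysis of the subcritical period-doubling transition,
    bifurcation and phase diagrams, cobweb data).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
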