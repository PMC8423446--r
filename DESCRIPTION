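Package: fluctlearn
Title: Regulatory Circuits that Learn Environment Fluctuation Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulator and analysis toolkit for regulatory circuits that learn
    the fluctuation structure (variance, correlations, dominant direction) of a
    stochastically fluctuating demand. Provides an epoch-structured
    Ornstein-Uhlenbeck demand generator with analytic stationary statistics; the
    simple end-product inhibition (SEPI) baseline and its generalization with an
    excess of self-activating, nonlinearly regulated regulators; two realistic
    biochemical implementations (an allosteric enzyme pair and a bifunctional
    enzyme homeostasis circuit); responsiveness and learned-angle estimators; a
    linear-quadratic tracking ceiling under a control-input-power constraint for
    optimality comparisons; and sweep drivers with a config-driven command-line
    entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
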