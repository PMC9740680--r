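Package: qcrsf
Title: Quartz Crystal Resonator Viscometry and Classification of Synovial Fluid
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discriminating septic from inflammatory synovial fluid
    using viscosity-linked features measured with a 10 MHz quartz crystal
    resonator. Implements the Kanazawa-Gordon relation between frequency shift
    and the density-viscosity product, Lorentzian conductance-sweep simulation
    and resonance/half-bandwidth extraction, a hierarchical synthetic cohort
    generator emulating repeated per-sample measurements, nonparametric group
    statistics (Mann-Whitney U, ROC/AUC with Hanley-McNeil standard errors),
    and a tabular classification workflow (multilayer perceptron, linear
    squared-hinge support vector machine, random forest) with robust scaling,
    random oversampling and confusion-matrix reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    ranger,
    stats,
    utils,
    yaml
Suggests:
    e1071,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
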