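Package: stereofract
Title: Design-Based Stereology with a Synthetic Tissue Simulator
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimators used in design-based stereology of thick serial
    sections: Cavalieri volume estimation with the Gundersen-Jensen
    coefficient of error, optical-fractionator cell counting with unbiased
    counting frames and optical disectors, and Spaceballs fiber length
    estimation, together with immunoreactivity-class bookkeeping,
    density/shrinkage reporting and marker-distribution heatmaps. A
    synthetic-tissue simulator generates Poisson cell fields, Bernoulli
    immunoreactivity-compartment labels and isotropic fiber fields inside
    regions of known geometry, and sections them with realistic z-collapse,
    xy shrinkage and truncation, so every estimator is verifiable by
    parameter recovery. Defaults follow a stereological study of the
    bottlenose dolphin inferior colliculus and ventral cochlear nucleus.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    mgcv,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
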