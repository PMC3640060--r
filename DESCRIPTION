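Package: standdist
Title: Modelling and Prediction of Stand Diameter Distributions
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for modelling tree diameter distributions in even-aged
    plantations. Implements the R distribution, a reparameterisation of the
    Richards growth function into a three-parameter cumulative distribution
    with interpretable scale, location and shape parameters, alongside the
    three-parameter Weibull baseline. Parameters are estimated per stand by
    nonlinear regression on cumulative diameter-class frequencies (NRM) or by
    maximum likelihood (MLEM), and distributions of unmeasured stands are
    predicted from stand characteristics by the parameter prediction method
    (PPM) and the parameter recovery method (PRM), using percentile diameters
    and the inflection point of the cumulative curve. Includes
    Kolmogorov-Smirnov goodness-of-fit evaluation stratified by thinning
    status, a plantation cohort simulator for end-to-end testing, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    minpack.lm,
    fitdistrplus,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
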