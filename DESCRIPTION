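Package: thzgmm
Title: Terahertz Spectral Classification of Pharmaceutical Powders with
    Gaussian Mixture Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quality-control analysis of pharmaceutical powders from
    terahertz time-domain spectroscopy (THz-TDS). Extracts frequency-domain
    optical parameters (refractive index and extinction coefficient) from
    paired sample/reference time-domain traces, samples extinction features
    on a configurable frequency grid, reduces dimension by principal
    component analysis, and classifies samples with a two-component
    multivariate Gaussian mixture model fitted by expectation-maximization
    with label-informed initialization. Includes a seeded synthetic THz-TDS
    data generator, a Beer-Lambert two-element linear-combination robustness
    harness with decision-tree and kernel-SVM comparators, and an end-to-end
    reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    signal,
    jsonlite,
    kernlab,
    withr
Suggests:
    testthat (>= 3.0.0),
    e1071,
    rpart,
    optparse
Config/testthat/edition: 3
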