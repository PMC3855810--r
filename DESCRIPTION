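Package: treelight
Title: Light-Availability Proxies for Tropical Tree Demography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to compare light-availability proxies for modelling
    tropical tree demography. Implements distance-dependent neighborhood
    competition indices (NCI) with a grid search over size and distance
    exponents, a canopy index (CAI) derived from layered canopy-occupancy
    censuses by quantile matching against a reference irradiance
    distribution, zero-intercept median quantile regression to convert NCI
    to the log canopy-index scale, and hierarchical Bayesian models of
    species-specific recruitment (negative-binomial counts) and diameter
    growth (lognormal process error with a two-component measurement-error
    mixture) fitted by adaptive Metropolis-Hastings MCMC. A synthetic
    forest-stand generator with known ground-truth parameters supports
    parameter-recovery testing without restricted census data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
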