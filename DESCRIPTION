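Package: emergrow
Title: Emergence of Classical Growth Laws from a Hybrid Cellular Potts Model
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hybrid multiscale simulator of diffusion-limited multicellular
    aggregate growth: a two-dimensional cellular Potts model (Graner-Glazier-
    Hogeweg) coupled to a reaction-diffusion oxygen field, with stochastic
    Gaussian intracellular responses driving cell proliferation and death.
    Includes unified-Richards growth-model fitting (with Bertalanffy, Gompertz
    and logistic submodels), aggregate best-fit-ellipse eccentricity analysis,
    and a probability-area statistic linking intracellular response profiles to
    emergent final aggregate size.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    jsonlite,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
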