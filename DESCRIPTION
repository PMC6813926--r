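Package: canopyflux
Title: Leaf-Resolving Canopy Radiation, Energy Balance and Photosynthesis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale, leaf-resolving simulator of plant canopy biophysics.
    Couples reverse Monte-Carlo radiation transport over arbitrary wavebands
    (collimated solar, isotropic diffuse, and thermal emission with an exact
    isothermal null) with a per-leaf surface energy balance solved by the
    secant method, a hyperbolic stomatal conductance model, and
    Farquhar-von Caemmerer-Berry C3 photosynthesis with intercellular CO2
    coupling. Includes procedural tree and canopy generation with custom leaf
    inclination distributions, clear-sky solar forcing, voxel binning and
    leaf-population aggregation statistics, and an orchestrated diurnal case
    study producing per-leaf distributions and top-decile flux fractions.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    xml2,
    minpack.lm
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
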