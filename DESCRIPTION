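Package: kappamax
Title: Static Chamber Greenhouse Gas Flux Estimation with a Dynamic
    Nonlinearity Restriction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calculates soil greenhouse gas fluxes from static (non-steady
    state) chamber closures using linear, robust linear and
    Hutchinson-Mosier (HMR) nonlinear regression, and implements a family
    of decision schemes that choose between the linear and nonlinear
    estimate per closure, centrally the kappa.max rule that bounds the
    fitted nonlinearity parameter by the ratio of the linear flux to the
    system's minimal detectable flux.  Includes Monte-Carlo estimation of
    the minimal detectable flux, a simulation framework that maps bias,
    uncertainty (IQ90) and mean squared error of each scheme over a grid
    of true fluxes and curvatures, sensitivity sweeps over instrument
    precision and deployment time, projection of measured datasets onto
    the simulation grid, and a synthetic fixture generator emulating a
    multi-year N2O field campaign.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown,
    yaml,
    optparse,
    jsonlite
Config/testthat/edition: 3
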