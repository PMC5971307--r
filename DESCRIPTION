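Package: ivcsim
Title: Finite-Element Simulation of Left-Ventricular Isovolumic Contraction
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Idealized finite-element model of the left ventricle for studying
    how transmural gradients in electromechanical delay and myocyte shortening
    velocity shape isovolumic contraction. Builds truncated-ellipsoid
    hexahedral meshes with a seven-layer fibre helix field, implements a
    transversely isotropic hyperelastic law for passive myocardium and a
    prescribed-strain active fibre contraction, recovers the zero-pressure
    reference geometry by backward-displacement iteration, and simulates the
    isovolumic phase with an exact cavity-volume constraint whose Lagrange
    multiplier is the intraventricular pressure. Includes calibration of the
    contraction rate to a target isovolumic duration, a comparative scenario
    suite (homogenised delay and/or shortening velocity, intramural
    activation), derived contractility metrics, and least-squares recovery of
    the passive constitutive parameters from synthetic biaxial test data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: Rcpp, Matrix, methods, stats, utils, minpack.lm, jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
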