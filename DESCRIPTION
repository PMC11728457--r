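Package: hemoclear
Title: Structure-Aware Modeling of Hollow-Fiber Hemodialyzer Clearance
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates solute clearance of hollow-fiber hemodialyzers from the
    structure of the membrane. Provides a one-dimensional transient
    electro-diffusion-reaction solver (Nernst-Planck fluxes under
    electroneutrality and zero current, with phosphate and water acid-base
    kinetics) across the diffusion boundary layer | membrane | diffusion
    boundary layer stack, a microheterogeneous structure-property model
    linking porosity and pore arrangement to the tortuosity coefficient, the
    counter-current clearance formula for fiber bundles, least-squares
    fitting of structural parameters to permeability and clearance data, and
    seeded synthetic-data generators for recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
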