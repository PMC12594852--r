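Package: hollowcond
Title: Phase-Field Simulation and Quantitative Imaging of Hollow
    Biomolecular Co-Condensates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying hollow (vesicle-like) biomolecular
    co-condensates formed by fusion oncoproteins with nucleic acids.
    Implements a three-order-parameter Ohta-Kawasaki phase-field model of
    protein-DNA co-condensation with a semi-implicit Fourier-spectral
    integrator, steady-state morphology classification and state-diagram
    sweeps over initial compositions, the elliptical-annulus radial
    profiling procedure used for super-resolution (STED) images of
    condensate shells, ImageJ-style condensate morphometry (background
    subtraction, particle filtering, diameter from area, hollowness
    scoring), and a synthetic microscopy generator that renders shell
    images and droplet panels with known ground truth so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    EBImage,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
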