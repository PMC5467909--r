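Package: ttfieldsim
Title: Finite-Element Dosimetry of Tumor Treating Fields in Synthetic Head Phantoms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Electrostatic finite-element simulation of tumor treating fields
    (TTFields) delivered through scalp electrode arrays. Builds synthetic
    tetrahedral head and slab phantoms with five tissue compartments and
    embedded two-compartment spherical tumors, maps tissue labels and
    synthetic fiber tensors to per-element conductivity tensors (isotropic,
    direct-mapped anisotropic, and arithmetic-mean isotropized), solves the
    quasi-static Laplace equation with first-order tetrahedral elements and a
    preconditioned conjugate-gradient solver, rescales solutions to a target
    electrode current, and summarizes electric-field dose as volume-weighted
    median and interquartile range in regions of interest. Closed-form
    layered-slab and layered-sphere solutions are included for validation,
    together with drivers that sweep tumor positions and compare montages,
    necrotic versus solid tumors, and anisotropic versus isotropic
    conductivity models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
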