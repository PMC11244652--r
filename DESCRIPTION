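Package: dermaflux
Title: Hemodynamics, Barrier Transport and Immune-Cell Trafficking Analysis
    for Vascularized Skin-on-a-Chip Devices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis pipeline for perfusable vascularized
    skin-on-a-chip experiments. Solves steady Hagen-Poiseuille flow on the
    printed channel graph and classifies wall-shear zones; forward-simulates
    dextran transport from a perfused lumen across a semi-permeable
    endothelial barrier into the hydrogel dermis (finite differences with a
    Robin membrane condition, plus closed-form erfc and surface-conductance
    oracles); estimates endothelial permeability and gel diffusivity from
    time-lapse fluorescence traces by bounded least-squares inversion;
    quantifies T-cell retention per shear zone and infiltration distance
    from the nearest vessel from time-lapse image stacks; and generates
    seeded synthetic microscopy with recorded ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    EBImage,
    pracma,
    mgcv,
    tiff,
    jsonlite,
    yaml,
    optparse,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
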