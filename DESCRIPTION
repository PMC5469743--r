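Package: pdacRF
Title: Continuum Simulation of Pancreatic Tumor Response to Chemotherapy with
    Radiofrequency-Enhanced Drug Transport
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to simulate the response of hypovascularized pancreatic
    adenocarcinoma lesions to gemcitabine chemotherapy with and without
    non-invasive radiofrequency (RF) pre-treatment. A two-dimensional
    continuum model couples reaction-diffusion transport of oxygen, drug,
    angiogenic factors and matrix-degrading enzymes with sprouting
    angiogenesis, Darcy-flow tissue mechanics, pharmacokinetics of bolus
    dosing, and a pharmacodynamic kill model calibrated against spheroid
    cytotoxicity data. RF exposure is modeled as a transient increase of the
    drug's diffusive penetration and vascular extravasation transfer rate.
    The package also implements the image-quantification procedures used to
    measure drug penetration and cytotoxicity (radial intensity profiles,
    nuclear-stain blob segmentation, positive-area fractions, distance
    transforms to vessels) together with synthetic-image generators carrying
    planted ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    EBImage,
    igraph,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
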