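Package: bodycompCT
Title: Automated CT Body Composition from Single Axial Slices
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automated analysis of body composition from single axial CT
    slices in Hounsfield units: liver attenuation via a shape-atlas and
    two-pass distance-transform segmentation with Gaussian histogram
    fitting, abdominal visceral and subcutaneous adipose tissue (VAT/SAT)
    separation built around a directional "inside lean tissue" (ILT)
    ray-accumulation filter, and thigh muscle, subcutaneous, subfascial
    and intermuscular adipose tissue segmentation. Includes a seeded
    synthetic phantom generator with ground-truth labels for validation,
    overlap and repeatability metrics, and a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    Rcpp,
    EBImage,
    RNifti,
    minpack.lm,
    pracma,
    jsonlite,
    yaml,
    png
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
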