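Package: RadTex3D
Title: Robustness Analysis of 3D Texture Features in Tumor MRI
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies how three-dimensional second-order texture features
    of a tumor region of interest respond to changes in image spatial
    resolution and grey-level dynamic range. Builds 3D grey-level
    co-occurrence matrices (26-neighbourhood, unit Chebyshev distance) and
    grey-level run-length matrices (13 directions) over a segmented volume
    of interest, computes sixteen classical heterogeneity features from
    them, and evaluates feature robustness with the coefficient of
    variation across a grid of in-plane matrix sizes, slice thicknesses
    and quantization levels. Includes a seeded synthetic tumor-phantom
    generator emulating contrast-enhanced T1-weighted brain MRI so the
    full pipeline is reproducible without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    RNifti,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
biocViews: Software, ImageImport, FeatureExtraction, Cancer
Config/testthat/edition: 3
RoxygenNote: 7.3.3
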