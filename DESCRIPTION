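Package: dcecad
Title: Texture-Based Computer-Aided Detection for Dynamic
    Contrast-Enhanced Breast MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Voxelwise computer-aided detection of malignant lesions in
    dynamic contrast-enhanced magnetic resonance (DCE-MR) mammography.
    Fits a two-compartment (Brix-type) contrast-exchange model to every
    voxel's time-intensity curve to produce pharmacokinetic parameter
    pseudoimages (peak enhancement A, back-transfer rate k_ep,
    elimination rate k_el), raster-scans a 5x5x2 volume of interest to
    compute three-dimensional gray-level co-occurrence matrices and ten
    Haralick texture statistic pseudoimages per parameter and principal
    direction (90 feature volumes), classifies voxels with a small
    feedforward neural network trained against radiologist masks, and
    evaluates voxelwise true/false positive fractions with a paired
    one-sample t-test against a second reader. Includes a synthetic
    digital phantom generator so the full pipeline is reproducible
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    RNifti,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    EBImage
Config/testthat/edition: 3
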