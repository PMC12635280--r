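Package: tizmapr
Title: Susceptibility-Source Mapping of the Tumor and Immune Cell
    Infiltration Zone in Peritumoral Edema
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: End-to-end quantitative susceptibility mapping (QSM) pipeline
    for delineating a tumor and immune cell infiltration zone (TIZ) in
    peritumoral edema from multi-echo gradient-echo MRI. Implements
    Laplacian phase unwrapping, V-SHARP background-field removal, two
    dipole-inversion algorithms, a constrained paramagnetic/diamagnetic
    sub-voxel source decomposition (PCS/DCS), the PDR ratio metric with
    contralateral gray-matter thresholding, DSC perfusion (nCBV with
    leakage correction) and DCE permeability (extended Tofts Ktrans)
    quantification for blood-voxel exclusion, the associated nonparametric
    statistics and Welch-type power analysis, and a symmetric digital
    tumor-brain phantom that provides ground truth for every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
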