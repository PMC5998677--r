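Package: voxplace
Title: Template-Driven Automated Voxel Placement for Single-Voxel MRS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for accurate and reliable placement of single-voxel
    magnetic resonance spectroscopy (MRS) prescriptions. Supports authoring
    template voxels on a template anatomical image, automated coregistration
    of a template voxel onto a subject T1-weighted image (rigid 6-dof for
    angulation, 9-dof rotation+scale for the centre coordinate), and post-hoc
    quantification of placement accuracy and reliability through
    partial-volume-aware 3D geometric overlap metrics on a 0.5 mm grid,
    including between- and within-subject overlap, coefficient of variation,
    and tissue composition from partial-volume maps. Includes a synthetic
    head-phantom generator with known ground-truth transforms for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
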