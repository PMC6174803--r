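Package: ropseg
Title: Registration-Based Liver Positioning and Coarse-to-Fine CT Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for automatic liver and liver-tumor delineation in abdominal
    CT volumes. A registration-based organ positioning (ROP) step obtains a
    per-slice liver bounding box by registering a standard template slice, used
    as the float image, onto each unseen slice and propagating the template
    label extent, so no inverse registration is needed. Inside each box a
    coarse liver mask is produced by fusing fuzzy c-means clustering with an
    extreme learning machine pixel classifier (126 texture features per pixel,
    sine hidden layer, Moore-Penrose output weights), with fusion weights set
    from per-slice training accuracies. The coarse boundary is refined by a
    parametric active contour. A tumor stage classifies pixels inside the
    segmented liver with a second extreme learning machine. The package ships
    a synthetic abdominal phantom generator, the standard volumetric and
    surface evaluation metrics (VOE, RVD, ASD, RMSD, MSD, Dice), a
    cross-validation harness, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    RNifti,
    png,
    jsonlite,
    grDevices,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pracma,
    yaml
Config/testthat/edition: 3
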