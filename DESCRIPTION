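Package: spikemorph
Title: Intra-Spike Grain Morphometrics and Variation Statistics from Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-based phenotyping of wheat grains arranged by spikelet
    position: scale calibration, automatic thresholding and particle
    segmentation, per-grain morphometrics (area, perimeter, Feret and MinFeret
    caliper diameters, best-fit ellipse axes, circularity, aspect ratio,
    roundness, solidity), and the intra-spike variation statistic ISVAD
    (population standard deviation of a grain-size parameter within a spike or
    spike region). Includes a synthetic spike-image generator with exact
    ground truth, caliper-versus-image calibration with k-fold
    cross-validation, split-plot/RCBD analysis of variance and Duncan's
    multiple range test with letter displays, plus batch processing and
    ImageJ-dialect CSV interchange.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    grDevices,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
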