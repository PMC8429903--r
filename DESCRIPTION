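Package: tpmRatiometry
Title: Ratiometric Two-Photon Microscopy Analysis of Enzyme-Activity Probes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of two-channel two-photon microscopy
    z-stacks acquired with ratiometric enzyme-activity probes
    (beta-galactosidase, carboxylesterase, hNQO1). Computes
    foreground-masked per-voxel Ch2/Ch1 ratio volumes, whole-depth sample
    mean ratios, per-section depth profiles, pseudocolor renderings,
    group discrimination statistics, and first-order kinetics analysis of
    lysate plate-reader time courses. Includes a calibrated
    synthetic-tissue phantom and cohort simulator with gland-structured
    intensity fields, depth attenuation and Poisson noise, used for
    validation in the absence of deposited clinical images.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tiff,
    png,
    jsonlite,
    yaml,
    minpack.lm,
    EBImage,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
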