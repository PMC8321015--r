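Package: vitimap
Title: Semi-Automatic Detection and Population Mapping of Vitiligo Patches in Black-Light Facial Photographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for semi-automatic segmentation of vitiligo patches in
    facial photographs acquired under black-light (Wood's lamp, ~365 nm)
    illumination, where depigmented skin fluoresces and patch contrast is
    concentrated in the blue and green channels. Provides four RGB
    channel-arithmetic contrast filters, per-region adaptive thresholding
    driven by user-annotated polygonal regions of interest, ellipse-based
    normalization of per-patient detections onto a fixed face template,
    population occurrence maps with cohort filtering, overlap-based
    validation against gold-standard masks, a global-threshold stability
    sweep, and a seedable synthetic-face generator with known ground truth
    for end-to-end testing. A command-line interface exposes the full
    pipeline (simulate, detect, aggregate, validate, sweep) over JSON
    session files and CSV metadata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    pracma,
    jsonlite,
    grDevices,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
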