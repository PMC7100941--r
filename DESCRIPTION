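Package: wormescape
Title: High-Content Phenotyping of C. elegans Escape Responses to Targeted Thermal Stimuli
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analysis pipeline for single-worm bright-field recordings of
    Caenorhabditis elegans responding to targeted infrared laser pulses:
    image segmentation (threshold polling, front-propagation refinement,
    loop-aware hole filling), midline skeletonization with head-tail
    correction, eigenworm posture decomposition, phase-velocity estimation
    of the undulatory cycle, four-state ethogram segmentation with minimum
    bout duration, subpixel stage-motion registration, stimulus targeting
    geometry, ratiometric fluorescence thermometry of the laser pulse, and
    stimulus-aligned population summaries. Includes a synthetic locomotion
    generator with ground truth so every stage is testable without external
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    igraph,
    jsonlite,
    yaml,
    pracma,
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
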