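Package: kymoslide
Title: Simulation and Quantification of Antiparallel Microtubule Sliding Kymographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying relative sliding and stalling of antiparallel
    microtubule pairs crosslinked by the PRC1-Kif4A system. Includes a
    mechanistic simulator of overlap-length-dependent sliding with
    length-scaled end-tags and roadblock stalling, a renderer producing noisy
    two-channel TIRF-like kymographs, sub-pixel kymograph quantification
    (edge detection, end-tag segmentation, overlap intensity measurements),
    three-phase velocity segmentation, the saturating velocity-overlap model
    with sliding-efficiency estimation, and the event-level filtering and
    descriptive statistics used to analyse sliding ensembles.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tiff,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
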