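Package: RecoilQuant
Title: Laser-Ablation Recoil Quantification and Tension Inference for
    Epithelial Tissue
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies tissue tension from laser-ablation time-lapse
    recordings of membrane-stained epithelia. Simulates ablation recordings
    with known ground-truth recoil (polygonal cell meshes, damped recoil of
    the cut margins, rigid heartbeat motion artifact, imaging noise),
    measures initial recoil velocity (IRV) from pre/post ablation frame
    pairs (denoising, masked rigid-body registration, cell-vertex point-pair
    tracking, triplicate perpendicular distances), applies measurement
    exclusion rules with a full audit log, and runs variance-gated
    two-sample comparisons across tissue region, ablation orientation,
    embryo sex and developmental stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    EBImage,
    tiff,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
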