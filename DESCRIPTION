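Package: ciliakit
Title: Automated Image Analysis for Airway-on-a-Chip Ciliary Function
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automated computation pipelines for monitoring small-airway
    epithelium cultured on microfluidic chips from time-lapse microscopy.
    Estimates ciliary beating frequency (CBF) per pixel by peak counting of
    high-pass-filtered intensity time series after frame-difference
    localization of beating regions; tracks drifting fluorescent particles to
    quantify mucociliary clearance speed and directionality (rose diagrams)
    with removal of cilia-stuck decoy trajectories; builds tiled, labeled,
    augmented patch datasets with leakage-safe k-fold cross-validation for
    epithelial differentiability prediction; and generates ground-truthed
    synthetic videos and texture tiles so every stage is verifiable by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    grDevices,
    graphics,
    jsonlite,
    png,
    Rcpp,
    signal,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
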