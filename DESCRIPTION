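Package: rmquant
Title: Quantification of Nucleoprotein Condensation, AFM Volumetrics, and
    Single-Molecule Kinetics for Rec114-Mei4 DNA-Binding Assays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Image and table analysis for in vitro studies of the minimal
    Rec114-Mei4 trimerization-and-DNA-binding (RM-TDB) module: AFM height-map
    volumetrics and DNA contour tracing by skeletonization, per-molecule
    protein-particle counting and trimer stoichiometry, condensate core/halo
    morphometry from two-channel confocal images, thresholded foci
    quantification, C50 titration statistics from gel-shift (EMSA) tables,
    and single-exponential dissociation-rate fitting of ROI photon-count
    series from optical-trap scan movies. Seeded synthetic-data generators
    (worm-like-chain DNA rendered as tip-broadened AFM ridges, disc-plus-halo
    condensate scenes, Hill isotherms, exponential photon decays) emulate
    every input so each stage is testable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
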