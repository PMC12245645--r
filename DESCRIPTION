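Package: paoxi
Title: Automated Photoacoustic Brain Oximetry at the Superior Sagittal Sinus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for automatic photoacoustic (PA) monitoring of perinatal
    brain oxygenation. Implements a two-step measurement workflow: a U-Net
    heatmap regressor localizes the superior sagittal sinus (SSS) in
    multiwavelength coronal PA images, and least-squares spectral unmixing
    with depth-dependent attenuation compensation estimates venous oxygen
    saturation (O2Satss) averaged over a grid-search-optimized region of
    interest. Monte Carlo dropout provides per-measurement confidence
    scores. A synthetic multispectral head-phantom generator with known
    SSS location and oxygenation trajectories makes the full pipeline,
    including leave-one-subject-out evaluation and end-to-end CNN
    baselines, exercisable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    EBImage,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
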