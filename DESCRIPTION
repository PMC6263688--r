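Package: thermowelfare
Title: Contactless Rodent Welfare Monitoring from Thermal Video
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Two thermal-imaging pipelines for laboratory-rodent welfare
    assessment. Respiratory rate is estimated without contact from the
    periodic chest-wall motion of an anesthetized animal: Shi-Tomasi
    feature points inside a thorax region of interest are tracked with
    pyramidal Lucas-Kanade optical flow, unstable trajectories are pruned,
    the motion is band-pass filtered to the species' breathing band with
    an equiripple FIR filter, principal-component analysis separates the
    sources, and the most periodic component (peak-to-total spectral
    ratio) yields the rate. Locomotor activity in Open Field tests is
    quantified with a sparse-representation (l1-minimization) particle
    filter tracker, producing velocity series, occupancy heat maps
    (linear and logarithmic) and center/periphery zone metrics. A
    ground-truthed synthetic thermal-scene generator makes every stage
    testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    tiff,
    png,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    withr,
    jsonlite
Config/testthat/edition: 3
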