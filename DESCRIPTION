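Package: autoqc
Title: Reconstruction-Based Automatic Quality Control for High-Throughput
    Microscopy Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised quality control for high-throughput microscopy.
    Trains reconstruction models (autoencoder, variational autoencoder,
    f-AnoGAN, a denoising diffusion model with direct clean-image prediction,
    and a patch-conditioned diffusion variant) on curated normal images only,
    flags abnormal frames through pixel-wise reconstruction-error score maps,
    localizes anomalous regions by learned thresholding, and evaluates
    detections with classification (accuracy, AUROC) and segmentation (Dice,
    AUPRC) metrics. Includes a synthetic brightfield benchmark generator with
    five injectable anomaly classes (air bubbles, dust artifacts, defocus,
    illumination defects, contamination) and exact ground-truth masks, plus a
    curation mode that ranks an unlabeled image pool by anomaly confidence.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    png,
    Rcpp,
    stats,
    tiff,
    tools,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
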