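Package: pemt
Title: Perturbation-Enhanced Mean-Teacher Semi-Supervised Image Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Semi-supervised training of compact 2D encoder-decoder
    segmentation networks with a student/teacher (mean-teacher) pair.
    Implements the perturbation-enhanced exponential moving average (pEMA)
    weight coupling, residual-guided uncertainty maps (RUM) estimated from
    Monte-Carlo dropout forward passes, uncertainty-masked consistency
    losses with ramp-up schedules, overlap and surface-distance evaluation
    metrics (Dice, Jaccard, 95th-percentile Hausdorff, average surface
    distance), and a seeded generator of synthetic 2D segmentation datasets
    with fuzzy, noisy object boundaries for end-to-end experiments on a CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    ggplot2,
    Rcpp,
    stats,
    tibble,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    optparse,
    png,
    RNifti,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
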