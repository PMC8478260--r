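Package: gazeSPRT
Title: Neurally-Constrained SPRT Simulation and Gaze Analytics for Flicker
    Change-Blindness Tasks
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates human gaze during flicker change-blindness trials with a
    neurally-constrained sequential probability ratio test (SPRT) model:
    foveal magnification via a Cartesian variable resolution transform,
    frequency-tuned saliency encoded as bounded Poisson firing rates, a
    Bessel-function likelihood ratio for change versus no change on spike-count
    differences, leaky noisy evidence accumulation against dual decision
    bounds, and a temperature-controlled softmax saccade policy with human
    amplitude/turn-angle biases. Includes the three matched control models,
    parameter-sweep experiments, an inhibition-of-return saliency baseline,
    eye-movement analytics (gaze-feature extraction and selection scores,
    density-filtered fixation clustering with BIC model selection, scanpath
    string edit distances, saccade probability matrices, fixation maps,
    change-proximity profiles) and synthetic generators for flicker image
    pairs and two-group gaze logs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    EBImage,
    farver,
    withr,
    minpack.lm
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Software, Visualization, CellBasedAssays
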