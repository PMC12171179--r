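Package: cadfuse
Title: Multimodal Adaptive-Weight Fusion Models for Coronary Stenosis Risk
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains and inspects a multimodal classifier of coronary artery
    stenosis severity (>=75 percent vs <75 percent) that fuses four data
    streams: tongue photographs, facial photographs, radial pulse pressure
    waveforms and clinical laboratory panels. Each modality is encoded by a
    dedicated branch (a small residual convolutional network with
    self-attention for images, an LSTM for the pulse waveform, a dense
    encoder for screened clinical features) and the branch embeddings are
    combined by a learnable adaptive-weight decision layer. The package
    includes radial pulse waveform preprocessing and fiducial-parameter
    extraction (percussion, tidal and dicrotic wave amplitudes, timings and
    widths), random-forest screening of clinical features, classical
    machine-learning baselines, Grad-CAM and input-gradient saliency for
    interpretation, ablation harnesses over modules, modalities, fusion
    strategies and learning rates, and a class-conditional synthetic cohort
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    png,
    EBImage,
    signal,
    pracma,
    data.table,
    Rcpp,
    jsonlite,
    yaml,
    randomForest,
    e1071,
    class,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
LinkingTo:
    Rcpp,
    RcppArmadillo
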