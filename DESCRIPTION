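Package: vocalmod
Title: Analysis of Ultrasonic-Vocalization-Modulated Neural Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for characterizing how single neurons are
    modulated around rat ultrasonic vocalizations (USVs). Provides a synthetic
    session generator with planted ground truth (USV bouts, inhomogeneous
    Poisson spike trains with multiplicative peri-call gain kernels, and
    optogenetic tagging sessions), a spectrogram-threshold syllable segmenter
    with first/subsequent call splitting and flat/FM call typing, unit quality
    control and spike-width cell typing, peri-event responsiveness testing
    with auROC response normalization, unsupervised response-type discovery
    (PCA, t-SNE, watershed on the embedded density), identification of
    light-responsive units via the stimulus-associated spike latency test
    (SALT), and group-level contingency and permutation statistics with
    odds-ratio confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    Rtsne,
    EBImage,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
Config/testthat/edition: 3
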