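Package: instaspace
Title: Instantaneous Subspaces, Principal Angles, and Latent-Dynamics
    Alignment for Neural Population Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for condition-dependent co-modulation in
    premotor cortex neural populations recorded during a delayed
    reach-grasp-manipulate task performed (execution) or watched
    (observation). Spike trains are binned at 1 ms, smoothed with a
    Gaussian kernel, square-root transformed, aligned to four behavioral
    events and concatenated into per-object units x trials x time tensors.
    From the four object condition means the package identifies a 1 ms time
    series of instantaneous three-dimensional subspaces, tracks their
    progression with principal angles (with bootstrap variability and a
    random-subspace chance calibration), quantifies trajectory-segment
    separation, decodes object identity from latent segments with a compact
    bidirectional LSTM classifier, and aligns latent dynamics across
    sessions, contexts, and neuron classes with a QR+SVD canonical
    correlation bootstrap. A synthetic-session generator with planted
    latent structure provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    data.table,
    nnet
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
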