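Package: reinstatr
Title: Representational Similarity Analysis of Episodic Memory Reinstatement in fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring reinstatement of event-specific spatial
    activity patterns across encoding, immediate retrieval and delayed
    retrieval phases of a video-memory fMRI study. Implements per-trial
    t-statistic pattern estimation from run time series, zero-sum
    same-versus-different and behaviour-weighted RSA contrast matrices,
    volumetric spherical-searchlight and region-of-interest statistics on
    Fisher-transformed pattern correlations, leave-one-out inter-subject
    pattern correlation, sign-flip permutation cluster-extent family-wise
    error correction, and behavioural scoring statistics. A synthetic-study
    generator with known ground-truth reinstatement structure makes every
    stage testable without access to raw imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
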