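Package: middecode
Title: Time-Resolved EEG Decoding of Motion-in-Depth Cues
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multivariate pattern analysis of EEG responses to
    stereoscopic motion-in-depth stimuli. Builds geometrically faithful
    changing-disparity (CD), interocular-velocity-difference (IOVD) and
    static-disparity random-dot stereogram sequences; simulates 64-channel
    EEG sessions with condition-locked spatiotemporal components embedded in
    1/f, alpha and sensor noise; preprocesses epochs (30 Hz low-pass,
    linear-interpolation downsampling, z-scoring); forms bootstrap-averaged
    pseudo-epochs; decodes condition pairs per timepoint with a linear
    support vector machine (within-cue, pooled, cross-trained and relabeled
    controls); and assesses group-level significance with cluster-mass
    sign-flip permutation tests and a Bonferroni alternative.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
LinkingTo:
    Rcpp
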