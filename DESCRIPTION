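Package: saipai
Title: Instantaneous Sympathetic and Parasympathetic Activity Indices
    from Heartbeat Point Processes, with fMRI Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates time-resolved sympathetic (SAI) and parasympathetic
    (PAI) autonomic activity indices from heartbeat event series using an
    inverse-Gaussian point-process model whose mean heart period is an
    orthonormal Laguerre expansion of past intervals, fitted by local
    maximum likelihood on a sliding window.  Includes pulse-waveform beat
    detection and artifact correction, goodness-of-fit by the
    time-rescaling theorem, construction of hemodynamically convolved
    fMRI regressors from the indices, a three-level voxelwise GLM with
    sign-flip permutation cluster correction for mapping central autonomic
    networks, and synthetic-data generators (integral pulse frequency
    modulation heartbeats, pulse waveforms, BOLD volumes with planted
    autonomic coupling) for validation at desk scale.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    igraph,
    jsonlite,
    pracma,
    RNifti,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
LinkingTo:
    Rcpp,
    RcppArmadillo
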