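Package: envhmm
Title: Transient Whole-Brain States from Band-Limited Amplitude Envelopes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Discovery of fast transient whole-brain states from band-limited
    oscillatory amplitude envelopes. Implements a variational-Bayes hidden
    Markov model with multivariate-normal observation models over
    PCA-whitened, group-concatenated envelope data, together with the
    surrounding machinery: LCMV scalar beamformer projection with
    projected-noise normalization, Hilbert amplitude envelopes with
    windowed downsampling and spatial smoothing, Viterbi state paths and
    their temporal summary statistics (fractional occupancy, life times,
    interval lengths), partial-correlation spatial maps via a GLM on state
    indicators, timescale analyses of fractional-occupancy regressors, and
    seedable synthetic-data generators for all of the above.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    RNifti,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
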