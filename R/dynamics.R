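#' Representative voxel of a state
#'
#' The voxel whose envelope most (positively) correlates with the state's
#' time course: the argmax of the state's partial-correlation map, ties
#' broken to the lowest voxel index.
#'
#' @param map a [partial_correlation_maps()] result.
#' @param k state index.
#' @return voxel index.
#' @export
representative_voxel <- function(map, k) {
  stopifnot(inherits(map, "partial_correlation_map"))
  v <- map$coefficients[k, ]
  if (all(is.na(v))) stop("state ", k, " has no map (absent from the path)")
  which.max(v)
}

#' Fractional-occupancy window-width sweep
#'
#' For each candidate window width, computes the state's fractional
#' occupancy within a sliding window stepping one sample at a time (so the
#' regressor shares the envelope's time base), aligns it to the envelope
#' sample at the window center, and records the Pearson correlation (the
#' single-regressor GLM fit on z-scored series). The width with the
#' highest correlation indicates the timescale at which state occupancy
#' best explains the envelope.
#'
#' @param path a [state_path()].
#' @param k state index.
#' @param envelope_voxel_ts envelope time course at one voxel, same length
#'   and rate as the path.
#' @param widths window widths in seconds; defaults to a logarithmic grid
#'   over 0.1--8 s.
#' @return object of class `window_sweep`: `widths`, `correlations`,
#'   `argmax_width`.
#' @export
fo_window_sweep <- function(path, k, envelope_voxel_ts,
                            widths = default_sweep_widths()) {
  pm <- path_meta(path)
  x <- as.numeric(envelope_voxel_ts)
  if (length(x) != length(pm$states))
    stop("envelope and path lengths differ")
  if (any(diff(widths) <= 0)) stop("widths must be strictly increasing")
  ind <- as.numeric(pm$states == k)
  cors <- vapply(widths, function(w) {
    wsamp <- as.integer(round(w * pm$sampling_rate))
    if (wsamp < 1L) stop("window width ", w, " s is shorter than one sample")
    if (wsamp > length(x)) stop("window width ", w, " s exceeds the series")
    reg <- windowed_means(ind, wsamp, 1L)
    centers <- window_starts(length(x), wsamp, 1L) + (wsamp - 1L) %/% 2L
    if (stats::sd(reg) == 0) return(NA_real_)
    stats::cor(reg, x[centers])
  }, numeric(1))
  structure(list(widths = widths, correlations = cors,
                 argmax_width = widths[which.max(cors)]),
            class = "window_sweep")
}

#' Default logarithmic sweep grid over 0.1--8 s
#'
#' @param n number of grid points (default 15).
#' @return numeric vector of widths in seconds.
#' @export
default_sweep_widths <- function(n = 15) {
  exp(seq(log(0.1), log(8), length.out = n))
}

#' Low-pass filter an envelope dataset
#'
#' Zero-phase Butterworth low-pass applied to each voxel's envelope, used
#' as the slow-dynamics control (e.g. a 0.5 Hz cutoff removes the fast
#' envelope fluctuations).
#'
#' @param dataset an [envelope_dataset()].
#' @param cutoff_hz cutoff frequency in Hz.
#' @param order filter order (default 5).
#' @return filtered [envelope_dataset()] (marked normalized, as filtering
#'   can produce small negative values).
#' @export
lowpass_envelopes <- function(dataset, cutoff_hz, order = 5) {
  stopifnot(inherits(dataset, "envelope_dataset"))
  out <- dataset
  out$data <- lowpass(dataset$data, dataset$sampling_rate, cutoff_hz, order)
  out$normalized <- TRUE
  out
}

#' Add band-limited Gaussian noise to an envelope dataset
#'
#' Adds seeded Gaussian noise low-passed at `cutoff_hz` (reflecting the
#' spectral content of envelope data) and rescaled per voxel to standard
#' deviation `noise_sd` after filtering. `noise_sd = 0` is the identity.
#'
#' @param dataset an [envelope_dataset()].
#' @param cutoff_hz low-pass cutoff for the noise in Hz.
#' @param noise_sd post-filter standard deviation of the added noise.
#' @param seed integer seed.
#' @return noisy [envelope_dataset()] (marked normalized).
#' @export
add_bandlimited_noise <- function(dataset, cutoff_hz, noise_sd, seed = 1L) {
  stopifnot(inherits(dataset, "envelope_dataset"))
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (noise_sd == 0) return(dataset)
  V <- nrow(dataset$data); Tn <- ncol(dataset$data)
  set.seed(seed)
  noise <- matrix(stats::rnorm(V * Tn), V, Tn)
  noise <- lowpass(noise, dataset$sampling_rate, cutoff_hz)
  sds <- apply(noise, 1L, stats::sd)
  noise <- noise * (noise_sd / sds)
  out <- dataset
  out$data <- dataset$data + noise
  out$normalized <- TRUE
  out
}

#' Sliding-window envelope correlation
#'
#' Pearson correlation between two time courses within each sliding window
#' (default 10 s, 75% overlap); trailing partial windows are dropped.
#'
#' @param ts_a,ts_b numeric vectors of equal length.
#' @param window_s window width in seconds (default 10).
#' @param overlap_fraction overlap between adjacent windows (default 0.75).
#' @param sampling_rate sampling rate in Hz.
#' @return object of class `sliding_correlation`: `correlations`,
#'   `starts`, `window_s`, `overlap_fraction`, `sampling_rate`.
#' @export
sliding_envelope_correlation <- function(ts_a, ts_b, window_s = 10,
                                         overlap_fraction = 0.75,
                                         sampling_rate = 40) {
  a <- as.numeric(ts_a); b <- as.numeric(ts_b)
  if (length(a) != length(b)) stop("time courses must have equal lengths")
  ws <- window_samples(sampling_rate, window_s, overlap_fraction)
  starts <- window_starts(length(a), ws$width, ws$step)
  cors <- vapply(starts, function(s) {
    idx <- s:(s + ws$width - 1L)
    suppressWarnings(stats::cor(a[idx], b[idx]))
  }, numeric(1))
  structure(list(correlations = cors, starts = starts, window_s = window_s,
                 overlap_fraction = overlap_fraction,
                 sampling_rate = sampling_rate),
            class = "sliding_correlation")
}

#' Correlate fractional occupancy with sliding envelope correlation
#'
#' Pearson correlation between a state's within-window fractional
#' occupancy and a sliding-window envelope-correlation time course
#' computed with identical window settings.
#'
#' @param fo_tc_for_state numeric vector: one state's column of an
#'   [fo_timecourse()] occupancy matrix (or any window-level series).
#' @param envcorr_tc numeric vector: the `correlations` of a
#'   [sliding_envelope_correlation()] with matching windows.
#' @return scalar Pearson correlation.
#' @export
compare_fo_envcorr <- function(fo_tc_for_state, envcorr_tc) {
  a <- as.numeric(fo_tc_for_state); b <- as.numeric(envcorr_tc)
  if (length(a) != length(b))
    stop("series lengths differ; both inputs must use identical windows")
  stats::cor(a, b)
}
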