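#' Zero-phase band-pass filter
#'
#' Butterworth band-pass applied forward and backward (`signal::filtfilt`)
#' for zero phase distortion. Operates on a numeric vector or on each row of
#' a matrix (rows are time series).
#'
#' @param ts numeric vector or matrix (series x time).
#' @param sampling_rate sampling rate in Hz.
#' @param low_hz,high_hz band edges, `0 < low < high < Nyquist`.
#' @param order Butterworth order (default 5).
#' @return filtered series, same shape as the input.
#' @export
bandpass <- function(ts, sampling_rate, low_hz = 4, high_hz = 30, order = 5) {
  nyq <- sampling_rate / 2
  if (low_hz <= 0 || high_hz <= low_hz || high_hz >= nyq)
    stop("band edges must satisfy 0 < low < high < Nyquist (", nyq, " Hz)")
  bf <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  apply_filter_rows(ts, bf)
}

#' Zero-phase low-pass filter
#'
#' @inheritParams bandpass
#' @param cutoff_hz cutoff frequency, `0 < cutoff < Nyquist`.
#' @return filtered series, same shape as the input.
#' @export
lowpass <- function(ts, sampling_rate, cutoff_hz, order = 5) {
  nyq <- sampling_rate / 2
  if (cutoff_hz <= 0 || cutoff_hz >= nyq)
    stop("cutoff must lie in (0, Nyquist)")
  bf <- signal::butter(order, cutoff_hz / nyq, type = "low")
  apply_filter_rows(ts, bf)
}

apply_filter_rows <- function(ts, bf) {
  if (is.matrix(ts)) {
    out <- t(apply(ts, 1L, function(x) filtfilt_zi(bf, x)))
    dimnames(out) <- dimnames(ts)
    out
  } else {
    filtfilt_zi(bf, as.numeric(ts))
  }
}

# Zero-phase forward-backward filtering with odd-reflection padding and
# steady-state initial conditions (the classic filtfilt edge handling).
# signal::filtfilt starts both passes from a zero state, which leaves long
# edge transients for narrow-band filters; this version is transient-free
# (a constant input passes through a low-pass exactly).
filtfilt_zi <- function(bf, x) {
  b <- bf$b; a <- bf$a
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b))) / a[1L]
  a <- c(a, rep(0, n - length(a))) / a[1L]
  zi <- lfilter_zi(b, a)
  nfact <- min(3L * (n - 1L), length(x) - 1L)
  pre <- 2 * x[1L] - x[(nfact + 1L):2L]
  post <- 2 * x[length(x)] - x[(length(x) - 1L):(length(x) - nfact)]
  xx <- c(pre, x, post)
  y <- iir_filter_cpp(b, a, xx, zi * xx[1L])
  y <- rev(iir_filter_cpp(b, a, rev(y), zi * y[length(y)]))
  y[(nfact + 1L):(nfact + length(x))]
}

# steady-state state vector of the direct-form-II-transposed filter for a
# unit step input (so that zi * x[1] removes the startup transient)
lfilter_zi <- function(b, a) {
  n <- length(a)
  A <- cbind(-a[-1L], rbind(diag(n - 2L), 0))
  B <- b[-1L] - a[-1L] * b[1L]
  solve(diag(n - 1L) - A, B)
}

#' Amplitude envelope via the Hilbert transform
#'
#' Pointwise magnitude of the analytic signal, computed in the frequency
#' domain (positive frequencies doubled, negative zeroed). No installed
#' package exposes the analytic-signal construction, so it is implemented
#' directly on top of [stats::fft()].
#'
#' @param ts numeric vector or matrix (series x time).
#' @return non-negative envelope, same shape as the input.
#' @export
hilbert_envelope <- function(ts) {
  if (is.matrix(ts)) {
    out <- t(apply(ts, 1L, hilbert_envelope_vec))
    dimnames(out) <- dimnames(ts)
    return(out)
  }
  hilbert_envelope_vec(as.numeric(ts))
}

hilbert_envelope_vec <- function(x) {
  if (any(!is.finite(x))) stop("input must be finite")
  n <- length(x)
  f <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1L, n / 2 + 1L)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1
    if (n > 1L) h[2:((n + 1L) / 2)] <- 2
  }
  Mod(stats::fft(f * h, inverse = TRUE) / n)
}

#' Downsample by averaging within sliding windows
#'
#' Each output sample is the arithmetic mean of one sliding window of the
#' input; trailing windows that would be incomplete are dropped. With a
#' 100 ms window and 75% overlap on 200 Hz input the output rate is
#' `1 / (window_s * (1 - overlap)) = 40` Hz.
#'
#' @param envelope numeric vector or matrix (series x time).
#' @param sampling_rate input sampling rate in Hz.
#' @param window_s window width in seconds.
#' @param overlap_fraction overlap between consecutive windows in `[0, 1)`.
#' @return list with `data` (downsampled series, same orientation) and
#'   `sampling_rate` (the output rate in Hz).
#' @export
window_downsample <- function(envelope, sampling_rate, window_s = 0.1,
                              overlap_fraction = 0.75) {
  ws <- window_samples(sampling_rate, window_s, overlap_fraction)
  out_rate <- sampling_rate / ws$step
  if (is.matrix(envelope)) {
    out <- t(apply(envelope, 1L, windowed_means, width = ws$width,
                   step = ws$step))
    rownames(out) <- rownames(envelope)
  } else {
    out <- windowed_means(as.numeric(envelope), ws$width, ws$step)
  }
  list(data = out, sampling_rate = out_rate)
}

#' Spatial Gaussian smoothing over voxels
#'
#' Replaces each voxel by a Gaussian-weighted average of all voxels, with
#' `sigma = fwhm / (2 sqrt(2 ln 2))` and weights normalized to sum to one
#' per voxel. Requires voxel coordinates. `fwhm_mm <= 0` is the identity.
#'
#' @param dataset an [envelope_dataset()] with `voxel_coords`.
#' @param fwhm_mm kernel full width at half maximum in mm (default 9.4).
#' @return smoothed [envelope_dataset()].
#' @export
spatial_smooth <- function(dataset, fwhm_mm = 9.4) {
  stopifnot(inherits(dataset, "envelope_dataset"))
  if (fwhm_mm <= 0) return(dataset)
  if (is.null(dataset$voxel_coords))
    stop("spatial smoothing requires voxel coordinates")
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2)))
  d2 <- as.matrix(stats::dist(dataset$voxel_coords))^2
  W <- exp(-d2 / (2 * sigma^2))
  W <- W / rowSums(W)
  out <- dataset
  smoothed <- W %*% dataset$data
  dimnames(smoothed) <- dimnames(dataset$data)
  out$data <- smoothed
  out
}

#' Demean, variance-normalize and concatenate per-subject envelopes
#'
#' Per subject: subtract each voxel's mean, then divide all voxels by the
#' single global standard deviation pooled over voxels and samples (so each
#' subject block has pooled variance 1). Blocks are concatenated in order
#' and the cumulative segment boundaries recorded.
#'
#' @param datasets list of per-subject [envelope_dataset()] objects with
#'   equal voxel counts and sampling rates.
#' @return a group-level [envelope_dataset()] with `normalized = TRUE`.
#' @export
normalize_and_concatenate <- function(datasets) {
  stopifnot(length(datasets) >= 1L,
            all(vapply(datasets, inherits, TRUE, "envelope_dataset")))
  V <- nrow(datasets[[1L]]$data)
  fs <- datasets[[1L]]$sampling_rate
  for (d in datasets) {
    if (nrow(d$data) != V) stop("all subjects must share the voxel count")
    if (d$sampling_rate != fs)
      stop("all subjects must share the sampling rate")
  }
  blocks <- lapply(datasets, function(d) {
    X <- d$data - rowMeans(d$data)
    g <- stats::sd(as.numeric(X))
    if (g == 0) stop("a subject has zero global variance")
    X / g
  })
  data <- do.call(cbind, blocks)
  lens <- vapply(datasets, function(d) ncol(d$data), integer(1))
  envelope_dataset(data, sampling_rate = fs,
                   voxel_coords = datasets[[1L]]$voxel_coords,
                   segment_boundaries = cumsum(lens), normalized = TRUE)
}

#' Envelope preparation pipeline for one subject
#'
#' Fixed-order preparation of band-limited source time courses into
#' downsampled, optionally smoothed amplitude envelopes:
#' band-pass -> Hilbert envelope -> windowed downsampling -> spatial
#' smoothing. Normalization and concatenation across subjects is performed
#' separately by [normalize_and_concatenate()].
#'
#' @param source_ts V x T matrix of source time courses.
#' @param sampling_rate input rate in Hz.
#' @param band band edges in Hz (default `c(4, 30)`).
#' @param window_s,overlap_fraction downsampling window (defaults 0.1 s,
#'   0.75).
#' @param fwhm_mm smoothing kernel FWHM in mm; 0 disables. Requires
#'   `voxel_coords`.
#' @param voxel_coords optional V x 3 voxel coordinates.
#' @return an [envelope_dataset()] at the downsampled rate.
#' @export
prepare_envelopes <- function(source_ts, sampling_rate, band = c(4, 30),
                              window_s = 0.1, overlap_fraction = 0.75,
                              fwhm_mm = 0, voxel_coords = NULL) {
  x <- bandpass(as.matrix(source_ts), sampling_rate, band[1L], band[2L])
  env <- hilbert_envelope(x)
  ds <- window_downsample(env, sampling_rate, window_s, overlap_fraction)
  out <- envelope_dataset(ds$data, sampling_rate = ds$sampling_rate,
                          voxel_coords = voxel_coords)
  if (fwhm_mm > 0) out <- spatial_smooth(out, fwhm_mm)
  out
}
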