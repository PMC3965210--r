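#' Sliding-window start indices
#'
#' The single windowing utility shared by every windowed operation in the
#' package (envelope downsampling, fractional-occupancy time courses,
#' sliding envelope correlations). Windows cover samples
#' `[start, start + width - 1]`; a trailing window that would run past the
#' end of the series is dropped rather than padded.
#'
#' @param n number of samples.
#' @param width window width in samples (>= 1).
#' @param step step between window starts in samples (>= 1).
#' @return integer vector of window start indices (possibly empty).
#' @export
window_starts <- function(n, width, step) {
  width <- as.integer(round(width)); step <- as.integer(round(step))
  if (width < 1L) stop("window width must be at least one sample")
  if (step < 1L) stop("window step must be at least one sample")
  if (width > n) return(integer(0))
  seq.int(1L, n - width + 1L, by = step)
}

# width/step in samples from seconds + overlap fraction
window_samples <- function(sampling_rate, window_s, overlap_fraction) {
  if (overlap_fraction < 0 || overlap_fraction >= 1)
    stop("overlap_fraction must be in [0, 1)")
  width <- as.integer(round(window_s * sampling_rate))
  if (width < 1L) stop("window shorter than one sample")
  step <- as.integer(round(width * (1 - overlap_fraction)))
  if (step < 1L) stop("window step below one sample; reduce the overlap")
  list(width = width, step = step)
}

# mean of x within each window; x a vector
windowed_means <- function(x, width, step) {
  starts <- window_starts(length(x), width, step)
  cs <- cumsum(c(0, x))
  (cs[starts + width] - cs[starts]) / width
}
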