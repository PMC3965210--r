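#' Envelope dataset container
#'
#' Holds a voxels-by-time matrix of oscillatory amplitude envelopes together
#' with its sampling rate, optional voxel coordinates (mm) and the sample
#' indices at which the concatenated per-subject segments end.
#'
#' @param data numeric matrix, V voxels x T samples.
#' @param sampling_rate sampling rate in Hz (40 after the standard windowed
#'   downsampling).
#' @param voxel_coords optional V x 3 matrix of voxel coordinates in mm.
#' @param segment_boundaries integer vector of cumulative segment end
#'   indices (strictly increasing, last element equal to `ncol(data)`).
#'   Defaults to a single segment.
#' @param normalized logical; `TRUE` once per-subject demeaning/variance
#'   normalization has been applied (values may then be negative). Raw
#'   envelopes must be non-negative.
#' @return an object of class `envelope_dataset`.
#' @export
envelope_dataset <- function(data, sampling_rate, voxel_coords = NULL,
                             segment_boundaries = ncol(data),
                             normalized = FALSE) {
  data <- as.matrix(data)
  if (!is.numeric(data) || any(!is.finite(data)))
    stop("envelope data must be a finite numeric matrix")
  if (!normalized && any(data < 0))
    stop("raw amplitude envelopes must be non-negative")
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      sampling_rate <= 0)
    stop("sampling_rate must be a positive scalar")
  segment_boundaries <- as.integer(segment_boundaries)
  check_segment_boundaries(segment_boundaries, ncol(data))
  if (!is.null(voxel_coords)) {
    voxel_coords <- as.matrix(voxel_coords)
    if (nrow(voxel_coords) != nrow(data) || ncol(voxel_coords) != 3L)
      stop("voxel_coords must be a V x 3 matrix matching the data")
  }
  structure(
    list(data = data, sampling_rate = sampling_rate,
         voxel_coords = voxel_coords,
         segment_boundaries = segment_boundaries,
         normalized = normalized),
    class = "envelope_dataset")
}

#' @export
print.envelope_dataset <- function(x, ...) {
  cat(sprintf("<envelope_dataset> %d voxels x %d samples @ %g Hz, %d segment(s)%s\n",
              nrow(x$data), ncol(x$data), x$sampling_rate,
              length(x$segment_boundaries),
              if (x$normalized) ", normalized" else ""))
  invisible(x)
}

#' Hard state path container
#'
#' A per-sample hard state assignment (e.g. a Viterbi decoding), carrying the
#' sampling rate and subject segment boundaries needed by the temporal
#' summary statistics.
#'
#' @param states integer vector of states in `1..K`.
#' @param sampling_rate sampling rate in Hz.
#' @param segment_boundaries cumulative segment end indices; defaults to a
#'   single segment.
#' @param K number of states (defaults to `max(states)`).
#' @return an object of class `state_path`.
#' @export
state_path <- function(states, sampling_rate = 1,
                       segment_boundaries = length(states),
                       K = max(states)) {
  states <- as.integer(states)
  if (length(states) < 1L) stop("states must contain at least one sample")
  if (any(is.na(states)) || any(states < 1L) || any(states > K))
    stop("states must be integers in 1..K")
  segment_boundaries <- as.integer(segment_boundaries)
  check_segment_boundaries(segment_boundaries, length(states))
  structure(
    list(states = states, sampling_rate = sampling_rate,
         segment_boundaries = segment_boundaries, K = as.integer(K)),
    class = "state_path")
}

#' @export
print.state_path <- function(x, ...) {
  cat(sprintf("<state_path> %d samples, K = %d, %g Hz, %d segment(s)\n",
              length(x$states), x$K, x$sampling_rate,
              length(x$segment_boundaries)))
  invisible(x)
}

#' Sensor-level recording container
#'
#' @param data numeric matrix, N channels x T samples.
#' @param sampling_rate sampling rate in Hz.
#' @return an object of class `sensor_recording`.
#' @export
sensor_recording <- function(data, sampling_rate = 1) {
  data <- as.matrix(data)
  if (any(!is.finite(data))) stop("sensor data must be finite")
  if (nrow(data) < 2L) stop("a sensor recording needs at least 2 channels")
  structure(list(data = data, sampling_rate = sampling_rate,
                 channel_count = nrow(data)),
            class = "sensor_recording")
}

# --- internal helpers -------------------------------------------------------

check_segment_boundaries <- function(b, n) {
  if (length(b) < 1L || any(diff(b) <= 0L) || b[1L] < 1L || b[length(b)] != n)
    stop("segment_boundaries must be strictly increasing and end at the ",
         "number of samples (", n, ")")
  invisible(b)
}

# segment start indices from cumulative end indices
segment_starts <- function(boundaries) {
  c(1L, utils::head(boundaries, -1L) + 1L)
}

as_data_matrix <- function(x) {
  if (inherits(x, "envelope_dataset")) x$data else as.matrix(x)
}

as_states <- function(path) {
  if (inherits(path, "state_path")) path$states else as.integer(path)
}

path_meta <- function(path, sampling_rate = NULL, segment_boundaries = NULL,
                      K = NULL) {
  if (inherits(path, "state_path")) {
    list(states = path$states,
         sampling_rate = sampling_rate %||% path$sampling_rate,
         segment_boundaries = segment_boundaries %||% path$segment_boundaries,
         K = K %||% path$K)
  } else {
    s <- as.integer(path)
    list(states = s, sampling_rate = sampling_rate %||% 1,
         segment_boundaries = segment_boundaries %||% length(s),
         K = K %||% max(s))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
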