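#' Number of occurrences of a state
#'
#' Counts entries into state `k` along the path:
#' `sum_t ((u_t == k) - (u_(t-1) == k)) == 1`. The virtual sample before
#' the first sample of each subject segment is treated as "not k", so a
#' run that opens a segment counts as an occurrence.
#'
#' @param path a [state_path()] or integer vector.
#' @param k state index in `1..K`; when missing, a K-vector over all
#'   states is returned.
#' @return integer count (or K-vector of counts).
#' @export
number_of_occurrences <- function(path, k) {
  pm <- path_meta(path)
  if (missing(k))
    return(vapply(seq_len(pm$K), function(kk)
      number_of_occurrences(path, kk), integer(1)))
  if (k < 1L || k > pm$K) stop("k must lie in 1..", pm$K)
  ind <- as.integer(pm$states == k)
  starts <- segment_starts(pm$segment_boundaries)
  prev <- c(0L, ind[-length(ind)])
  prev[starts] <- 0L
  sum((ind - prev) == 1L)
}

#' Fractional occupancy
#'
#' Fraction of samples spent in each state, `(1/T) sum_t (u_t == k)`.
#'
#' @param path a [state_path()] or integer vector.
#' @return K-vector summing to 1.
#' @export
fractional_occupancy <- function(path) {
  pm <- path_meta(path)
  tabulate(pm$states, nbins = pm$K) / length(pm$states)
}

#' Mean life time of a state
#'
#' Average dwell time per visit: total samples in the state divided by its
#' number of occurrences, converted to seconds by the sampling rate.
#' `NA` when the state never occurs.
#'
#' @inheritParams number_of_occurrences
#' @return seconds (scalar, or K-vector when `k` is missing).
#' @export
mean_life_time <- function(path, k) {
  pm <- path_meta(path)
  if (missing(k))
    return(vapply(seq_len(pm$K), function(kk)
      mean_life_time(path, kk), numeric(1)))
  occ <- number_of_occurrences(path, k)
  if (occ == 0L) return(NA_real_)
  dwell <- sum(pm$states == k)
  (dwell / occ) / pm$sampling_rate
}

#' Mean interval length of a state
#'
#' The time spent out of a state per visit, by the printed formula
#' `(T - sum_t(u_t == k)) / occurrences(k)`, converted to seconds. Note
#' this differs from the literal mean gap between consecutive visits (see
#' [mean_gap_between_visits()]). `NA` when the state never occurs.
#'
#' @inheritParams number_of_occurrences
#' @return seconds (scalar, or K-vector when `k` is missing).
#' @export
mean_interval_length <- function(path, k) {
  pm <- path_meta(path)
  if (missing(k))
    return(vapply(seq_len(pm$K), function(kk)
      mean_interval_length(path, kk), numeric(1)))
  occ <- number_of_occurrences(path, k)
  if (occ == 0L) return(NA_real_)
  ((length(pm$states) - sum(pm$states == k)) / occ) / pm$sampling_rate
}

#' Literal mean gap between consecutive visits
#'
#' Auxiliary statistic: the arithmetic mean of the actual gaps separating
#' consecutive visits to state `k` within each segment (gaps before the
#' first and after the last visit are not gaps *between* visits and are
#' excluded). `NA` when fewer than two visits exist.
#'
#' @inheritParams number_of_occurrences
#' @return seconds (scalar, or K-vector when `k` is missing).
#' @export
mean_gap_between_visits <- function(path, k) {
  pm <- path_meta(path)
  if (missing(k))
    return(vapply(seq_len(pm$K), function(kk)
      mean_gap_between_visits(path, kk), numeric(1)))
  starts <- segment_starts(pm$segment_boundaries)
  gaps <- numeric(0)
  for (s in seq_along(starts)) {
    seg <- pm$states[starts[s]:pm$segment_boundaries[s]]
    r <- rle(seg == k)
    on <- which(r$values)
    if (length(on) >= 2L) {
      between <- setdiff(seq.int(min(on), max(on)), on)
      # runs of FALSE strictly between two TRUE runs
      gaps <- c(gaps, r$lengths[between])
    }
  }
  if (!length(gaps)) return(NA_real_)
  mean(gaps) / pm$sampling_rate
}

#' Temporal summary statistics of a state path
#'
#' @param path a [state_path()].
#' @return data.frame with one row per state: `state`,
#'   `fractional_occupancy`, `mean_life_time_s`, `mean_interval_length_s`,
#'   `number_of_occurrences`.
#' @export
summary_stats <- function(path) {
  pm <- path_meta(path)
  data.frame(state = seq_len(pm$K),
             fractional_occupancy = fractional_occupancy(path),
             mean_life_time_s = mean_life_time(path),
             mean_interval_length_s = mean_interval_length(path),
             number_of_occurrences = number_of_occurrences(path))
}

#' Fractional-occupancy time course
#'
#' Within-window occupancy of each state along a sliding window (default
#' 10 s with 75% overlap): per window, the mean of each state's indicator.
#' Trailing partial windows are dropped. Rows sum to 1.
#'
#' @param path a [state_path()] (its sampling rate sets the window size in
#'   samples).
#' @param window_s window width in seconds (default 10).
#' @param overlap_fraction overlap between adjacent windows (default 0.75).
#' @return object of class `fo_timecourse`: `occupancy` (windows x K),
#'   `window_s`, `overlap_fraction`, `starts` (window start samples),
#'   `sampling_rate`.
#' @export
fo_timecourse <- function(path, window_s = 10, overlap_fraction = 0.75) {
  pm <- path_meta(path)
  ws <- window_samples(pm$sampling_rate, window_s, overlap_fraction)
  starts <- window_starts(length(pm$states), ws$width, ws$step)
  ind <- outer(pm$states, seq_len(pm$K), `==`) * 1
  occ <- vapply(seq_len(pm$K), function(k)
    windowed_means(ind[, k], ws$width, ws$step), numeric(length(starts)))
  occ <- matrix(occ, nrow = length(starts), ncol = pm$K)
  structure(list(occupancy = occ, window_s = window_s,
                 overlap_fraction = overlap_fraction, starts = starts,
                 sampling_rate = pm$sampling_rate),
            class = "fo_timecourse")
}

#' Correlation matrix between fractional-occupancy time courses
#'
#' Pearson correlations between the per-state within-window occupancy
#' series; symmetric with unit diagonal.
#'
#' @param fotc an [fo_timecourse()].
#' @return K x K correlation matrix.
#' @export
fo_correlation_matrix <- function(fotc) {
  stopifnot(inherits(fotc, "fo_timecourse"))
  stats::cor(fotc$occupancy)
}

#' Transition probability matrix
#'
#' From a fitted model: the posterior expected transition matrix. From a
#' state path: empirical within-segment transition frequencies (counts of
#' `i -> j` normalized per row; transitions across segment boundaries are
#' not counted). Optionally the diagonal (probability of remaining in the
#' same state) is masked with `NA`, without renormalizing the rows.
#'
#' @param x an `hmm_model` or a [state_path()].
#' @param mask_diagonal logical; mask self-transitions with `NA`.
#' @return K x K matrix.
#' @export
transition_probability_matrix <- function(x, mask_diagonal = FALSE) {
  if (inherits(x, "hmm_model")) {
    A <- expected_transition_matrix(x)
  } else {
    pm <- path_meta(x)
    K <- pm$K
    counts <- matrix(0, K, K)
    starts <- segment_starts(pm$segment_boundaries)
    for (s in seq_along(starts)) {
      seg <- pm$states[starts[s]:pm$segment_boundaries[s]]
      if (length(seg) > 1L) {
        from <- factor(seg[-length(seg)], levels = seq_len(K))
        to <- factor(seg[-1L], levels = seq_len(K))
        counts <- counts + unclass(table(from, to))
      }
    }
    A <- counts / pmax(rowSums(counts), 1)
  }
  if (mask_diagonal) diag(A) <- NA_real_
  A
}
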