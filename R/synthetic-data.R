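#' Ground truth for synthetic HMM data
#'
#' Bundles the generative parameters of a Markov-switching multivariate
#' normal model: transition matrix, initial state probabilities, per-state
#' means and covariances, and (for the envelope simulator) non-negative
#' per-state amplitude topographies.
#'
#' @param transition_matrix K x K row-stochastic matrix.
#' @param initial_probs K-vector summing to 1.
#' @param state_means K x M matrix of state means.
#' @param state_covs list of K symmetric positive semi-definite M x M
#'   covariance matrices.
#' @param topographies optional K x V non-negative amplitude-gain matrix.
#' @param seed integer seed recorded with the ground truth.
#' @return an object of class `ground_truth`.
#' @export
ground_truth <- function(transition_matrix, initial_probs, state_means,
                         state_covs, topographies = NULL, seed = 1L) {
  transition_matrix <- as.matrix(transition_matrix)
  K <- nrow(transition_matrix)
  check_stochastic_matrix(transition_matrix)
  initial_probs <- as.numeric(initial_probs)
  if (length(initial_probs) != K || any(initial_probs < 0) ||
      abs(sum(initial_probs) - 1) > 1e-12)
    stop("initial_probs must be a length-K probability vector summing to 1")
  state_means <- as.matrix(state_means)
  if (nrow(state_means) != K) stop("state_means must have K rows")
  if (!is.list(state_covs) || length(state_covs) != K)
    stop("state_covs must be a list of K covariance matrices")
  M <- ncol(state_means)
  for (k in seq_len(K)) {
    S <- as.matrix(state_covs[[k]])
    if (!isTRUE(all.equal(S, t(S), tolerance = 1e-10)))
      stop("state covariance ", k, " is not symmetric")
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-10 * max(abs(ev), 1))
      stop("state covariance ", k, " is not positive semi-definite")
    state_covs[[k]] <- S
  }
  if (!is.null(topographies)) {
    topographies <- as.matrix(topographies)
    if (nrow(topographies) != K) stop("topographies must have K rows")
    if (any(topographies < 0))
      stop("topographies must be non-negative amplitude gains")
  }
  structure(list(transition_matrix = transition_matrix,
                 initial_probs = initial_probs,
                 state_means = state_means, state_covs = state_covs,
                 topographies = topographies,
                 K = K, M = M, seed = as.integer(seed)),
            class = "ground_truth")
}

check_stochastic_matrix <- function(A, tol = 1e-12) {
  if (nrow(A) != ncol(A)) stop("transition matrix must be square")
  if (any(A < 0)) stop("transition matrix entries must be non-negative")
  bad <- which(abs(rowSums(A) - 1) > tol)
  if (length(bad))
    stop("transition matrix row(s) ", paste(bad, collapse = ", "),
         " do not sum to 1")
  invisible(A)
}

#' Canonical parameter-recovery ground truth
#'
#' A reference Markov-switching Gaussian fixture for recovery studies:
#' persistent states (self-transition `diag_p`, off-diagonal mass spread
#' uniformly), means placed at exact unit pairwise separation (scaled
#' standard basis vectors), and per-state covariances
#' `noise_scale^2 (I + u_k u_k')` with a seeded random unit vector `u_k`,
#' so each state carries a distinct correlation structure and the means
#' sit roughly `1 / noise_scale` noise standard deviations apart.
#'
#' @param K number of states (<= M).
#' @param M observation dimensionality.
#' @param diag_p self-transition probability (default 0.9).
#' @param separation pairwise distance between state means (default 1).
#' @param noise_scale observation noise scale sigma (default 0.25).
#' @param seed seed for the covariance structure vectors.
#' @return a [ground_truth()].
#' @export
example_ground_truth <- function(K = 4, M = 10, diag_p = 0.9,
                                 separation = 1, noise_scale = 0.25,
                                 seed = 1L) {
  stopifnot(K <= M, K >= 2)
  A <- matrix((1 - diag_p) / (K - 1), K, K)
  diag(A) <- diag_p
  mu <- cbind(diag(K), matrix(0, K, M - K)) * separation / sqrt(2)
  set.seed(seed)
  covs <- lapply(seq_len(K), function(k) {
    u <- stats::rnorm(M); u <- u / sqrt(sum(u^2))
    noise_scale^2 * (diag(M) + tcrossprod(u))
  })
  ground_truth(A, rep(1 / K, K), mu, covs, seed = seed)
}

#' Simulate a Markov chain of hidden states
#'
#' @param initial_probs K-vector of initial state probabilities.
#' @param transition_matrix K x K row-stochastic matrix.
#' @param n_samples length of the chain.
#' @param seed integer seed; identical seeds give identical chains.
#' @param sampling_rate sampling rate (Hz) recorded on the returned path.
#' @return a [state_path()].
#' @export
simulate_markov_chain <- function(initial_probs, transition_matrix,
                                  n_samples, seed = 1L, sampling_rate = 40) {
  transition_matrix <- as.matrix(transition_matrix)
  check_stochastic_matrix(transition_matrix)
  K <- nrow(transition_matrix)
  if (length(initial_probs) != K || any(initial_probs < 0))
    stop("initial_probs must be a non-negative length-K vector")
  if (n_samples < 1L) stop("n_samples must be at least 1")
  set.seed(seed)
  u <- integer(n_samples)
  u[1L] <- sample.int(K, 1L, prob = initial_probs)
  if (n_samples > 1L) {
    r <- stats::runif(n_samples - 1L)
    cum <- t(apply(transition_matrix, 1L, cumsum))
    for (t in 2:n_samples) {
      # inverse-CDF draw from the current row
      u[t] <- 1L + sum(r[t - 1L] > cum[u[t - 1L], ])
    }
  }
  state_path(u, sampling_rate = sampling_rate, K = K)
}

#' Simulate observations from a Gaussian hidden Markov model
#'
#' Draws a hidden Markov chain from the ground truth and, at each sample,
#' an observation from the multivariate normal of the active state.
#'
#' @param gt a [ground_truth()].
#' @param n_samples number of samples.
#' @param seed integer seed.
#' @param sampling_rate sampling rate (Hz) recorded on the returned path.
#' @return a list with `observations` (n_samples x M) and `path`
#'   (a [state_path()]).
#' @export
simulate_gaussian_hmm <- function(gt, n_samples, seed = 1L,
                                  sampling_rate = 40) {
  stopifnot(inherits(gt, "ground_truth"))
  path <- simulate_markov_chain(gt$initial_probs, gt$transition_matrix,
                                n_samples, seed = seed,
                                sampling_rate = sampling_rate)
  K <- gt$K; M <- gt$M
  # symmetric matrix square roots; eigen handles the PSD (including zero)
  # covariances the degenerate-noise tests rely on
  sqrts <- lapply(gt$state_covs, function(S) {
    e <- eigen(S, symmetric = TRUE)
    e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
  })
  set.seed(seed + 1L)
  Z <- matrix(stats::rnorm(n_samples * M), n_samples, M)
  Y <- matrix(0, n_samples, M)
  for (k in seq_len(K)) {
    idx <- which(path$states == k)
    if (!length(idx)) next
    Y[idx, ] <- Z[idx, , drop = FALSE] %*% sqrts[[k]] +
      matrix(gt$state_means[k, ], length(idx), M, byrow = TRUE)
  }
  list(observations = Y, path = path)
}

#' Simulate an envelope-like voxel dataset with embedded state topographies
#'
#' Generates a multi-subject, non-negative voxels-by-time dataset emulating
#' band-limited amplitude envelopes whose spatial pattern switches with a
#' hidden Markov chain: baseline level plus the active state's additive
#' amplitude topography plus Gaussian noise, rectified at zero. Dwell times
#' are geometric; `mean_lifetime_samples` maps to a self-transition
#' probability `p = 1 - 1/mean`, the HMM's own dwell-time law. Each subject
#' segment is an independent chain restart.
#'
#' @param topographies K x V non-negative amplitude-gain matrix.
#' @param baseline_level positive baseline amplitude added everywhere.
#' @param mean_lifetime_samples target mean dwell time in samples (>= 1).
#' @param n_subjects number of independent subject segments.
#' @param samples_per_subject samples per segment.
#' @param noise_sd standard deviation of the additive Gaussian noise.
#' @param seed integer seed.
#' @param sampling_rate sampling rate in Hz (40 emulates the downsampled
#'   envelope rate).
#' @param voxel_coords optional V x 3 coordinates attached to the dataset.
#' @return list with `dataset` (an [envelope_dataset()]) and `path` (the
#'   generating [state_path()], segment boundaries included).
#' @export
simulate_envelope_dataset <- function(topographies, baseline_level = 1,
                                      mean_lifetime_samples = 6,
                                      n_subjects = 3,
                                      samples_per_subject = 8000,
                                      noise_sd = 0.2, seed = 1L,
                                      sampling_rate = 40,
                                      voxel_coords = NULL) {
  topographies <- as.matrix(topographies)
  if (any(topographies < 0))
    stop("topographies must be non-negative amplitude gains")
  if (baseline_level <= 0) stop("baseline_level must be positive")
  if (mean_lifetime_samples < 1) stop("mean_lifetime_samples must be >= 1")
  K <- nrow(topographies); V <- ncol(topographies)
  p_stay <- 1 - 1 / mean_lifetime_samples
  A <- matrix((1 - p_stay) / max(K - 1, 1), K, K)
  diag(A) <- if (K > 1) p_stay else 1
  init <- rep(1 / K, K)
  states <- integer(0)
  for (s in seq_len(n_subjects)) {
    seg <- simulate_markov_chain(init, A, samples_per_subject,
                                 seed = seed + 7919L * s,
                                 sampling_rate = sampling_rate)
    states <- c(states, seg$states)
  }
  Tn <- n_subjects * samples_per_subject
  boundaries <- seq_len(n_subjects) * samples_per_subject
  X <- t(topographies[states, , drop = FALSE]) + baseline_level  # V x T
  if (noise_sd > 0) {
    set.seed(seed + 104729L)
    X <- X + matrix(stats::rnorm(V * Tn, sd = noise_sd), V, Tn)
  }
  X <- pmax(X, 0)
  list(dataset = envelope_dataset(X, sampling_rate = sampling_rate,
                                  voxel_coords = voxel_coords,
                                  segment_boundaries = boundaries),
       path = state_path(states, sampling_rate = sampling_rate,
                         segment_boundaries = boundaries, K = K))
}

#' Simulate sensor-level data from dipolar sources
#'
#' Sensor measurement model `m(t) = sum_r H_r (phi_r a_r(t)) + e(t)` with
#' independent Gaussian sensor noise of standard deviation `noise_sd`. The
#' noise draw depends only on the seed and the data dimensions, so the
#' multi-dipole output equals the sum of single-dipole outputs when the
#' noise is attributed to exactly one of them.
#'
#' @param leadfields list of N x 3 lead-field matrices, one per dipole.
#' @param dipole_timecourses list (same length) of
#'   `list(ts = <length-T amplitude>, orientation = <3-vector>)`.
#' @param noise_sd sensor noise standard deviation.
#' @param seed integer seed.
#' @return N x T sensor time-series matrix.
#' @export
simulate_sensor_data <- function(leadfields, dipole_timecourses,
                                 noise_sd = 0, seed = 1L) {
  if (length(leadfields) != length(dipole_timecourses))
    stop("need one lead field per dipole time course")
  if (!length(leadfields)) stop("at least one dipole is required")
  N <- nrow(as.matrix(leadfields[[1L]]))
  Tn <- length(dipole_timecourses[[1L]]$ts)
  M <- matrix(0, N, Tn)
  for (i in seq_along(leadfields)) {
    H <- as.matrix(leadfields[[i]])
    if (ncol(H) != 3L || nrow(H) != N)
      stop("lead field ", i, " must be an N x 3 matrix")
    d <- dipole_timecourses[[i]]
    phi <- as.numeric(d$orientation)
    if (length(phi) != 3L) stop("dipole ", i, " needs a 3-vector orientation")
    if (length(d$ts) != Tn) stop("dipole time courses must share a length")
    M <- M + (H %*% phi) %*% matrix(d$ts, 1L, Tn)
  }
  set.seed(seed)
  M + noise_sd * matrix(stats::rnorm(N * Tn), N, Tn)
}
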