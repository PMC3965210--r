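#' PCA whitening of group-concatenated envelopes
#'
#' Reduces the voxels-by-time envelope data to `n_components` principal
#' temporal components with zero mean and unit variance. The sign of each
#' component is fixed deterministically by making its largest-magnitude
#' voxel loading positive.
#'
#' @param dataset an [envelope_dataset()] or a V x T numeric matrix.
#' @param n_components number of components M (default 40); must not
#'   exceed the rank of the data.
#' @return object of class `whitened_data`: `scores` (T x M), `transform`
#'   (V x M, maps demeaned voxel data to scores), `center` (per-voxel
#'   means), `sdev` (component standard deviations before scaling),
#'   `sampling_rate`, `segment_boundaries`.
#' @export
pca_whiten <- function(dataset, n_components = 40) {
  X <- as_data_matrix(dataset)                 # V x T
  Tn <- ncol(X)
  ctr <- rowMeans(X)
  Xc <- t(X - ctr)                             # T x V, columns demeaned
  sv <- svd(Xc)
  rank <- sum(sv$d > max(sv$d) * 1e-10)
  if (n_components > rank)
    stop("n_components (", n_components, ") exceeds the data rank (",
         rank, ")")
  d <- sv$d[seq_len(n_components)]
  U <- sv$u[, seq_len(n_components), drop = FALSE]
  V <- sv$v[, seq_len(n_components), drop = FALSE]
  # deterministic sign: largest |loading| positive per component
  for (j in seq_len(n_components)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) { V[, j] <- -V[, j]; U[, j] <- -U[, j] }
  }
  scores <- U * sqrt(Tn - 1)
  transform <- V %*% diag(sqrt(Tn - 1) / d, n_components)
  structure(list(
    scores = scores, transform = transform, center = ctr,
    sdev = d / sqrt(Tn - 1),
    sampling_rate = if (inherits(dataset, "envelope_dataset"))
      dataset$sampling_rate else NULL,
    segment_boundaries = if (inherits(dataset, "envelope_dataset"))
      dataset$segment_boundaries else Tn),
    class = "whitened_data")
}

#' @export
print.whitened_data <- function(x, ...) {
  cat(sprintf("<whitened_data> %d samples x %d components\n",
              nrow(x$scores), ncol(x$scores)))
  invisible(x)
}

whitened_scores <- function(data) {
  if (inherits(data, "whitened_data")) data$scores else as.matrix(data)
}
data_boundaries <- function(data) {
  if (inherits(data, "whitened_data")) data$segment_boundaries
  else attr(data, "segment_boundaries")
}

# seeded initialization of the responsibilities: a k-means partition of the
# scores, softened so every state keeps some mass everywhere. Random
# near-symmetric responsibilities leave the variational updates next to the
# symmetric saddle point, where they stall; the k-means labels break the
# symmetry decisively. Falls back to sparse random responsibilities if
# k-means degenerates (e.g. fewer distinct points than states).
init_responsibilities <- function(Y, K, soften = 0.1) {
  cl <- tryCatch(
    stats::kmeans(Y, centers = K, nstart = 1, iter.max = 50)$cluster,
    error = function(e) sample.int(K, nrow(Y), replace = TRUE))
  onehot <- outer(cl, seq_len(K), `==`) * 1
  (1 - soften) * onehot + soften / K
}

# M-step from initial responsibilities; xi and the segment-initial
# marginals are approximated from the responsibilities
init_model_from_responsibilities <- function(gamma, data, prior, boundaries) {
  model <- new_hmm_model(prior)
  starts <- segment_starts(boundaries)
  xi <- matrix(0, prior$K, prior$K)
  for (s in seq_along(starts)) {
    idx <- starts[s]:boundaries[s]
    if (length(idx) > 1L)
      xi <- xi + crossprod(gamma[idx[-length(idx)], , drop = FALSE],
                           gamma[idx[-1L], , drop = FALSE])
  }
  posterior <- structure(list(gamma = gamma, xi_sum = xi,
                              first_gamma = gamma[starts, , drop = FALSE],
                              logZ = NA_real_,
                              segment_boundaries = boundaries),
                         class = "state_posterior")
  vb_m_step(posterior, data, model)
}

#' Fit the variational Gaussian-observation HMM
#'
#' Runs variational Bayes to convergence from several seeded random
#' initializations (random Dirichlet responsibilities followed by an
#' M-step) and returns the realization with the lowest final free energy.
#' Convergence is declared when the relative free-energy change falls
#' below `tol` or after `max_iter` iterations.
#'
#' @param data a `whitened_data` object or T x M matrix (segment
#'   boundaries taken from the object, an attribute, or one segment).
#' @param K number of states.
#' @param n_restarts number of seeded initializations (default 10).
#' @param max_iter maximum VB iterations per restart (default 500).
#' @param tol relative free-energy convergence tolerance (default 1e-5).
#' @param seed integer root seed; restart r uses `seed + r - 1`.
#' @param prior optional [hmm_prior()] override.
#' @param segment_boundaries optional override of the data's boundaries.
#' @return list with `model` (an `hmm_model` carrying `free_energy`,
#'   `free_energy_trace`, `restart_energies`, `seed`, `settings`) and
#'   `posterior` (the matching `state_posterior`).
#' @export
fit_hmm <- function(data, K, n_restarts = 10, max_iter = 500, tol = 1e-5,
                    seed = 1L, prior = NULL, segment_boundaries = NULL) {
  Y <- whitened_scores(data)
  if (K < 1L) stop("K must be at least 1")
  if (n_restarts < 1L) stop("n_restarts must be at least 1")
  if (any(apply(Y, 2L, stats::var) <= 0))
    stop("degenerate data: a component has zero variance")
  boundaries <- segment_boundaries %||% data_boundaries(data) %||% nrow(Y)
  boundaries <- as.integer(boundaries)
  check_segment_boundaries(boundaries, nrow(Y))
  M <- ncol(Y)
  prior <- prior %||% hmm_prior(K, M)
  best <- NULL
  restart_energies <- numeric(n_restarts)
  min_iter <- 5L
  for (r in seq_len(n_restarts)) {
    set.seed(seed + r - 1L)
    gamma0 <- init_responsibilities(Y, K)
    model <- init_model_from_responsibilities(gamma0, Y, prior, boundaries)
    trace <- numeric(0)
    F_old <- Inf
    posterior <- NULL
    for (it in seq_len(max_iter)) {
      posterior <- vb_e_step(model, Y, boundaries)
      F_new <- free_energy(model, posterior)
      trace <- c(trace, F_new)
      if (it >= min_iter && is.finite(F_old) &&
          abs(F_new - F_old) < tol * abs(F_old)) { F_old <- F_new; break }
      F_old <- F_new
      model <- vb_m_step(posterior, Y, model)
    }
    restart_energies[r] <- F_old
    if (is.null(best) || F_old < best$free_energy) {
      model$free_energy <- F_old
      model$free_energy_trace <- trace
      best <- list(model = model, posterior = posterior,
                   free_energy = F_old, restart = r)
    }
  }
  best$model$restart_energies <- restart_energies
  best$model$seed <- as.integer(seed)
  best$model$settings <- list(K = K, n_restarts = n_restarts,
                              max_iter = max_iter, tol = tol)
  list(model = best$model, posterior = best$posterior)
}

#' Viterbi decoding of the most probable state path
#'
#' Most probable joint path under the expected log parameters, computed
#' independently within each subject segment (each restarts from the
#' initial-state distribution). Ties break to the lowest state index.
#'
#' @param model a fitted `hmm_model`.
#' @param data the data used for fitting (`whitened_data` or T x M matrix).
#' @param segment_boundaries optional override of the data's boundaries.
#' @return a [state_path()].
#' @export
viterbi_decode <- function(model, data, segment_boundaries = NULL) {
  Y <- whitened_scores(data)
  boundaries <- segment_boundaries %||% data_boundaries(data) %||% nrow(Y)
  boundaries <- as.integer(boundaries)
  check_segment_boundaries(boundaries, nrow(Y))
  logB <- expected_log_density(model, Y)
  logA <- expected_log_transition(model)
  logpi <- expected_log_initial(model)
  starts <- segment_starts(boundaries)
  u <- integer(nrow(Y))
  for (s in seq_along(starts)) {
    idx <- starts[s]:boundaries[s]
    u[idx] <- viterbi_cpp(logB[idx, , drop = FALSE], logA, logpi)
  }
  fs <- if (inherits(data, "whitened_data") && !is.null(data$sampling_rate))
    data$sampling_rate else 1
  state_path(u, sampling_rate = fs, segment_boundaries = boundaries,
             K = model$K)
}

#' Sweep over the number of states
#'
#' Fits one HMM per candidate K and tabulates the model-order selection
#' metrics: final free energy, minimum fractional occupancy, and mean life
#' time over states (from the Viterbi path).
#'
#' @param data data to fit (`whitened_data` or T x M matrix).
#' @param K_list candidate state counts.
#' @param n_restarts restarts per fit.
#' @param seed root seed; fit i uses `seed + 131 * i`.
#' @param ... further arguments passed to [fit_hmm()].
#' @return data.frame with columns `K`, `free_energy`,
#'   `min_fractional_occupancy`, `mean_life_time_s`.
#' @export
model_order_sweep <- function(data, K_list, n_restarts = 3, seed = 1L, ...) {
  if (!length(K_list)) stop("K_list must be non-empty")
  rows <- lapply(seq_along(K_list), function(i) {
    K <- K_list[i]
    fit <- fit_hmm(data, K, n_restarts = n_restarts,
                   seed = seed + 131L * i, ...)
    path <- viterbi_decode(fit$model, data)
    fo <- fractional_occupancy(path)
    mlt <- mean_life_time(path)
    data.frame(K = K, free_energy = fit$model$free_energy,
               min_fractional_occupancy = min(fo),
               mean_life_time_s = mean(mlt, na.rm = TRUE))
  })
  do.call(rbind, rows)
}

#' Align estimated state labels to a reference
#'
#' Enumerates all permutations of the K labels and picks the one
#' maximizing the summed Pearson correlations between matched rows of
#' `est` and `ref` (e.g. state means, or spatial maps). Intended for
#' small K (the search is K!).
#'
#' @param est,ref K x D matrices of per-state feature vectors.
#' @return integer permutation `p`: estimated state `j` corresponds to
#'   reference state `p[j]`; relabel a path with `p[path$states]`.
#' @export
align_state_labels <- function(est, ref) {
  est <- as.matrix(est); ref <- as.matrix(ref)
  K <- nrow(est)
  stopifnot(nrow(ref) == K)
  perms <- all_permutations(K)
  score <- function(p) sum(vapply(seq_len(K), function(j)
    stats::cor(est[j, ], ref[p[j], ]), numeric(1)))
  scores <- vapply(perms, score, numeric(1))
  perms[[which.max(scores)]]
}

all_permutations <- function(K) {
  if (K == 1L) return(list(1L))
  sub <- all_permutations(K - 1L)
  out <- list()
  for (p in sub)
    for (i in seq_len(K))
      out[[length(out) + 1L]] <- append(p, K, after = i - 1L)
  out
}

#' Serialize a fitted model to JSON
#'
#' Writes the prior and posterior hyperparameters, expected parameters,
#' free energy, seed and settings.
#'
#' @param model an `hmm_model`.
#' @param path file path; when `NULL` the JSON string is returned.
#' @return the JSON string, invisibly when written to a file.
#' @export
model_to_json <- function(model, path = NULL) {
  obj <- list(
    K = model$K, M = model$M,
    prior = model$prior,
    posterior = model$post,
    expected = list(
      transition = expected_transition_matrix(model),
      initial = model$post$alpha0 / sum(model$post$alpha0),
      means = model$post$m,
      covariances = lapply(seq_len(model$K), function(k)
        model$post$Winv[[k]] / (model$post$nu[k] - model$M - 1))),
    free_energy = model$free_energy,
    free_energy_trace = model$free_energy_trace,
    restart_energies = model$restart_energies,
    seed = model$seed, settings = model$settings)
  js <- jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
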