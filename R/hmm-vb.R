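#' Prior hyperparameters for the variational Gaussian-observation HMM
#'
#' Broad conjugate priors: symmetric Dirichlet over each transition row and
#' over the initial-state probabilities, and a Gaussian-Wishart over each
#' state's mean and precision. Defaults are weakly informative on whitened
#' (zero-mean, unit-variance) data: prior mean 0, mean-precision scale 1e-3,
#' Wishart degrees of freedom M and inverse scale `M * I`, so the prior
#' expected precision (and covariance) is the identity.
#'
#' @param K number of states.
#' @param M observation dimensionality.
#' @param dirichlet_alpha concentration per transition entry (default 1).
#' @param init_alpha concentration per initial-state entry (default 1).
#' @param m0 prior mean vector (default zeros).
#' @param beta0 prior mean-precision scale (default 1e-3).
#' @param nu0 Wishart degrees of freedom (default M; must be > M - 1).
#' @param W0inv Wishart inverse scale matrix (default `M * I`).
#' @return list of prior hyperparameters.
#' @export
hmm_prior <- function(K, M, dirichlet_alpha = 1, init_alpha = 1,
                      m0 = rep(0, M), beta0 = 1e-3, nu0 = M,
                      W0inv = diag(M) * M) {
  if (nu0 <= M - 1) stop("nu0 must exceed M - 1")
  if (beta0 <= 0) stop("beta0 must be positive")
  list(K = K, M = M,
       alpha = matrix(dirichlet_alpha, K, K),
       alpha0 = rep(init_alpha, K),
       m0 = as.numeric(m0), beta0 = beta0, nu0 = nu0,
       W0inv = as.matrix(W0inv))
}

# model object: prior + posterior hyperparameters of the same families
new_hmm_model <- function(prior) {
  K <- prior$K; M <- prior$M
  structure(list(
    K = K, M = M, prior = prior,
    post = list(alpha = prior$alpha, alpha0 = prior$alpha0,
                beta = rep(prior$beta0, K),
                m = matrix(rep(prior$m0, each = K), K, M),
                nu = rep(prior$nu0, K),
                Winv = replicate(K, prior$W0inv, simplify = FALSE))),
    class = "hmm_model")
}

#' @export
print.hmm_model <- function(x, ...) {
  cat(sprintf("<hmm_model> K = %d states, M = %d dimensions%s\n", x$K, x$M,
              if (!is.null(x$free_energy))
                sprintf(", free energy %.4f", x$free_energy) else ""))
  invisible(x)
}

#' Posterior expected transition matrix of a fitted model
#'
#' @param model an `hmm_model`.
#' @return K x K row-stochastic matrix of posterior mean transition
#'   probabilities.
#' @export
expected_transition_matrix <- function(model) {
  a <- model$post$alpha
  a / rowSums(a)
}

# expected log transition / initial weights under the Dirichlet posteriors
expected_log_transition <- function(model) {
  a <- model$post$alpha
  digamma(a) - digamma(rowSums(a))
}
expected_log_initial <- function(model) {
  a <- model$post$alpha0
  digamma(a) - digamma(sum(a))
}

# T x K expected log Gaussian densities under the Gaussian-Wishart
# posteriors:
#   E[ln N(y | mu_k, Lambda_k^-1)] =
#     (E[ln|Lambda_k|] - M ln 2pi - M/beta_k
#      - nu_k (y - m_k)' W_k (y - m_k)) / 2
expected_log_density <- function(model, Y) {
  K <- model$K; M <- model$M
  Tn <- nrow(Y)
  out <- matrix(0, Tn, K)
  for (k in seq_len(K)) {
    R <- chol(model$post$Winv[[k]])          # Winv = R'R, W = R^-1 R^-T
    D <- t(Y) - model$post$m[k, ]            # M x T
    Z <- backsolve(R, D, transpose = TRUE)   # R' Z = D  =>  quad = ||Z||^2
    quad <- model$post$nu[k] * colSums(Z^2) + M / model$post$beta[k]
    elnlam <- sum(digamma((model$post$nu[k] + 1 - seq_len(M)) / 2)) +
      M * log(2) - 2 * sum(log(diag(R)))
    out[, k] <- 0.5 * (elnlam - M * log(2 * pi) - quad)
  }
  out
}

#' Variational E-step: posterior state marginals
#'
#' Forward-backward recursions per subject segment under the expected log
#' transition weights and expected log Gaussian densities of the current
#' posterior hyperparameters. Each segment restarts from the initial-state
#' distribution; no transitions are counted across segment boundaries. The
#' recursions are scaled per sample and remain stable for chains up to
#' 1e6 samples.
#'
#' @param model an `hmm_model`.
#' @param data a `whitened_data` object or a T x M numeric matrix.
#' @param segment_boundaries cumulative segment end indices (defaults to
#'   those carried by `data`, else one segment).
#' @return object of class `state_posterior`: `gamma` (T x K marginals,
#'   rows sum to 1), `xi_sum` (K x K expected transition counts),
#'   `first_gamma` (segments x K marginals at segment starts), `logZ`
#'   (summed log normalizers), `segment_boundaries`.
#' @export
vb_e_step <- function(model, data, segment_boundaries = NULL) {
  Y <- whitened_scores(data)
  boundaries <- segment_boundaries %||% data_boundaries(data) %||% nrow(Y)
  boundaries <- as.integer(boundaries)
  check_segment_boundaries(boundaries, nrow(Y))
  K <- model$K
  logB <- expected_log_density(model, Y)
  logA <- expected_log_transition(model)
  logpi <- expected_log_initial(model)
  starts <- segment_starts(boundaries)
  gamma <- matrix(0, nrow(Y), K)
  xi <- matrix(0, K, K)
  first_gamma <- matrix(0, length(starts), K)
  logZ <- 0
  for (s in seq_along(starts)) {
    idx <- starts[s]:boundaries[s]
    fb <- forward_backward_cpp(logB[idx, , drop = FALSE], logA, logpi)
    gamma[idx, ] <- fb$gamma
    xi <- xi + fb$xi_sum
    first_gamma[s, ] <- fb$gamma[1L, ]
    logZ <- logZ + fb$logZ
  }
  structure(list(gamma = gamma, xi_sum = xi, first_gamma = first_gamma,
                 logZ = logZ, segment_boundaries = boundaries),
            class = "state_posterior")
}

#' Variational M-step: conjugate posterior updates
#'
#' Dirichlet posteriors are prior concentrations plus expected transition
#' (and segment-initial) counts; Gaussian-Wishart posteriors are updated
#' from the responsibility-weighted sufficient statistics (weighted means
#' and scatter). A state with (numerically) zero responsibility keeps its
#' prior.
#'
#' @param posterior a `state_posterior` from [vb_e_step()].
#' @param data the same data the E-step used.
#' @param model the `hmm_model` whose priors to update against.
#' @return updated `hmm_model`.
#' @export
vb_m_step <- function(posterior, data, model) {
  Y <- whitened_scores(data)
  K <- model$K; M <- model$M
  pr <- model$prior
  gamma <- posterior$gamma
  Nk <- colSums(gamma)
  post <- model$post
  post$alpha <- pr$alpha + posterior$xi_sum
  post$alpha0 <- pr$alpha0 + colSums(posterior$first_gamma)
  for (k in seq_len(K)) {
    if (Nk[k] > 1e-12) {
      xbar <- colSums(gamma[, k] * Y) / Nk[k]
      Ys <- sqrt(gamma[, k]) * Y
      Sk_scaled <- crossprod(Ys) - Nk[k] * tcrossprod(xbar)  # = Nk * Sk
    } else {
      xbar <- pr$m0
      Sk_scaled <- matrix(0, M, M)
    }
    beta_k <- pr$beta0 + Nk[k]
    d <- xbar - pr$m0
    Winv_k <- pr$W0inv + Sk_scaled +
      (pr$beta0 * Nk[k] / beta_k) * tcrossprod(d)
    post$beta[k] <- beta_k
    post$nu[k] <- pr$nu0 + Nk[k]
    post$m[k, ] <- (pr$beta0 * pr$m0 + Nk[k] * xbar) / beta_k
    post$Winv[[k]] <- (Winv_k + t(Winv_k)) / 2
  }
  model$post <- post
  model
}

#' Variational free energy
#'
#' The negative evidence lower bound in its collapsed form: minus the log
#' normalizer accumulated by the scaled forward pass (under the expected
#' log parameters), plus the KL divergences of the parameter posteriors
#' from their priors. Lower is better; `-F` approximates the log model
#' evidence. Valid when `posterior` is the E-step output under `model`'s
#' current posteriors.
#'
#' @param model an `hmm_model`.
#' @param posterior the matching `state_posterior`.
#' @param data unused (the required statistics are cached in `posterior`);
#'   accepted for call-site symmetry with the E/M steps.
#' @return scalar free energy.
#' @export
free_energy <- function(model, posterior, data = NULL) {
  pr <- model$prior; po <- model$post
  kl <- kl_dirichlet(po$alpha0, pr$alpha0)
  for (i in seq_len(model$K))
    kl <- kl + kl_dirichlet(po$alpha[i, ], pr$alpha[i, ])
  for (k in seq_len(model$K))
    kl <- kl + kl_gauss_wishart(
      po$m[k, ], po$beta[k], po$Winv[[k]], po$nu[k],
      pr$m0, pr$beta0, pr$W0inv, pr$nu0)
  -posterior$logZ + kl
}

kl_dirichlet <- function(a, b) {
  lgamma(sum(a)) - lgamma(sum(b)) - sum(lgamma(a)) + sum(lgamma(b)) +
    sum((a - b) * (digamma(a) - digamma(sum(a))))
}

# multivariate log gamma
lmvgamma <- function(a, p) {
  (p * (p - 1) / 4) * log(pi) + sum(lgamma(a + (1 - seq_len(p)) / 2))
}

# KL( NW(m1,b1,W1,nu1) || NW(m0,b0,W0,nu0) ), Wishart parameterized by the
# inverse scale matrices Winv = W^-1
kl_gauss_wishart <- function(m1, b1, W1inv, nu1, m0, b0, W0inv, nu0) {
  M <- length(m1)
  R1 <- chol(W1inv)
  logdetW1 <- -2 * sum(log(diag(R1)))
  logdetW0 <- -determinant(W0inv, logarithm = TRUE)$modulus[1L]
  elnlam <- sum(digamma((nu1 + 1 - seq_len(M)) / 2)) + M * log(2) + logdetW1
  W1 <- chol2inv(R1)
  trW0invW1 <- sum(W0inv * W1)
  d <- m1 - m0
  quad <- nu1 * sum(d * (W1 %*% d))
  kl_normal <- 0.5 * (M * log(b1 / b0) - M + b0 * (M / b1 + quad))
  lnB1 <- -(nu1 / 2) * logdetW1 - (nu1 * M / 2) * log(2) - lmvgamma(nu1 / 2, M)
  lnB0 <- -(nu0 / 2) * logdetW0 - (nu0 * M / 2) * log(2) - lmvgamma(nu0 / 2, M)
  kl_wishart <- lnB1 - lnB0 + ((nu1 - nu0) / 2) * elnlam +
    (nu1 / 2) * (trW0invW1 - M)
  kl_normal + kl_wishart
}
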