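# Shared fixtures and independent oracles for the test suite.

# Brute-force enumeration over all K^T hidden paths under given expected
# log parameters; the independent oracle for the E-step, the log
# normalizer and Viterbi decoding on tiny problems.
enumerate_paths <- function(logB, logA, logpi) {
  Tn <- nrow(logB); K <- ncol(logB)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), Tn)))
  logw <- apply(paths, 1L, function(s) {
    lp <- logpi[s[1L]] + logB[1L, s[1L]]
    if (Tn > 1L)
      for (t in 2:Tn) lp <- lp + logA[s[t - 1L], s[t]] + logB[t, s[t]]
    lp
  })
  w <- exp(logw - max(logw))
  gamma <- vapply(seq_len(K), function(k)
    vapply(seq_len(Tn), function(t) sum(w[paths[, t] == k]) / sum(w),
           numeric(1)), numeric(Tn))
  gamma <- matrix(gamma, Tn, K)
  # lowest-index tie-break on the MAP path, matching the decoder contract
  best <- which(logw >= max(logw) - 1e-12)
  map <- paths[best[order(apply(paths[best, , drop = FALSE], 1L, paste,
                                collapse = ""))[1L]], ]
  list(gamma = gamma, logZ = max(logw) + log(sum(w)), map = as.integer(map))
}

# a small fitted-model stand-in with hand-set, asymmetric posteriors so
# that expectations are non-trivial
perturbed_model <- function(K, M, seed = 1) {
  set.seed(seed)
  model <- envhmm:::new_hmm_model(hmm_prior(K, M))
  model$post$alpha <- matrix(stats::rgamma(K * K, 3) + 0.5, K, K)
  model$post$alpha0 <- stats::rgamma(K, 2) + 0.5
  model$post$m <- matrix(stats::rnorm(K * M), K, M)
  model$post$beta <- stats::rgamma(K, 5) + 1
  model$post$nu <- M + stats::rgamma(K, 3)
  model$post$Winv <- replicate(K, {
    A <- matrix(stats::rnorm(M * M), M, M)
    crossprod(A) + diag(M)
  }, simplify = FALSE)
  model
}

# permute the state labels of a model: state k becomes perm[k]
permute_model <- function(model, perm) {
  inv <- order(perm)
  out <- model
  out$post$alpha <- model$post$alpha[inv, inv, drop = FALSE]
  out$post$alpha0 <- model$post$alpha0[inv]
  out$post$m <- model$post$m[inv, , drop = FALSE]
  out$post$beta <- model$post$beta[inv]
  out$post$nu <- model$post$nu[inv]
  out$post$Winv <- model$post$Winv[inv]
  out
}

# well-separated 3-state ground truth for quick end-to-end fits
separated_gt3 <- function(M = 5, sep = 3) {
  mu <- matrix(0, 3, M)
  mu[1, 1] <- sep; mu[2, 2] <- sep; mu[3, 3] <- -sep
  A <- matrix(0.05, 3, 3); diag(A) <- 0.9
  ground_truth(A, rep(1 / 3, 3), mu,
               replicate(3, diag(M), simplify = FALSE))
}

# independent run-length encoding statistics for a path with segments
rle_stats <- function(states, boundaries, k) {
  starts <- c(1L, utils::head(boundaries, -1L) + 1L)
  runs <- integer(0)
  for (s in seq_along(starts)) {
    r <- rle(states[starts[s]:boundaries[s]])
    runs <- c(runs, r$lengths[r$values == k])
  }
  list(occurrences = length(runs), dwell = sum(runs),
       mean_run = if (length(runs)) mean(runs) else NA_real_)
}
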