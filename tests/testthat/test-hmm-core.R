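test_that("PCA whitening produces unit-variance, reconstructable scores", {
  set.seed(1)
  # exact rank-2 data reconstructs from 2 components
  base <- matrix(rnorm(2 * 200), 2, 200)
  X <- rbind(base[1, ] + base[2, ], base[1, ] - base[2, ],
             2 * base[1, ], base[2, ])
  wh <- pca_whiten(X, 2)
  Xc <- t(X - rowMeans(X))
  # the transform maps centered voxel data to the scores, and the scores
  # reconstruct the rank-2 data through the unscaled loadings
  expect_equal(wh$scores, Xc %*% wh$transform, tolerance = 1e-8)
  loadings <- wh$transform %*% diag(wh$sdev^2, 2)  # V x 2, scores -> data
  expect_equal(wh$scores %*% t(loadings), Xc, tolerance = 1e-8)
  expect_lt(max(abs(crossprod(wh$scores) / (ncol(X) - 1) - diag(2))), 1e-6)
  expect_lt(max(abs(colMeans(wh$scores))), 1e-8)

  # deterministic output
  expect_identical(pca_whiten(X, 2)$scores, wh$scores)

  # rank bound enforced
  expect_error(pca_whiten(matrix(rnorm(38 * 100), 38, 100), 40), "rank")
})

test_that("E-step marginals match exhaustive path enumeration", {
  set.seed(2)
  for (K in 2:3) {
    for (Tn in c(4L, 6L)) {
      model <- perturbed_model(K, 2, seed = K * 10 + Tn)
      Y <- matrix(rnorm(Tn * 2), Tn, 2)
      post <- vb_e_step(model, Y)
      oracle <- enumerate_paths(envhmm:::expected_log_density(model, Y),
                                envhmm:::expected_log_transition(model),
                                envhmm:::expected_log_initial(model))
      expect_lt(max(abs(post$gamma - oracle$gamma)), 1e-10)
      expect_lt(abs(post$logZ - oracle$logZ), 1e-8)
    }
  }
})

test_that("E-step degenerate and symmetry behavior", {
  set.seed(3)
  Y <- matrix(rnorm(40), 20, 2)
  m1 <- perturbed_model(1, 2)
  expect_equal(vb_e_step(m1, Y)$gamma, matrix(1, 20, 1))

  model <- perturbed_model(3, 2, seed = 5)
  perm <- c(2L, 3L, 1L)
  g <- vb_e_step(model, Y)$gamma
  gp <- vb_e_step(permute_model(model, perm), Y)$gamma
  expect_equal(gp[, perm], g, tolerance = 1e-12)

  # chains restart at segment boundaries: a segment is inferred
  # identically whether alone or concatenated after another
  Y2 <- rbind(Y, Y[1:10, ])
  post <- vb_e_step(model, Y2, segment_boundaries = c(20L, 30L))
  alone <- vb_e_step(model, Y[1:10, ])
  expect_equal(post$gamma[21:30, ], alone$gamma, tolerance = 1e-12)
})

test_that("M-step performs the conjugate updates (hand arithmetic)", {
  Y <- matrix(c(1, 2, 4, 0.5, -1, 3), 3, 2)   # T=3, M=2
  prior <- hmm_prior(2, 2)
  model <- envhmm:::new_hmm_model(prior)
  gamma <- matrix(c(0.9, 0.1, 0.3, 0.7, 0.6, 0.4), 3, 2, byrow = TRUE)
  xi <- matrix(c(0.5, 0.6, 0.4, 0.5), 2, 2, byrow = TRUE)
  post <- structure(list(gamma = gamma, xi_sum = xi,
                         first_gamma = gamma[1, , drop = FALSE],
                         logZ = NA_real_, segment_boundaries = 3L),
                    class = "state_posterior")
  up <- vb_m_step(post, Y, model)
  expect_equal(up$post$alpha, prior$alpha + xi, tolerance = 1e-14)
  expect_equal(up$post$alpha0, prior$alpha0 + gamma[1, ], tolerance = 1e-14)
  # state 1 by hand: N1 = 1.8, xbar = (sum gamma*y)/N1
  N1 <- 0.9 + 0.3 + 0.6
  xbar1 <- c(sum(gamma[, 1] * Y[, 1]), sum(gamma[, 1] * Y[, 2])) / N1
  expect_equal(up$post$beta[1], 1e-3 + N1)
  expect_equal(up$post$nu[1], 2 + N1)
  expect_equal(up$post$m[1, ], N1 * xbar1 / (1e-3 + N1), tolerance = 1e-12)
  S1 <- matrix(0, 2, 2)
  for (t in 1:3) {
    d <- Y[t, ] - xbar1
    S1 <- S1 + gamma[t, 1] * tcrossprod(d)
  }
  W1inv <- prior$W0inv + S1 + (1e-3 * N1 / (1e-3 + N1)) * tcrossprod(xbar1)
  expect_equal(up$post$Winv[[1]], W1inv, tolerance = 1e-10)

  # all mass on state 1: state 2 keeps its prior
  g1 <- cbind(rep(1, 3), rep(0, 3))
  post1 <- structure(list(gamma = g1, xi_sum = matrix(c(2, 0, 0, 0), 2, 2),
                          first_gamma = g1[1, , drop = FALSE],
                          logZ = NA_real_, segment_boundaries = 3L),
                     class = "state_posterior")
  up1 <- vb_m_step(post1, Y, model)
  expect_equal(up1$post$m[2, ], prior$m0)
  expect_equal(up1$post$beta[2], prior$beta0)
  expect_equal(up1$post$Winv[[2]], prior$W0inv)

  # duplicate responsibilities give identical updates
  gd <- cbind(rep(0.5, 3), rep(0.5, 3))
  postd <- structure(list(gamma = gd, xi_sum = matrix(0.5, 2, 2),
                          first_gamma = gd[1, , drop = FALSE],
                          logZ = NA_real_, segment_boundaries = 3L),
                     class = "state_posterior")
  upd <- vb_m_step(postd, Y, model)
  expect_equal(upd$post$m[1, ], upd$post$m[2, ])
  expect_equal(upd$post$Winv[[1]], upd$post$Winv[[2]])
})

test_that("free energy is non-increasing and label-invariant", {
  gt <- separated_gt3()
  sim <- simulate_gaussian_hmm(gt, 3000, seed = 7)
  Y <- sim$observations
  prior <- hmm_prior(3, 5)
  set.seed(8)
  gamma0 <- envhmm:::init_responsibilities(Y, 3)
  model <- envhmm:::init_model_from_responsibilities(gamma0, Y, prior,
                                                     nrow(Y))
  Fs <- numeric(50)
  for (it in 1:50) {
    post <- vb_e_step(model, Y)
    Fs[it] <- free_energy(model, post)
    model <- vb_m_step(post, Y, model)
  }
  expect_true(all(diff(Fs) <= abs(Fs[-50]) * 1e-6))

  perm <- c(3L, 1L, 2L)
  mp <- permute_model(model, perm)
  postp <- vb_e_step(mp, Y)
  expect_equal(free_energy(mp, postp), free_energy(model, vb_e_step(model, Y)),
               tolerance = 1e-8)
})

test_that("free energy for K=1 equals the conjugate closed-form evidence", {
  set.seed(9)
  Tn <- 300; M <- 3
  Y <- matrix(rnorm(Tn * M, mean = 0.3, sd = 1.2), Tn, M)
  fit <- fit_hmm(Y, K = 1, n_restarts = 1, seed = 1)
  pr <- fit$model$prior; po <- fit$model$post
  lmg <- function(a, p) (p * (p - 1) / 4) * log(pi) +
    sum(lgamma(a + (1 - seq_len(p)) / 2))
  logdet <- function(X) determinant(X, logarithm = TRUE)$modulus[1]
  lnp <- -(Tn * M / 2) * log(pi) + (M / 2) * log(pr$beta0 / po$beta) +
    lmg(po$nu / 2, M) - lmg(pr$nu0 / 2, M) +
    (po$nu / 2) * (-logdet(po$Winv[[1]])) -
    (pr$nu0 / 2) * (-logdet(pr$W0inv))
  expect_lt(abs(fit$model$free_energy - (-lnp)), 1e-6)
})

test_that("fit_hmm is deterministic and returns the best restart", {
  gt <- separated_gt3()
  sim <- simulate_gaussian_hmm(gt, 1500, seed = 11)
  f1 <- fit_hmm(sim$observations, 3, n_restarts = 1, seed = 4)
  f2 <- fit_hmm(sim$observations, 3, n_restarts = 1, seed = 4)
  expect_identical(f1$model$post, f2$model$post)
  expect_identical(f1$model$free_energy, f2$model$free_energy)

  f3 <- fit_hmm(sim$observations, 3, n_restarts = 4, seed = 4)
  expect_true(all(f3$model$free_energy <= f3$model$restart_energies + 1e-9))

  expect_error(fit_hmm(cbind(rnorm(100), rep(1, 100)), 2), "zero variance")
  expect_error(fit_hmm(sim$observations, 0), "K")
})

test_that("fit_hmm recovers generating parameters on separated data", {
  gt <- separated_gt3()
  sim <- simulate_gaussian_hmm(gt, 8000, seed = 13)
  fit <- fit_hmm(sim$observations, 3, n_restarts = 3, seed = 5)
  path <- viterbi_decode(fit$model, sim$observations)
  perm <- align_state_labels(fit$model$post$m, gt$state_means)
  expect_gt(mean(perm[path$states] == sim$path$states), 0.95)
  A <- expected_transition_matrix(fit$model)
  Aal <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) Aal[perm[i], perm[j]] <- A[i, j]
  expect_lt(max(abs(Aal - gt$transition_matrix)), 0.05)
})

test_that("viterbi decoding matches exhaustive maximization", {
  set.seed(14)
  model <- perturbed_model(3, 2, seed = 21)
  Y <- matrix(rnorm(8 * 2), 8, 2)
  path <- viterbi_decode(model, Y)
  oracle <- enumerate_paths(envhmm:::expected_log_density(model, Y),
                            envhmm:::expected_log_transition(model),
                            envhmm:::expected_log_initial(model))
  expect_identical(path$states, oracle$map)

  # unambiguous emissions reproduce the generating path exactly
  gt <- separated_gt3(sep = 10)
  sim <- simulate_gaussian_hmm(gt, 4000, seed = 15)
  fit <- fit_hmm(sim$observations, 3, n_restarts = 2, seed = 6)
  dec <- viterbi_decode(fit$model, sim$observations)
  perm <- align_state_labels(fit$model$post$m, gt$state_means)
  expect_identical(perm[dec$states], sim$path$states)

  # K = 1: constant path
  m1 <- perturbed_model(1, 2)
  expect_true(all(viterbi_decode(m1, Y)$states == 1L))
})

test_that("model order sweep reports finite metrics and state splitting", {
  gt <- example_ground_truth(K = 4, M = 6, noise_scale = 0.25, seed = 3)
  sim <- simulate_gaussian_hmm(gt, 6000, seed = 17)
  sweep <- model_order_sweep(sim$observations, c(1L, 4L, 8L),
                             n_restarts = 2, seed = 9)
  expect_equal(nrow(sweep), 3L)
  expect_true(all(is.finite(as.matrix(sweep))))
  # splitting a 4-state process into 8 states shrinks the rarest state
  expect_lte(sweep$min_fractional_occupancy[sweep$K == 8],
             sweep$min_fractional_occupancy[sweep$K == 4])
  # the true model order explains the data far better than one state
  expect_lte(sweep$free_energy[sweep$K == 4], sweep$free_energy[sweep$K == 1])
})
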