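test_that("markov chain simulation respects absorbing and stochastic structure", {
  # identity transition matrix: whatever state is entered first is kept
  p <- simulate_markov_chain(c(0, 1, 0), diag(3), 500, seed = 4)
  expect_true(all(p$states == p$states[1L]))
  expect_equal(p$states[1L], 2L)

  # empirical transition frequencies approach the generating matrix
  A <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2, byrow = TRUE)
  p <- simulate_markov_chain(c(0.5, 0.5), A, 1e5, seed = 7)
  emp <- transition_probability_matrix(p)
  expect_lt(max(abs(emp - A)), 0.01)

  # occupancy of a long chain matches the stationary distribution
  # (leading left eigenvector, computed by an independent eigen call)
  A3 <- matrix(c(0.8, 0.15, 0.05,
                 0.1, 0.8, 0.1,
                 0.05, 0.25, 0.7), 3, 3, byrow = TRUE)
  e <- eigen(t(A3))
  stat <- Re(e$vectors[, which.max(Re(e$values))])
  stat <- stat / sum(stat)
  p3 <- simulate_markov_chain(c(1, 0, 0), A3, 2e5, seed = 9)
  expect_lt(max(abs(fractional_occupancy(p3) - stat)), 0.01)
})

test_that("markov chain validation names the offending row", {
  A <- matrix(c(0.9, 0.1, 0.3, 0.8), 2, 2, byrow = TRUE)
  expect_error(simulate_markov_chain(c(1, 0), A, 10), "row\\(s\\) 2")
  expect_error(simulate_markov_chain(c(1, 0), diag(2), 0), "n_samples")
})

test_that("dwell times are geometric with mean 1/(1 - p_stay)", {
  p_stay <- 0.85
  A <- matrix(c(p_stay, 1 - p_stay, 1 - p_stay, p_stay), 2, 2)
  p <- simulate_markov_chain(c(0.5, 0.5), A, 1e5, seed = 21)
  runs <- rle(p$states)$lengths
  expect_lt(abs(mean(runs) - 1 / (1 - p_stay)) / (1 / (1 - p_stay)), 0.05)
  # chi-square goodness of fit of run lengths against the geometric pmf
  maxlen <- 25L
  obs <- tabulate(pmin(runs, maxlen), nbins = maxlen)
  pr <- (1 - p_stay)^0 * p_stay^(seq_len(maxlen) - 1) * (1 - p_stay)
  pr[maxlen] <- p_stay^(maxlen - 1)          # tail lumped into the last bin
  keep <- pr * length(runs) >= 5
  chi <- sum((obs[keep] - length(runs) * pr[keep])^2 /
               (length(runs) * pr[keep]))
  expect_gt(stats::pchisq(chi, df = sum(keep) - 1, lower.tail = FALSE),
            1e-3)
})

test_that("gaussian HMM emissions follow the state-conditional normals", {
  gt0 <- ground_truth(diag(2), c(0, 1),
                      matrix(c(1, 2, -3, 4), 2, 2, byrow = TRUE),
                      replicate(2, matrix(0, 2, 2), simplify = FALSE))
  sim <- simulate_gaussian_hmm(gt0, 50, seed = 3)
  expect_true(all(sim$path$states == 2L))
  expect_equal(sim$observations,
               matrix(rep(c(-3, 4), each = 50), 50, 2))

  gt <- separated_gt3()
  sim <- simulate_gaussian_hmm(gt, 5e4, seed = 13)
  for (k in 1:3) {
    idx <- sim$path$states == k
    se <- sqrt(diag(gt$state_covs[[k]]) / sum(idx))
    dev <- abs(colMeans(sim$observations[idx, ]) - gt$state_means[k, ])
    expect_true(all(dev < 3 * se + 1e-12))
  }
})

test_that("label swaps leave the marginal observation distribution unchanged", {
  gt <- separated_gt3()
  perm <- c(3L, 1L, 2L)
  gt_perm <- ground_truth(gt$transition_matrix[perm, perm],
                          gt$initial_probs[perm],
                          gt$state_means[perm, ],
                          gt$state_covs[perm])
  a <- simulate_gaussian_hmm(gt, 3e4, seed = 5)$observations
  b <- simulate_gaussian_hmm(gt_perm, 3e4, seed = 6)$observations
  expect_lt(max(abs(colMeans(a) - colMeans(b))), 0.1)
  expect_lt(max(abs(stats::cov(a) - stats::cov(b))), 0.15)
})

test_that("ground truth validation rejects bad inputs", {
  expect_error(ground_truth(matrix(c(0.5, 0.4, 0.1, 0.9), 2, 2,
                                   byrow = TRUE),
                            c(0.5, 0.5), matrix(0, 2, 2),
                            replicate(2, diag(2), simplify = FALSE)),
               "row")
  bad_cov <- matrix(c(1, 2, 2, 1), 2, 2)  # indefinite
  expect_error(ground_truth(diag(2), c(0.5, 0.5), matrix(0, 2, 2),
                            list(diag(2), bad_cov)),
               "positive semi-definite")
})

test_that("envelope simulator embeds topographies with geometric dwells", {
  topo <- rbind(c(2, 0, 0, 1), c(0, 2, 0, 1), c(0, 0, 2, 1))
  sim <- simulate_envelope_dataset(topo, baseline_level = 1,
                                   mean_lifetime_samples = 5,
                                   n_subjects = 2, samples_per_subject = 400,
                                   noise_sd = 0, seed = 8)
  # noiseless: value is exactly baseline + topography of the active state
  expect_equal(sim$dataset$data,
               t(topo[sim$path$states, ]) + 1)
  expect_equal(sim$dataset$segment_boundaries, c(400L, 800L))

  sim2 <- simulate_envelope_dataset(topo, mean_lifetime_samples = 6,
                                    n_subjects = 1,
                                    samples_per_subject = 1e5,
                                    noise_sd = 0.3, seed = 10)
  expect_true(all(sim2$dataset$data >= 0))
  runs <- rle(sim2$path$states)$lengths
  expect_lt(abs(mean(runs) - 6) / 6, 0.05)

  expect_error(simulate_envelope_dataset(-topo), "non-negative")
})

test_that("sensor simulation is a noisy linear superposition of dipoles", {
  set.seed(31)
  N <- 12; Tn <- 300
  H1 <- matrix(rnorm(N * 3), N, 3)
  H2 <- matrix(rnorm(N * 3), N, 3)
  d1 <- list(ts = sin(2 * pi * (1:Tn) / 25), orientation = c(1, 0, 0))
  d2 <- list(ts = cos(2 * pi * (1:Tn) / 40), orientation = c(0, 1, 1) / sqrt(2))

  # single dipole, no noise: data lie in a 1-D subspace
  m1 <- simulate_sensor_data(list(H1), list(d1), noise_sd = 0, seed = 1)
  sv <- svd(m1)$d
  expect_lt(sv[2] / sv[1], 1e-12)

  # zero amplitude: per-channel variance matches the noise level
  d0 <- list(ts = rep(0, 20000), orientation = c(1, 0, 0))
  m0 <- simulate_sensor_data(list(H1), list(d0), noise_sd = 0.7, seed = 2)
  v <- apply(m0, 1, stats::var)
  expect_lt(max(abs(v - 0.49)), 0.49 * 0.1)

  # superposition at equal seeds, with the noise attributed once
  mb <- simulate_sensor_data(list(H1, H2), list(d1, d2), noise_sd = 0.5,
                             seed = 3)
  ma <- simulate_sensor_data(list(H1), list(d1), noise_sd = 0.5, seed = 3)
  mc <- simulate_sensor_data(list(H2), list(d2), noise_sd = 0, seed = 3)
  expect_equal(mb, ma + mc, tolerance = 1e-12)
})

test_that("generators are pure functions of their seeds", {
  A <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2, byrow = TRUE)
  expect_identical(simulate_markov_chain(c(1, 0), A, 1000, seed = 5)$states,
                   simulate_markov_chain(c(1, 0), A, 1000, seed = 5)$states)
  gt <- separated_gt3()
  expect_identical(simulate_gaussian_hmm(gt, 500, seed = 9)$observations,
                   simulate_gaussian_hmm(gt, 500, seed = 9)$observations)
  topo <- rbind(c(1, 0), c(0, 1))
  expect_identical(
    simulate_envelope_dataset(topo, n_subjects = 1,
                              samples_per_subject = 300, seed = 2)$dataset$data,
    simulate_envelope_dataset(topo, n_subjects = 1,
                              samples_per_subject = 300, seed = 2)$dataset$data)
})
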