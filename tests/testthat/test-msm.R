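make_label_set <- function(labs, fi = 1) {
  structure(labs, frame_interval_ns = fi)
}

test_that("k-means recovers well-separated blob centres and degenerate cases", {
  # two Gaussian blobs 20 sd apart: centres within 0.1 sd of the blob means
  set.seed(1)
  blob1 <- matrix(rnorm(4000, 0, 1), ncol = 2)
  blob2 <- matrix(rnorm(4000, 20, 1), ncol = 2)
  proj <- make_feature_set_like(list(rbind(blob1, blob2)))
  disc <- cluster_microstates(proj, k = 2, seed = 2)
  cen <- disc$centers[order(disc$centers[, 1]), ]
  expect_lt(max(abs(cen[1, ] - colMeans(blob1))), 0.1)
  expect_lt(max(abs(cen[2, ] - colMeans(blob2))), 0.1)
  # cross-check against the stock k-means implementation
  km <- stats::kmeans(rbind(blob1, blob2), centers = 2, nstart = 5)
  cen_ref <- km$centers[order(km$centers[, 1]), ]
  expect_lt(max(abs(cen - cen_ref)), 0.1)
  # k = number of distinct points: zero inertia, each point its own centre
  pts <- matrix(c(0, 0, 1, 0, 0, 1, 2, 2), ncol = 2, byrow = TRUE)
  d2 <- cluster_microstates(make_feature_set_like(list(pts)), k = 4, seed = 3)
  expect_equal(d2$inertia, 0)
  expect_equal(sort(unique(d2$labels[[1]])), 1:4)
  expect_error(cluster_microstates(make_feature_set_like(list(pts)), k = 10),
               "exceeds")
})

test_that("sliding-window counts match a hand count and respect replica boundaries", {
  cc <- count_and_connect(make_label_set(list(c(1L, 2L, 1L, 2L))), lag_ns = 1)
  expect_equal(unname(cc$counts), matrix(c(0, 1, 2, 0), 2))
  expect_equal(cc$active_set, 1:2)
  # two replicas with disjoint state sets: active set is the larger component
  cc2 <- count_and_connect(
    make_label_set(list(c(1L, 2L, 1L, 2L, 1L), c(3L, 4L, 5L, 3L, 4L, 5L))),
    lag_ns = 1)
  expect_equal(cc2$active_set, 3:5)
  expect_lt(cc2$coverage, 1)
})

test_that("empirical count frequencies match the simulating chain within 3 multinomial SEs", {
  ch <- example_dimer_chain("symmetric")
  labs <- simulate_markov_chain(ch, 2e5, 1, seed = 4)
  cc <- count_and_connect(labs, lag_ns = ch$lag_step_ns)
  P <- ch$transition_matrix
  for (a in seq_len(nrow(P))) {
    n_a <- sum(cc$counts[a, ])
    for (b in seq_len(ncol(P))) {
      se <- sqrt(max(P[a, b] * (1 - P[a, b]), 1e-12) / n_a)
      expect_lt(abs(cc$counts[a, b] / n_a - P[a, b]), 3 * se + 1e-12)
    }
  }
})

test_that("reversible MLE fixed points: symmetric and detailed-balance counts", {
  m <- estimate_reversible_transition_matrix(matrix(5, 2, 2), lag_ns = 1)
  expect_equal(m$transition_matrix, matrix(0.5, 2, 2), tolerance = 1e-9)
  expect_equal(m$stationary, c(0.5, 0.5), tolerance = 1e-9)
  # counts already satisfying detailed balance: MLE equals row normalization
  pi_d <- c(0.5, 0.3, 0.2)
  P_d <- reversible_from_weights(matrix(c(4, 2, 1, 2, 3, 1, 1, 1, 2), 3))
  C_db <- diag(pi_d) %*% P_d * 1e6
  m2 <- estimate_reversible_transition_matrix(C_db, lag_ns = 1)
  expect_equal(m2$transition_matrix, C_db / rowSums(C_db), tolerance = 1e-8)
})

test_that("reversible MLE satisfies detailed balance and has a real unit-leading spectrum", {
  ch <- example_dimer_chain("asymmetric")
  labs <- simulate_markov_chain(ch, 5e4, 2, seed = 6)
  m <- estimate_msm(labs, lag_ns = ch$lag_step_ns)
  T_ <- m$transition_matrix
  pi_ <- m$stationary
  expect_lt(max(abs(rowSums(T_) - 1)), 1e-10)
  db <- abs(pi_ * T_ - t(pi_ * T_)) / pmax(pi_ * T_, 1e-300)
  db[T_ == 0 & t(T_) == 0] <- 0
  expect_lt(max(db), 1e-8)
  expect_equal(m$eigenvalues[1], 1, tolerance = 1e-10)
  expect_true(all(abs(Im(m$eigenvalues)) == 0))
  # pi agrees with the leading left eigenvector
  expect_lt(m$convergence$stationary_eigen_dev, 1e-8)
})

test_that("the estimator recovers a known reversible matrix and improves with data", {
  P_true <- reversible_from_weights(
    matrix(c(8, 1, 0.5, 1, 6, 1.5, 0.5, 1.5, 4), 3))
  err_at <- function(n_steps, seed) {
    s <- sample_chain_naive(P_true, n_steps, init = 1, seed = seed)
    m <- estimate_msm(make_label_set(list(s)), lag_ns = 1)
    max(abs(m$transition_matrix - P_true))
  }
  e_short <- err_at(1e4, 7)
  e_long <- err_at(1e6, 7)
  expect_lt(e_long, 1e-2)
  expect_lt(e_long, e_short)
})

test_that("implied timescales follow the closed form and are flat for Markov data", {
  # closed forms: lambda = exp(-1) at tau 1 -> t = 1; lambda 0.5 at tau 5
  # -> 5/ln 2
  P2 <- function(lam) matrix(c((1 + lam) / 2, (1 - lam) / 2,
                               (1 - lam) / 2, (1 + lam) / 2), 2)
  s <- sample_chain_naive(P2(exp(-1)), 2e5, 1, seed = 8)
  it1 <- implied_timescales(make_label_set(list(s)), lags_ns = 1)
  expect_equal(it1$timescale_ns[1], 1, tolerance = 0.1)
  s5 <- sample_chain_naive(P2(0.5), 4e5, 1, seed = 9)
  it5 <- implied_timescales(make_label_set(list(s5), fi = 5), lags_ns = 5)
  expect_equal(it5$timescale_ns[1], 5 / log(2), tolerance = 0.4)
  # Markov data: timescales flat in lag, matching -tau/ln lambda(T_true^k)
  P_true <- reversible_from_weights(
    matrix(c(8, 1, 0.5, 1, 6, 1.5, 0.5, 1.5, 4), 3))
  lam2 <- sort(eigen(P_true)$values, decreasing = TRUE)[2]
  t_true <- -1 / log(lam2)
  s3 <- sample_chain_naive(P_true, 5e5, 1, seed = 10)
  it <- implied_timescales(make_label_set(list(s3)), lags_ns = c(1, 2, 4),
                           n_timescales = 1)
  expect_true(all(abs(it$timescale_ns - t_true) / t_true < 0.1))
})

test_that("CK factor 1 is an identity and the model passes its own CK test", {
  ch <- example_dimer_chain("asymmetric")
  labs <- simulate_markov_chain(ch, 1e5, 2, seed = 11)
  m <- estimate_msm(labs, lag_ns = ch$lag_step_ns)
  sets <- list(which(ch$state_labels == "bound"),
               which(ch$state_labels == "unbound"))
  ckr <- ck_test(m, labs, sets, factors = 1:5)
  k1 <- ckr[ckr$factor == 1, ]
  expect_equal(k1$predicted, k1$estimated, tolerance = 1e-12)
  # data simulated from a Markov chain: agreement within ~3 bands for k <= 5
  expect_true(all(abs(ckr$predicted - ckr$estimated) <=
                    3 * ckr$se + 1e-6))
})

test_that("coarse discretization of a hidden-state chain produces a visible CK violation", {
  # hidden 3-state chain; states 2 and 3 are observed as one label, making
  # the observed 2-state process strongly non-Markovian
  P_h <- matrix(c(0.98, 0.02, 0.00,
                  0.02, 0.93, 0.05,
                  0.00, 0.05, 0.95), 3, byrow = TRUE)
  s_h <- sample_chain_naive(P_h, 2e5, 1, seed = 12)
  s_obs <- ifelse(s_h == 1L, 1L, 2L)
  m <- estimate_msm(make_label_set(list(s_obs)), lag_ns = 1)
  ckr <- ck_test(m, make_label_set(list(s_obs)), list(1L, 2L),
                 factors = c(1, 10, 25))
  viol <- ckr[ckr$factor == 25, ]
  expect_true(any(abs(viol$predicted - viol$estimated) > 3 * viol$se))
})

test_that("macrostate free energies follow -kT log(sum pi) with the expected identities", {
  pi_ <- c(0.5, 0.3, 0.15, 0.05)
  # one macrostate holding everything: dG = 0 exactly
  expect_equal(macrostate_free_energies(pi_, rep(1L, 4))$dG, 0)
  # equal-weight split: dG difference 0
  fe2 <- macrostate_free_energies(c(0.25, 0.25, 0.25, 0.25),
                                  c(1L, 1L, 2L, 2L))
  expect_equal(diff(fe2$dG), 0)
  # (0.8, 0.2) at 310 K: ddG = RT ln 4 = 3.573 kJ/mol
  fe3 <- macrostate_free_energies(c(0.8, 0.2), c(1L, 2L),
                                  temperature_K = 310)
  expect_equal(fe3$ddG[2], 8.314462618e-3 * 310 * log(4), tolerance = 1e-9)
  expect_equal(round(fe3$ddG[2], 3), 3.573)
  # free-energy differences are invariant to rescaling pi
  fe4 <- macrostate_free_energies(pi_ * 7, c(1L, 1L, 2L, 2L))
  fe5 <- macrostate_free_energies(pi_, c(1L, 1L, 2L, 2L))
  expect_equal(diff(fe4$dG), diff(fe5$dG), tolerance = 1e-12)
  # empty macrostate is flagged and infinite
  expect_warning(fe6 <- macrostate_free_energies(pi_, c(1L, 1L, 1L, 3L)),
                 "empty")
  expect_equal(fe6$dG[2], Inf)
})
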