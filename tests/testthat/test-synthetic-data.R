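test_that("chain constructor validates its invariants", {
  P <- matrix(c(0.9, 0.1, 0.5, 0.5), 2, byrow = TRUE)
  means <- matrix(c(3, 3, 3, 3, 8, 8, 8, 8), 2, 4, byrow = TRUE)
  ch <- ground_truth_chain(P, 1, means, 0.2, c("bound", "unbound"))
  expect_s3_class(ch, "ground_truth_chain")
  expect_error(ground_truth_chain(matrix(c(0.9, 0.2, 0.5, 0.5), 2,
                                         byrow = TRUE),
                                  1, means, 0.2, c("bound", "unbound")),
               "sum to 1")
  expect_error(ground_truth_chain(P, 1, means, 0, c("bound", "unbound")),
               "positive")
  expect_error(ground_truth_chain(P, 1, means[, 1:3], 0.2,
                                  c("bound", "unbound")), "n x 4")
})

test_that("identity transition matrix gives constant trajectories and an absorbing-state warning", {
  means <- matrix(5, 2, 4)
  ch <- ground_truth_chain(diag(2), 1, means, 0.1, c("bound", "unbound"))
  expect_warning(labs <- simulate_markov_chain(ch, 100, 2, seed = 3),
                 "absorbing")
  for (s in labs) expect_length(unique(s), 1L)
})

test_that("empirical transition frequencies match the matrix within 3 binomial SEs", {
  P <- matrix(c(0.9, 0.1, 0.5, 0.5), 2, byrow = TRUE)
  ch <- ground_truth_chain(P, 1, matrix(c(3, 3, 3, 3, 8, 8, 8, 8), 2, 4,
                                        byrow = TRUE),
                           0.2, c("bound", "unbound"))
  s <- simulate_markov_chain(ch, 1e6, 1, seed = 11)[[1]]
  i <- s[-length(s)]
  j <- s[-1]
  for (a in 1:2) {
    n_a <- sum(i == a)
    for (b in 1:2) {
      phat <- sum(i == a & j == b) / n_a
      se <- sqrt(P[a, b] * (1 - P[a, b]) / n_a)
      expect_lt(abs(phat - P[a, b]), 3 * se)
    }
  }
})

test_that("stationary occupancies converge to the analytic stationary distribution", {
  ch <- example_dimer_chain("asymmetric")
  pi_true <- stationary_distribution(ch$transition_matrix)
  s <- simulate_markov_chain(ch, 1e6, 1, seed = 5)[[1]]
  occ <- tabulate(s, ch$n_states) / length(s)
  expect_lt(0.5 * sum(abs(occ - pi_true)), 0.01)  # total variation
})

test_that("the replica plan of 15 x 5 us yields 75 us of aggregate simulated time", {
  ch <- example_dimer_chain("asymmetric", lag_step_ns = 5)
  n_steps <- 5000 / ch$lag_step_ns  # 5 us per replica
  labs <- simulate_markov_chain(ch, n_steps, 15, seed = 1)
  expect_length(labs, 15L)
  agg_ns <- sum(vapply(labs, length, 1L)) * ch$lag_step_ns
  expect_equal(agg_ns / 1000, 75)
})

test_that("seeds control reproducibility", {
  ch <- example_dimer_chain("symmetric")
  a <- simulate_markov_chain(ch, 500, 2, seed = 9)
  b <- simulate_markov_chain(ch, 500, 2, seed = 9)
  c_ <- simulate_markov_chain(ch, 500, 2, seed = 10)
  expect_identical(unclass(a)[1:2], unclass(b)[1:2])
  expect_false(identical(unclass(a)[1:2], unclass(c_)[1:2]))
  fa <- emit_distance_trajectories(a, ch, seed = 4)
  fb <- emit_distance_trajectories(b, ch, seed = 4)
  expect_identical(unclass(fa)[1:2], unclass(fb)[1:2])
})

test_that("dissociated start puts every replica in an unbound state", {
  ch <- example_dimer_chain("asymmetric")
  labs <- simulate_markov_chain(ch, 10, 20, seed = 2, start = "unbound")
  first <- vapply(labs, `[`, 1L, 1)
  expect_true(all(ch$state_labels[first] == "unbound"))
})

test_that("emissions have the designed means and truncate at zero", {
  # zero-noise limit: features equal the visited state means exactly
  ch <- example_dimer_chain("asymmetric", emission_sd = 1e-12)
  labs <- simulate_markov_chain(ch, 200, 1, seed = 3)
  f <- emit_distance_trajectories(labs, ch, seed = 3)[[1]]
  expect_equal(f, unname(ch$emission_means[labs[[1]], ]),
               ignore_attr = TRUE, tolerance = 1e-9)
  # CLT: 1-state chain at 8 nm, column means -> 8 within 3*sd/sqrt(T)
  one <- ground_truth_chain(matrix(1, 1, 1), 1, matrix(8, 1, 4), 0.5,
                            "unbound")
  suppressWarnings(l1 <- simulate_markov_chain(one, 20000, 1, seed = 6))
  f1 <- emit_distance_trajectories(l1, one, seed = 6)[[1]]
  expect_true(all(abs(colMeans(f1) - 8) < 3 * 0.5 / sqrt(nrow(f1))))
  expect_true(all(f1 >= 0))
  # out-of-range label reports replica and frame
  bad <- list(c(1L, 7L, 1L))
  expect_error(emit_distance_trajectories(bad, ch, seed = 1),
               "replica 1, frame 2")
})

test_that("event detection on emitted monomer-distance proxy recovers the basin sequence", {
  ch <- example_dimer_chain("asymmetric", emission_sd = 0.2)
  labs <- simulate_markov_chain(ch, 5000, 1, seed = 13)
  f <- emit_distance_trajectories(labs, ch, seed = 13)
  mono <- rowMeans(f[[1]])
  ev <- detect_association_events(mono, 6, 7, frame_interval_ns = 5)
  # reconstruct the per-frame bound/unbound calls from the segments
  calls <- rep(NA_character_, length(mono))
  seg <- ev$segments
  for (r in seq_len(nrow(seg))) {
    idx <- (seg$start_ns[r] / 5 + 1):(seg$end_ns[r] / 5)
    calls[idx] <- seg$state[r]
  }
  truth <- ch$state_labels[labs[[1]]]
  ok <- calls != "intermediate"
  expect_gt(mean(calls[ok] == truth[ok]), 0.99)
})

test_that("frozen Brownian dynamics leaves coordinates constant", {
  p <- langevin_params(diffusion_coeff = 0, rot_diffusion_coeff = 0,
                       well_depth = 0, n_steps = 20, seed = 1)
  ens <- simulate_langevin_dimerization(p)
  a <- ens$replicas[[1]]
  for (t in 2:dim(a)[1]) expect_equal(a[t, , ], a[1, , ])
  # and the initial separation is the dissociated 8.0 nm configuration
  d0 <- monomer_com_distance(ens)[[1]][1]
  expect_equal(d0, 8, tolerance = 1e-9)
})

test_that("bound-state occupancy without a well matches the geometric pair-volume fraction", {
  p <- langevin_params(well_depth = 0, contact_radius = 5, box_half_width = 7,
                       diffusion_coeff = 1.5, rot_diffusion_coeff = 0,
                       dt = 0.5, n_steps = 30000, seed = 21)
  ens <- simulate_langevin_dimerization(p)
  d <- monomer_com_distance(ens)[[1]]
  occ <- mean(d < p$contact_radius)
  # oracle: numeric integration of the Boltzmann weight (uniform measure) by
  # Monte Carlo over independent COM pairs in the box
  set.seed(99)
  n_mc <- 2e5
  x1 <- matrix(stats::runif(3 * n_mc, -7, 7), ncol = 3)
  x2 <- matrix(stats::runif(3 * n_mc, -7, 7), ncol = 3)
  p_geom <- mean(sqrt(rowSums((x1 - x2)^2)) < p$contact_radius)
  expect_lt(abs(occ - p_geom), 0.05)
})

test_that("a deep well binds longer and more often than a shallow one", {
  run <- function(depth) {
    p <- langevin_params(well_depth = depth, contact_radius = 4,
                         box_half_width = 6, diffusion_coeff = 1.0,
                         rot_diffusion_coeff = 0.05, dt = 0.05,
                         well_width = 1.0, n_steps = 40000, seed = 31)
    monomer_com_distance(simulate_langevin_dimerization(p))[[1]]
  }
  d_deep <- run(8)
  d_shallow <- run(1)
  expect_gt(mean(d_deep < 4), mean(d_shallow < 4))
  # brute-force event counting: mean unbound dwell ~ association MFPT, mean
  # bound dwell longer for the deep well
  dwell <- function(d) {
    ev <- detect_association_events(d, 4, 4.8, frame_interval_ns = 0.5)
    seg <- ev$segments
    c(bound = mean(seg$dwell_ns[seg$state == "bound"]),
      n_bind = ev$n_binding)
  }
  expect_gt(dwell(d_deep)["bound"], dwell(d_shallow)["bound"])
})

test_that("Brownian simulator keeps body COMs inside the box and bead count fixed", {
  p <- langevin_params(n_steps = 2000, seed = 8, diffusion_coeff = 0.5)
  ens <- simulate_langevin_dimerization(p)
  a <- ens$replicas[[1]]
  expect_equal(dim(a)[2], 2 * 2 * p$beads_per_domain)
  nb <- 2 * p$beads_per_domain
  for (t in seq(1, dim(a)[1], by = 97)) {
    com1 <- colMeans(a[t, 1:nb, ])
    com2 <- colMeans(a[t, nb + 1:nb, ])
    expect_true(all(abs(c(com1, com2)) <= p$box_half_width + 1e-9))
  }
})

test_that("an unstable time step is rejected", {
  expect_error(
    simulate_langevin_dimerization(
      langevin_params(diffusion_coeff = 500, dt = 10, box_half_width = 7,
                      n_steps = 100)),
    "displacement|step")
})
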