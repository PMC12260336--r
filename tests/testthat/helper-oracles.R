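# Independent oracles and fixture builders used across the test files.
# Everything here is deliberately written without calling the package
# functions under test.

# --- Monte Carlo mean hitting time (vectorized over paths) -----------------
# Samples n_paths trajectories of the chain P from source_dist and records
# the first time each one enters the target set. Independent of the
# package's linear-solve MFPT.
mc_hitting_time <- function(P, tau, source_dist, target, n_paths,
                            seed = 1, max_steps = 1e6) {
  set.seed(seed)
  n <- nrow(P)
  cur <- sample.int(n, n_paths, replace = TRUE, prob = source_dist)
  steps <- integer(n_paths)
  alive <- !(cur %in% target)
  t <- 0L
  while (any(alive) && t < max_steps) {
    t <- t + 1L
    idx <- which(alive)
    prev <- cur[idx]
    for (s in unique(prev)) {
      sel <- idx[prev == s]
      cur[sel] <- sample.int(n, length(sel), replace = TRUE, prob = P[s, ])
    }
    hit <- idx[cur[idx] %in% target]
    steps[hit] <- t
    alive[hit] <- FALSE
  }
  stopifnot(!any(alive))
  list(mean = mean(steps) * tau, se = stats::sd(steps) * tau / sqrt(n_paths))
}

# --- independent chain sampler --------------------------------------------
# Plain categorical sampler, step by step via sample.int; used as a data
# source independent of simulate_markov_chain where the generator itself is
# under test.
sample_chain_naive <- function(P, n_steps, init, seed = 1) {
  set.seed(seed)
  s <- integer(n_steps)
  s[1] <- init
  n <- nrow(P)
  for (t in 2:n_steps) {
    s[t] <- sample.int(n, 1L, prob = P[s[t - 1L], ])
  }
  s
}

# --- reversible matrices ---------------------------------------------------
# Build a reversible transition matrix from a symmetric positive weight
# matrix: T_ij = w_ij / sum_j w_ij satisfies detailed balance with
# pi_i proportional to row sums of w.
reversible_from_weights <- function(W) {
  W <- (W + t(W)) / 2
  W / rowSums(W)
}

# Block-structured reversible chain: strong weights within blocks, weak
# (eps) between; returns the matrix and the planted block labels.
planted_block_chain <- function(block_sizes, eps = 0.01, seed = 1) {
  set.seed(seed)
  n <- sum(block_sizes)
  lab <- rep(seq_along(block_sizes), block_sizes)
  W <- matrix(eps * stats::runif(n * n, 0.5, 1), n, n)
  for (b in seq_along(block_sizes)) {
    sel <- which(lab == b)
    W[sel, sel] <- stats::runif(length(sel)^2, 0.5, 1.5)
  }
  list(P = reversible_from_weights(W), labels = lab)
}

# --- toy ensemble builders -------------------------------------------------
# Minimal two-chain topology: one bead per domain per chain (4 beads).
toy_topology <- function(masses = rep(1, 4)) {
  data.frame(bead = 1:4,
             chain = c("A", "A", "B", "B"),
             domain = c("Ntd", "Ctd", "Ntd", "Ctd"),
             mass = masses, stringsAsFactors = FALSE)
}

# Ensemble with explicitly given frames: coords is a list of 4x3 matrices
# (one per frame) or a T x 4 x 3 array.
toy_ensemble <- function(frames, topology = toy_topology(),
                         frame_interval_ns = 1) {
  if (is.list(frames)) {
    arr <- array(NA_real_, c(length(frames), nrow(topology), 3))
    for (t in seq_along(frames)) arr[t, , ] <- frames[[t]]
  } else {
    arr <- frames
  }
  trajectory_ensemble(list(arr), topology, frame_interval_ns)
}

# random proper rotation matrix
random_proper_rotation <- function(seed = 1) {
  set.seed(seed)
  qr_res <- qr(matrix(stats::rnorm(9), 3, 3))
  R <- qr.Q(qr_res)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# minimal stand-in for a projected feature set: list of matrices plus a
# frame interval attribute
make_feature_set_like <- function(mats, fi = 1) {
  structure(mats, frame_interval_ns = fi)
}

# AR(1) series with autocorrelation phi at lag 1, unit stationary variance
ar1_series <- function(n, phi, seed = 1) {
  set.seed(seed)
  as.numeric(stats::arima.sim(list(ar = phi), n = n,
                              sd = sqrt(1 - phi^2)))
}
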