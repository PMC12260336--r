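#' Ground-truth Markov-jump chain with distance emissions
#'
#' Defines a discrete-state Markov chain together with a Gaussian emission
#' model for the four inter-monomer domain centre-of-mass distances. The
#' chain provides exact ground-truth kinetics (stationary distribution,
#' MFPTs, timescales) against which every downstream estimator can be tested.
#'
#' Emissions are Normal(emission_means[state, ], emission_sd), truncated at
#' zero because distances are nonnegative. The emission standard deviation is
#' shared across states.
#'
#' @param transition_matrix n x n row-stochastic matrix of jump probabilities
#'   per lag step.
#' @param lag_step_ns Physical time per chain step, in ns.
#' @param emission_means n x 4 matrix of mean inter-domain distances (nm) per
#'   state, columns ordered (A.Ntd-B.Ntd, A.Ntd-B.Ctd, A.Ctd-B.Ntd,
#'   A.Ctd-B.Ctd).
#' @param emission_sd Shared emission standard deviation (nm), > 0.
#' @param state_labels Character vector tagging each state "bound" or
#'   "unbound".
#' @return Object of class \code{ground_truth_chain}.
#' @export
ground_truth_chain <- function(transition_matrix, lag_step_ns, emission_means,
                               emission_sd, state_labels) {
  check_stochastic(transition_matrix)
  n <- nrow(transition_matrix)
  emission_means <- as.matrix(emission_means)
  if (nrow(emission_means) != n || ncol(emission_means) != 4) {
    stop("'emission_means' must be an n x 4 matrix of distances (nm)",
         call. = FALSE)
  }
  if (!is.numeric(emission_sd) || length(emission_sd) != 1 || emission_sd <= 0) {
    stop("'emission_sd' must be a single positive number (nm)", call. = FALSE)
  }
  if (length(state_labels) != n ||
      !all(state_labels %in% c("bound", "unbound"))) {
    stop("'state_labels' must tag each state 'bound' or 'unbound'",
         call. = FALSE)
  }
  if (!is.numeric(lag_step_ns) || lag_step_ns <= 0) {
    stop("'lag_step_ns' must be positive", call. = FALSE)
  }
  structure(
    list(transition_matrix = transition_matrix,
         lag_step_ns = lag_step_ns,
         emission_means = emission_means,
         emission_sd = emission_sd,
         state_labels = state_labels,
         n_states = n),
    class = "ground_truth_chain")
}

#' @export
print.ground_truth_chain <- function(x, ...) {
  cat(sprintf("ground_truth_chain: %d states (%d bound, %d unbound), lag step %.3g ns, emission sd %.3g nm\n",
              x$n_states, sum(x$state_labels == "bound"),
              sum(x$state_labels == "unbound"), x$lag_step_ns, x$emission_sd))
  invisible(x)
}

#' Six-state example chain emulating reversible dimerization kinetics
#'
#' A canned ground-truth chain with two designed basins: a bound (dimeric)
#' basin of four states with fast internal mixing and an unbound (monomeric)
#' basin of two states, coupled by slow association/dissociation jumps.
#' Emission means place bound states below 6 nm and unbound states above
#' 7 nm, matching the dimeric/monomeric distance conventions used by the
#' event detector.
#'
#' The \code{"asymmetric"} preset plants dissociation roughly 24-fold slower
#' than association, the kinetic signature of a deamidation-stabilized dimer;
#' \code{"symmetric"} plants comparable association and dissociation times,
#' as seen for the wild-type protein.
#'
#' @param kind One of "asymmetric" or "symmetric".
#' @param lag_step_ns Time per chain step in ns (default 5, a typical MSM
#'   lag for coarse-grained association kinetics).
#' @param emission_sd Emission noise in nm.
#' @return A \code{ground_truth_chain}.
#' @export
example_dimer_chain <- function(kind = c("asymmetric", "symmetric"),
                                lag_step_ns = 5, emission_sd = 0.35) {
  kind <- match.arg(kind)
  # bound states 1-4, unbound states 5-6. Within-basin mixing is fast;
  # cross-basin jumps set the association/dissociation timescales.
  # Jump probabilities calibrated (against the exact MFPTs of the resulting
  # matrix) so that at a 5 ns lag step the planted kinetics are:
  #   asymmetric: association ~58 ns, dissociation ~1391 ns (~24-fold)
  #   symmetric:  association ~417 ns, dissociation ~520 ns
  # Within-basin mixing is faster than basin exit on both sides, so the
  # bound/unbound split is also the chain's dominant metastable 2-partition
  # (what PCCA++ should find).
  p_mix <- 0.12        # exchange inside the bound ring, per step
  p_mix_u <- 0.4       # exchange between the two unbound states
  if (kind == "asymmetric") {
    p_off <- 0.0072981  # bound -> unbound (slow dissociation)
    p_on  <- 0.08681    # unbound -> bound (fast association)
  } else {
    p_off <- 0.020031
    p_on  <- 0.011989
  }
  P <- matrix(0, 6, 6)
  # bound basin: ring exchange among 1..4; states 4 and 1 are the "early
  # dimer" gateways that can dissociate
  for (i in 1:4) {
    j <- if (i == 4) 1 else i + 1
    P[i, j] <- p_mix
    P[j, i] <- p_mix
  }
  P[4, 5] <- p_off
  P[1, 6] <- p_off
  # unbound basin: encounter-complex states 5 and 6 mix quickly and both
  # can associate
  P[5, 6] <- p_mix_u
  P[6, 5] <- p_mix_u
  P[5, 4] <- p_on
  P[6, 1] <- p_on
  diag(P) <- 1 - rowSums(P)
  means <- rbind(
    c(3.0, 3.6, 3.6, 3.0),   # late dimer, compact
    c(3.8, 3.2, 4.4, 3.8),   # late dimer, Ntd-Ctd contact
    c(4.4, 4.0, 4.0, 4.4),   # late dimer, antiparallel
    c(5.2, 5.0, 5.0, 5.2),   # early dimer (gateway)
    c(7.6, 7.8, 7.8, 7.6),   # encounter / just-dissociated
    c(9.2, 9.5, 9.5, 9.2))   # fully dissociated
  ground_truth_chain(P, lag_step_ns, means, emission_sd,
                     state_labels = c(rep("bound", 4), rep("unbound", 2)))
}

#' Simulate label trajectories from a ground-truth chain
#'
#' Draws discrete Markov-jump trajectories from the chain's transition
#' matrix. By default the initial state of each replica is sampled from the
#' stationary distribution so that empirical state counts are stationary;
#' \code{start = "unbound"} instead starts every replica in a random unbound
#' state, mirroring a dissociated initial condition.
#'
#' @param chain A \code{ground_truth_chain}.
#' @param n_steps Steps per replica (>= 2).
#' @param n_replicas Number of independent replicas.
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @param start "stationary", "unbound", or a fixed integer state.
#' @return List of integer state vectors (one per replica), class
#'   \code{discrete_trajectories}, with the chain's lag step attached as the
#'   frame interval.
#' @export
simulate_markov_chain <- function(chain, n_steps, n_replicas = 1, seed = 1,
                                  start = "stationary") {
  stopifnot(inherits(chain, "ground_truth_chain"))
  if (n_steps < 2) stop("'n_steps' must be >= 2", call. = FALSE)
  P <- chain$transition_matrix
  n <- nrow(P)
  if (any(diag(P) >= 1 - 1e-15)) {
    warning("chain has an absorbing state; MFPTs out of it are undefined",
            call. = FALSE)
  }
  pi0 <- stationary_distribution(P)
  cum <- t(apply(P, 1, cumsum))
  cum[, n] <- 1  # guard against rounding
  set.seed(seed)
  out <- vector("list", n_replicas)
  for (r in seq_len(n_replicas)) {
    s <- integer(n_steps)
    s[1L] <- if (identical(start, "stationary")) {
      sample.int(n, 1L, prob = pi0)
    } else if (identical(start, "unbound")) {
      unb <- which(chain$state_labels == "unbound")
      if (!length(unb)) stop("no unbound state to start from", call. = FALSE)
      unb[sample.int(length(unb), 1L)]
    } else {
      as.integer(start)
    }
    u <- stats::runif(n_steps)
    for (t in 2:n_steps) {
      row <- cum[s[t - 1L], ]
      s[t] <- 1L + sum(u[t] > row[-n])
    }
    out[[r]] <- s
  }
  structure(out, class = "discrete_trajectories",
            frame_interval_ns = chain$lag_step_ns, n_states = n)
}

#' Emit distance feature trajectories from label trajectories
#'
#' Converts discrete state labels into per-frame four-dimensional distance
#' observations using the chain's Gaussian emission model. Negative draws are
#' truncated at zero (distances are nonnegative).
#'
#' @param labels Output of \code{\link{simulate_markov_chain}} (or a list of
#'   integer vectors).
#' @param chain The \code{ground_truth_chain} that defines the emissions.
#' @param seed Integer seed for the emission noise.
#' @return A feature set: list of T x 4 matrices (nm) with the frame
#'   interval attached, class \code{feature_set}.
#' @export
emit_distance_trajectories <- function(labels, chain, seed = 1) {
  stopifnot(inherits(chain, "ground_truth_chain"))
  n <- chain$n_states
  set.seed(seed)
  feats <- vector("list", length(labels))
  for (r in seq_along(labels)) {
    s <- labels[[r]]
    bad <- which(s < 1L | s > n)
    if (length(bad)) {
      stop(sprintf("label out of range at replica %d, frame %d (state %d of %d)",
                   r, bad[1], s[bad[1]], n), call. = FALSE)
    }
    T_ <- length(s)
    x <- chain$emission_means[s, , drop = FALSE] +
      matrix(stats::rnorm(T_ * 4L, sd = chain$emission_sd), T_, 4L)
    x[x < 0] <- 0
    colnames(x) <- feature_names()
    feats[[r]] <- x
  }
  new_feature_set(feats,
                 frame_interval_ns = attr(labels, "frame_interval_ns") %||%
                   chain$lag_step_ns)
}

#' Parameters for the toy Brownian dimerization simulator
#'
#' @param well_depth Depth of the attractive contact well, in kT units.
#' @param contact_radius COM separation (nm) below which the well is at full
#'   depth plus the switching edge; the well is zero beyond it.
#' @param box_half_width Half-width (nm) of the cubic reflecting box centred
#'   at the origin.
#' @param diffusion_coeff Translational diffusion coefficient per body,
#'   nm^2/ns.
#' @param rot_diffusion_coeff Rotational diffusion coefficient, rad^2/ns.
#' @param dt Time step = frame interval, ns.
#' @param n_steps Recorded frames per replica.
#' @param n_replicas Number of replicas.
#' @param beads_per_domain Beads per domain (each body has two domains).
#' @param well_width Width (nm) of the half-cosine switching edge that takes
#'   the well smoothly from full depth to zero at the contact radius, so the
#'   Brownian force stays finite.
#' @param identical_start If TRUE all replicas start from identical
#'   coordinates (identity orientations); if FALSE orientations are
#'   randomized per replica. Either way the two bodies start at 8.0 nm COM
#'   separation along x.
#' @param seed Integer seed.
#' @return Object of class \code{langevin_params}.
#' @export
langevin_params <- function(well_depth = 4, contact_radius = 6,
                            box_half_width = 9, diffusion_coeff = 0.15,
                            rot_diffusion_coeff = 0.05, dt = 1,
                            n_steps = 20000, n_replicas = 1,
                            beads_per_domain = 4, well_width = 0.5,
                            identical_start = TRUE, seed = 1) {
  if (dt <= 0) stop("'dt' must be positive", call. = FALSE)
  if (contact_radius >= box_half_width) {
    stop("'contact_radius' must be smaller than 'box_half_width'",
         call. = FALSE)
  }
  if (n_replicas < 1) stop("'n_replicas' must be >= 1", call. = FALSE)
  if (well_depth < 0) stop("'well_depth' must be >= 0", call. = FALSE)
  structure(as.list(environment()), class = "langevin_params")
}

# local bead geometry of one rigid body: two domains of beads_per_domain
# beads, domain centres at +/- 1 nm along the body x axis, beads on a small
# tetrahedral shell of radius 0.5 nm around each centre
body_template <- function(beads_per_domain) {
  shell <- matrix(c(1, 1, 1, 1, -1, -1, -1, 1, -1, -1, -1, 1),
                  ncol = 3, byrow = TRUE) / sqrt(3) * 0.5
  one_domain <- function(centre_x) {
    k <- beads_per_domain
    pts <- shell[rep_len(seq_len(4), k), , drop = FALSE]
    if (k > 4) pts <- pts * rep(seq_len(ceiling(k / 4)), each = 4)[seq_len(k)] / ceiling(k / 4)
    sweep(pts[seq_len(k), , drop = FALSE], 2, c(centre_x, 0, 0), `+`)
  }
  rbind(one_domain(-1), one_domain(1))
}

# small random rotation matrix: axis uniform on the sphere, angle N(0, sd)
random_rotation <- function(sd) {
  ax <- stats::rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  th <- stats::rnorm(1, sd = sd)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Simulate a toy Brownian dimerization of two rigid two-domain bodies
#'
#' Overdamped Euler-Maruyama dynamics of two rigid bodies (each two domains
#' of \code{beads_per_domain} beads) in a cubic reflecting box. The bodies
#' interact through a flat-bottom attractive well acting on their COM
#' separation: full depth \code{well_depth} (kT) below
#' \code{contact_radius - well_width}, switched smoothly to zero at
#' \code{contact_radius} by a half-cosine edge. Rigid-body rotational
#' diffusion is included; there are no internal degrees of freedom. The two
#' bodies start 8.0 nm apart, the dissociated configuration.
#'
#' @param params A \code{\link{langevin_params}} object.
#' @return A \code{\link{trajectory_ensemble}} with frame interval
#'   \code{dt} ns.
#' @export
simulate_langevin_dimerization <- function(params) {
  stopifnot(inherits(params, "langevin_params"))
  p <- params
  L <- p$box_half_width
  tmpl <- body_template(p$beads_per_domain)
  nb <- nrow(tmpl)  # beads per body
  sd_tr <- sqrt(2 * p$diffusion_coeff * p$dt)
  sd_rot <- sqrt(2 * p$rot_diffusion_coeff * p$dt)
  if (sd_tr * 6 > 2 * L) {
    stop("time step too large: typical displacement exceeds the box size",
         call. = FALSE)
  }
  # force magnitude dU/dr (kT/nm) on the switching edge
  edge_lo <- p$contact_radius - p$well_width
  dUdr <- function(r) {
    if (r <= edge_lo || r >= p$contact_radius) return(0)
    p$well_depth * pi / (2 * p$well_width) *
      sin(pi * (r - edge_lo) / p$well_width)
  }
  set.seed(p$seed)
  replicas <- vector("list", p$n_replicas)
  for (rep_i in seq_len(p$n_replicas)) {
    c1 <- c(-4, 0, 0); c2 <- c(4, 0, 0)   # 8.0 nm initial separation
    R1 <- diag(3); R2 <- diag(3)
    if (!p$identical_start) { R1 <- random_rotation(pi); R2 <- random_rotation(pi) }
    coords <- array(NA_real_, c(p$n_steps, 2L * nb, 3L))
    for (t in seq_len(p$n_steps)) {
      coords[t, seq_len(nb), ] <- sweep(tmpl %*% t(R1), 2, c1, `+`)
      coords[t, nb + seq_len(nb), ] <- sweep(tmpl %*% t(R2), 2, c2, `+`)
      if (t == p$n_steps) break
      d <- c2 - c1
      r <- sqrt(sum(d^2))
      f <- dUdr(r)                       # >0 pulls the bodies together
      drift <- if (f > 0) p$diffusion_coeff * f * p$dt * d / r else c(0, 0, 0)
      step1 <- drift + stats::rnorm(3, sd = sd_tr)
      step2 <- -drift + stats::rnorm(3, sd = sd_tr)
      if (max(abs(step1), abs(step2)) > 2 * L) {
        stop("unstable step: displacement exceeds the box size (reduce dt)",
             call. = FALSE)
      }
      c1 <- reflect_into_box(c1 + step1, L)
      c2 <- reflect_into_box(c2 + step2, L)
      if (sd_rot > 0) {
        R1 <- random_rotation(sd_rot) %*% R1
        R2 <- random_rotation(sd_rot) %*% R2
      }
    }
    replicas[[rep_i]] <- coords
  }
  topo <- data.frame(
    bead = seq_len(2L * nb),
    chain = rep(c("A", "B"), each = nb),
    domain = rep(rep(c("Ntd", "Ctd"), each = p$beads_per_domain), 2L),
    mass = 72,  # coarse-grained bead mass, amu
    stringsAsFactors = FALSE)
  trajectory_ensemble(replicas, topo, frame_interval_ns = p$dt)
}

# reflecting boundary on [-L, L] per axis
reflect_into_box <- function(x, L) {
  for (k in 1:3) {
    while (x[k] > L || x[k] < -L) {
      if (x[k] > L) x[k] <- 2 * L - x[k]
      if (x[k] < -L) x[k] <- -2 * L - x[k]
    }
  }
  x
}
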