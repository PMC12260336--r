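#' Discretize projected trajectories into microstates with k-means
#'
#' Clusters the pooled frames with k-means (k-means++ initialization, Lloyd
#' iterations) and assigns every frame to its nearest centre by Euclidean
#' distance, ties broken by the lowest centre index. An empty cluster during
#' the Lloyd iterations is re-seeded at the point farthest from its centre.
#' For large data sets the centres can be fitted on a random subsample
#' (\code{fit_frames}) and all frames assigned afterwards, which is standard
#' practice for trajectory discretization.
#'
#' @param projected List of T x m matrices (e.g. from
#'   \code{\link{project_tica}}).
#' @param k Number of microstates.
#' @param seed Integer seed for initialization and subsampling.
#' @param max_iter Maximum Lloyd iterations.
#' @param tol Relative change in inertia below which iterations stop.
#' @param fit_frames If non-NULL and smaller than the pooled frame count,
#'   the number of randomly subsampled frames used to fit the centres.
#' @return Object of class \code{discretization} with centres, per-replica
#'   integer label vectors, the seed and the final inertia.
#' @export
cluster_microstates <- function(projected, k, seed = 42, max_iter = 200,
                                tol = 1e-8, fit_frames = NULL) {
  mats <- lapply(projected, as.matrix)
  X <- do.call(rbind, mats)
  n <- nrow(X)
  if (n < k) stop(sprintf("k = %d exceeds the %d available frames", k, n),
                  call. = FALSE)
  set.seed(seed)
  fit_idx <- if (!is.null(fit_frames) && fit_frames < n) {
    sort(sample.int(n, fit_frames))
  } else {
    seq_len(n)
  }
  Xf <- X[fit_idx, , drop = FALSE]
  if (nrow(Xf) < k) stop("'fit_frames' must be at least k", call. = FALSE)
  centers <- kmeanspp_init(Xf, k)
  prev_inertia <- Inf
  for (iter in seq_len(max_iter)) {
    asg <- nearest_center(Xf, centers)
    inertia <- sum((Xf - centers[asg$label, , drop = FALSE])^2)
    for (j in seq_len(k)) {
      sel <- asg$label == j
      if (!any(sel)) {
        # re-seed an empty cluster at the globally farthest point
        far <- which.max(asg$d2)
        centers[j, ] <- Xf[far, ]
        asg$d2[far] <- 0
        message(sprintf("k-means: re-seeded empty cluster %d at the farthest point", j))
      } else {
        centers[j, ] <- colMeans(Xf[sel, , drop = FALSE])
      }
    }
    if (is.finite(prev_inertia) &&
        abs(prev_inertia - inertia) <= tol * max(prev_inertia, 1e-300)) break
    prev_inertia <- inertia
  }
  labels_all <- nearest_center(X, centers)$label
  inertia <- sum((X - centers[labels_all, , drop = FALSE])^2)
  nf <- vapply(mats, nrow, 1L)
  splits <- rep(seq_along(mats), nf)
  labels <- split(labels_all, splits)
  names(labels) <- NULL
  structure(list(centers = centers, labels = labels, seed = seed,
                 inertia = inertia, iterations = iter,
                 frame_interval_ns = attr(projected, "frame_interval_ns")),
            class = "discretization")
}

#' @export
print.discretization <- function(x, ...) {
  cat(sprintf("discretization: %d microstates over %d replica(s), inertia %.4g (%d Lloyd iterations, seed %d)\n",
              nrow(x$centers), length(x$labels), x$inertia, x$iterations,
              x$seed))
  invisible(x)
}

# k-means++ seeding (Arthur & Vassilvitskii): each new centre drawn with
# probability proportional to squared distance from the nearest chosen one
kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  i <- sample.int(n, 1L)
  centers[1L, ] <- X[i, ]
  d2 <- rowSums(sweep(X, 2, centers[1L, ])^2)
  for (j in seq_len(k)[-1L]) {
    i <- if (sum(d2) <= 0) sample.int(n, 1L) else
      sample.int(n, 1L, prob = d2 / sum(d2))
    centers[j, ] <- X[i, ]
    d2 <- pmin(d2, rowSums(sweep(X, 2, centers[j, ])^2))
  }
  centers
}

# chunked nearest-centre assignment; ties go to the lowest centre index
# (max.col with ties.method = "first" on negated distances)
nearest_center <- function(X, centers, chunk = 50000L) {
  n <- nrow(X)
  cn2 <- rowSums(centers^2)
  label <- integer(n)
  d2 <- numeric(n)
  for (lo in seq(1L, n, by = chunk)) {
    hi <- min(lo + chunk - 1L, n)
    Xi <- X[lo:hi, , drop = FALSE]
    D <- sweep(-2 * Xi %*% t(centers), 2, cn2, `+`)  # d2 minus rowSums(Xi^2)
    lab <- max.col(-D, ties.method = "first")
    label[lo:hi] <- lab
    d2[lo:hi] <- D[cbind(seq_len(hi - lo + 1L), lab)] + rowSums(Xi^2)
  }
  d2[d2 < 0] <- 0
  list(label = label, d2 = d2)
}

#' Count transitions and find the largest connected set
#'
#' Sliding-window transition counts \eqn{C_{ij} = \#\{t: s_t = i,
#' s_{t+\mathrm{lag}} = j\}} pooled over replicas (never across replica
#' boundaries), followed by restriction to the largest strongly connected
#' component of the count graph. Frames outside the connected set are
#' excluded from all MSM quantities and reported via the coverage fraction.
#'
#' @param labels A \code{discretization}, a \code{discrete_trajectories}
#'   object, or a plain list of integer vectors.
#' @param lag_ns Count lag in ns.
#' @param frame_interval_ns Frame interval override.
#' @param n_states Number of microstates (default: the maximum label seen).
#' @return List with the full count matrix, the active-set count matrix,
#'   the active set (original microstate indices), the lag, and the
#'   coverage fraction; class \code{msm_counts}.
#' @export
count_and_connect <- function(labels, lag_ns, frame_interval_ns = NULL,
                              n_states = NULL) {
  lab_list <- if (inherits(labels, "discretization")) labels$labels else labels
  fi <- frame_interval_ns %||% attr(labels, "frame_interval_ns") %||%
    (if (inherits(labels, "discretization")) labels$frame_interval_ns) %||% 1
  lagf <- lag_to_frames(lag_ns, fi)
  k <- as.integer(n_states %||% max(vapply(lab_list, max, numeric(1))))
  C <- matrix(0, k, k)
  usable <- 0L
  for (s in lab_list) {
    T_ <- length(s)
    if (T_ <= lagf) next
    usable <- usable + 1L
    i <- s[seq_len(T_ - lagf)]
    j <- s[seq_len(T_ - lagf) + lagf]
    tab <- tabulate(i + (j - 1L) * k, nbins = k * k)
    C <- C + matrix(tab, k, k)
  }
  if (usable == 0L) stop("no replica is longer than the lag", call. = FALSE)
  g <- igraph::graph_from_adjacency_matrix(1 * (C > 0), mode = "directed")
  comp <- igraph::components(g, mode = "strong")
  sizes <- tabulate(comp$membership, comp$no)
  # largest component by state count; counts within it break ties
  best <- which(sizes == max(sizes))
  if (length(best) > 1) {
    wt <- vapply(best, function(b) {
      m <- comp$membership == b
      sum(C[m, m])
    }, 0)
    best <- best[which.max(wt)]
  }
  active <- which(comp$membership == best)
  if (!length(active)) stop("empty active set", call. = FALSE)
  in_active <- sum(vapply(lab_list, function(s) sum(s %in% active), 0))
  total <- sum(vapply(lab_list, length, 0))
  structure(list(counts_full = C,
                 counts = C[active, active, drop = FALSE],
                 active_set = active, lag_frames = lagf,
                 lag_ns = lagf * fi, frame_interval_ns = fi,
                 coverage = in_active / total),
            class = "msm_counts")
}

#' Maximum-likelihood reversible transition matrix
#'
#' Estimates the reversible transition matrix maximizing the likelihood of
#' the transition counts under the detailed-balance constraint, via the
#' standard self-consistent iteration on the symmetric flux variables
#' \eqn{x_{ij} = x_{ji}}:
#' \deqn{x_{ij} \leftarrow (c_{ij} + c_{ji}) / (c_i/x_i + c_j/x_j)}
#' with \eqn{T_{ij} = x_{ij}/x_i} and \eqn{\pi_i = x_i/\sum x}. Iterations
#' stop when the maximum relative change falls below \code{tol}. The
#' stationary distribution is additionally verified against the leading
#' left eigenvector.
#'
#' @param counts An \code{msm_counts} object or a connected count matrix.
#' @param lag_ns Lag time in ns (taken from \code{counts} when available).
#' @param tol Convergence tolerance on the maximum relative change.
#' @param max_iter Maximum number of sweeps.
#' @return Object of class \code{msm_model}: reversible row-stochastic
#'   \code{transition_matrix} on the active set, \code{stationary}
#'   distribution, real sorted \code{eigenvalues}, count matrix, active
#'   set, lag, and convergence information.
#' @export
estimate_reversible_transition_matrix <- function(counts, lag_ns = NULL,
                                                  tol = 1e-10,
                                                  max_iter = 1e6) {
  if (inherits(counts, "msm_counts")) {
    C <- counts$counts
    active <- counts$active_set
    lag_ns <- lag_ns %||% counts$lag_ns
    fi <- counts$frame_interval_ns
    lagf <- counts$lag_frames
    coverage <- counts$coverage
  } else {
    C <- as.matrix(counts)
    active <- seq_len(nrow(C))
    lag_ns <- lag_ns %||% 1
    fi <- lag_ns
    lagf <- 1L
    coverage <- 1
    g <- igraph::graph_from_adjacency_matrix(1 * (C > 0), mode = "directed")
    if (igraph::components(g, mode = "strong")$no != 1) {
      stop("count matrix is not strongly connected; run count_and_connect first",
           call. = FALSE)
    }
  }
  k <- nrow(C)
  Csym <- C + t(C)
  ci <- rowSums(C)
  x <- Csym / sum(Csym)
  resid <- Inf
  for (iter in seq_len(max_iter)) {
    xi <- rowSums(x)
    denom <- outer(ci / xi, ci / xi, `+`)
    x_new <- Csym / denom
    x_new[Csym == 0] <- 0
    x_new <- x_new / sum(x_new)
    resid <- max(abs(x_new - x) / pmax(x, 1e-300))
    x <- x_new
    if (resid < tol) break
  }
  if (resid >= tol) {
    stop(sprintf("reversible estimator did not converge (residual %.3g after %d sweeps)",
                 resid, max_iter), call. = FALSE)
  }
  xi <- rowSums(x)
  T_ <- x / xi
  pi_ <- xi / sum(xi)
  # spectrum through the symmetric similarity transform (real for
  # reversible T); right eigenvectors recovered as D^{-1/2} v
  sp <- sqrt(pi_)
  S <- (T_ * outer(sp, 1 / sp))
  S <- (S + t(S)) / 2
  es <- eigen(S, symmetric = TRUE)
  ord <- order(es$values, decreasing = TRUE)
  evals <- es$values[ord]
  right_ev <- es$vectors[, ord, drop = FALSE] / sp
  # verify pi against the leading left eigenvector
  pi_eig <- sp * es$vectors[, ord[1]]
  pi_eig <- pi_eig * sign(sum(pi_eig))
  pi_eig <- pi_eig / sum(pi_eig)
  pi_dev <- max(abs(pi_eig - pi_))
  structure(list(transition_matrix = T_, stationary = pi_,
                 eigenvalues = evals, right_eigenvectors = right_ev,
                 counts = C, active_set = active, n_micro = k,
                 lag_ns = lag_ns, lag_frames = lagf, frame_interval_ns = fi,
                 coverage = coverage,
                 convergence = list(iterations = iter, residual = resid,
                                    stationary_eigen_dev = pi_dev)),
            class = "msm_model")
}

#' Estimate a reversible MSM from discretized trajectories
#'
#' Convenience wrapper: \code{\link{count_and_connect}} followed by
#' \code{\link{estimate_reversible_transition_matrix}}.
#'
#' @inheritParams count_and_connect
#' @param ... Passed to \code{estimate_reversible_transition_matrix}.
#' @return An \code{msm_model}.
#' @export
estimate_msm <- function(labels, lag_ns, frame_interval_ns = NULL,
                         n_states = NULL, ...) {
  cc <- count_and_connect(labels, lag_ns, frame_interval_ns, n_states)
  estimate_reversible_transition_matrix(cc, ...)
}

#' @export
print.msm_model <- function(x, ...) {
  cat(sprintf("msm_model: %d microstates (active set), lag %.3g ns, coverage %.1f%%\n",
              x$n_micro, x$lag_ns, 100 * x$coverage))
  nt <- min(4, length(x$eigenvalues) - 1)
  if (nt > 0) {
    ts <- -x$lag_ns / log(pmax(x$eigenvalues[1 + seq_len(nt)], 1e-300))
    cat("  leading implied timescales (ns):", sprintf("%.4g", ts), "\n")
  }
  invisible(x)
}

#' Implied relaxation timescales as a function of lag time
#'
#' For each lag, estimates a reversible MSM and reports
#' \eqn{t_i = -\tau / \ln \lambda_i} for the non-unit eigenvalues. Flat
#' timescale curves indicate Markovian behaviour at that discretization; the
#' plateau guides the lag choice. Non-positive eigenvalues have no defined
#' timescale and are reported as NA.
#'
#' @inheritParams count_and_connect
#' @param lags_ns Numeric vector of lags (ns).
#' @param n_timescales How many timescales to report per lag.
#' @return Data frame with columns lag_ns, index (2 = slowest), eigenvalue,
#'   timescale_ns.
#' @export
implied_timescales <- function(labels, lags_ns, n_timescales = 5,
                               frame_interval_ns = NULL, n_states = NULL) {
  out <- lapply(lags_ns, function(lag) {
    m <- estimate_msm(labels, lag, frame_interval_ns, n_states)
    nev <- min(n_timescales + 1, length(m$eigenvalues))
    lam <- m$eigenvalues[2:nev]
    bad <- lam <= 0
    if (any(bad)) {
      message(sprintf("lag %.3g ns: %d non-positive eigenvalue(s); timescale undefined",
                      lag, sum(bad)))
    }
    ts <- ifelse(lam > 0, -m$lag_ns / log(lam), NA_real_)
    data.frame(lag_ns = m$lag_ns, index = 1 + seq_along(lam),
               eigenvalue = lam, timescale_ns = ts)
  })
  do.call(rbind, out)
}

#' Chapman-Kolmogorov test
#'
#' Compares, for each metastable set and each lag multiple k, the residence
#' probability predicted by propagating the model, \eqn{T(\tau)^k}
#' aggregated over the set, with the same quantity from a model re-estimated
#' directly at lag \eqn{k\tau}. Agreement within the uncertainty bands
#' (normal approximation to the multinomial transition counts) validates the
#' Markov assumption at lag \eqn{\tau}.
#'
#' @param model An \code{msm_model}.
#' @param labels The discretized trajectories the model was built from.
#' @param macrosets A \code{macrostate_model} or a list of microstate index
#'   vectors (original indexing) partitioning the active set.
#' @param factors Integer lag multiples (k = 1 gives the identity check).
#' @return Data frame of class \code{ck_result}: set, factor, predicted,
#'   estimated, se (band half-width).
#' @export
ck_test <- function(model, labels, macrosets, factors = 1:5) {
  stopifnot(inherits(model, "msm_model"))
  sets <- macro_sets(macrosets, model)
  lab_list <- if (inherits(labels, "discretization")) labels$labels else labels
  max_len <- max(vapply(lab_list, length, 1L))
  rows <- list()
  for (k in sort(unique(as.integer(factors)))) {
    if (k < 1) next
    if (k * model$lag_frames >= max_len) {
      message(sprintf("CK factor %d dropped: lag %d frames exceeds every replica", k,
                      k * model$lag_frames))
      next
    }
    # predicted: propagate the tau-model k times
    Tk <- matrix_power(model$transition_matrix, k)
    est_model <- estimate_msm(lab_list, k * model$lag_ns,
                              frame_interval_ns = model$frame_interval_ns,
                              n_states = max(model$active_set))
    for (si in seq_along(sets)) {
      loc <- match(intersect(sets[[si]], model$active_set), model$active_set)
      if (!length(loc)) next
      w <- model$stationary[loc]
      w <- w / sum(w)
      pred <- sum(w * rowSums(Tk[loc, loc, drop = FALSE]))
      loc_e <- match(intersect(sets[[si]], est_model$active_set),
                     est_model$active_set)
      if (length(loc_e)) {
        we <- est_model$stationary[loc_e]
        we <- we / sum(we)
        est <- sum(we * rowSums(
          est_model$transition_matrix[loc_e, loc_e, drop = FALSE]))
        n_from <- sum(est_model$counts[loc_e, , drop = FALSE])
      } else {
        est <- NA_real_
        n_from <- 0
      }
      se <- if (n_from > 0) sqrt(max(est * (1 - est), 0) / n_from) else NA_real_
      rows[[length(rows) + 1]] <- data.frame(
        set = si, factor = k, lag_ns = k * model$lag_ns,
        predicted = pred, estimated = est, se = se)
    }
  }
  res <- do.call(rbind, rows)
  class(res) <- c("ck_result", class(res))
  res
}

# normalize macrostate specification to a list of original-index vectors
macro_sets <- function(macrosets, model) {
  if (inherits(macrosets, "macrostate_model")) {
    lapply(seq_len(macrosets$n_macrostates), function(I) {
      model$active_set[macrosets$assignment == I]
    })
  } else {
    macrosets
  }
}

#' Macrostate free energies from stationary probabilities
#'
#' \deqn{\Delta G(S_i) = -k_B T \ln \sum_{j \in S_i} \pi_j}
#' with \eqn{k_B T} expressed in kJ/mol. Also reported relative to the
#' minimum-free-energy macrostate (column \code{ddG}), where the
#' normalization of \eqn{\pi} cancels.
#'
#' @param pi Stationary distribution over microstates (normalized).
#' @param assignment Integer macrostate index per microstate, or a
#'   \code{macrostate_model}.
#' @param temperature_K Temperature in kelvin (default 310).
#' @return Data frame: macrostate, weight (sum of pi), dG (kJ/mol), ddG.
#' @export
macrostate_free_energies <- function(pi, assignment, temperature_K = 310) {
  if (inherits(assignment, "macrostate_model")) {
    assignment <- assignment$assignment
  }
  if (length(assignment) != length(pi)) {
    stop("'assignment' must map every microstate", call. = FALSE)
  }
  kT <- GAS_CONSTANT_KJ * temperature_K
  n_macro <- max(assignment)
  w <- vapply(seq_len(n_macro), function(I) sum(pi[assignment == I]), 0)
  if (any(w == 0)) {
    warning("empty macrostate(s): free energy infinite", call. = FALSE)
  }
  dG <- -kT * log(w)
  data.frame(macrostate = seq_len(n_macro), weight = w, dG = dG,
             ddG = dG - min(dG))
}
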