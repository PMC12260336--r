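#' PCCA++ metastable coarse-graining
#'
#' Groups the microstates of a reversible MSM into \code{n_macrostates}
#' metastable sets by Perron-cluster cluster analysis. The dominant right
#' eigenvectors span a simplex whose vertices correspond to the metastable
#' sets; the inner-simplex algorithm locates the vertex microstates by
#' successive Gram-Schmidt orthogonalization, and the membership matrix is
#' the linear transform mapping each microstate's spectral coordinates onto
#' the vertex basis. Slightly negative memberships from the linear solve are
#' clipped to zero and rows renormalized. Crisp macrostates are the row-wise
#' argmax. Macrostates are numbered by descending stationary weight.
#'
#' @param model An \code{msm_model} (reversible).
#' @param n_macrostates Number of metastable sets (>= 2, at most the number
#'   of retained positive eigenvalues).
#' @return Object of class \code{macrostate_model}: fuzzy memberships
#'   \code{chi} (n_micro x n_macro), crisp \code{assignment}, per-macrostate
#'   stationary \code{weights}.
#' @export
pcca_plus <- function(model, n_macrostates) {
  stopifnot(inherits(model, "msm_model"))
  m <- as.integer(n_macrostates)
  n <- model$n_micro
  if (m < 1 || m > n) stop("'n_macrostates' must be in [1, n_micro]",
                           call. = FALSE)
  lam <- model$eigenvalues
  if (m > 1 && lam[m] <= 0) {
    warning(sprintf(
      "requested %d macrostates but eigenvalue %d is %.3g <= 0; spectral support is weak (eigenvalues: %s)",
      m, m, lam[m], paste(sprintf("%.3f", lam[seq_len(min(m, n))]),
                          collapse = ", ")), call. = FALSE)
  }
  if (m > 1 && any(abs(diff(lam[seq_len(m)])) < 1e-12)) {
    message("PCCA++: degenerate eigenvalues; ties broken by index order")
  }
  X <- model$right_eigenvectors[, seq_len(m), drop = FALSE]
  # normalize the trivial eigenvector to exactly 1
  X[, 1] <- 1
  if (m == 1) {
    chi <- matrix(1, n, 1)
  } else {
    idx <- inner_simplex_vertices(X)
    A <- solve(X[idx, , drop = FALSE])
    chi <- X %*% A
    chi[chi < 0] <- 0
    chi <- chi / rowSums(chi)
  }
  assignment <- max.col(chi, ties.method = "first")
  w <- vapply(seq_len(m), function(I) sum(model$stationary[assignment == I]), 0)
  # renumber by descending stationary weight
  ord <- order(w, decreasing = TRUE)
  relabel <- integer(m)
  relabel[ord] <- seq_len(m)
  chi <- chi[, ord, drop = FALSE]
  assignment <- relabel[assignment]
  w <- w[ord]
  structure(list(chi = chi, assignment = assignment, weights = w,
                 n_macrostates = m, active_set = model$active_set),
            class = "macrostate_model")
}

# inner-simplex vertex search: pick the row farthest from the origin, shift
# it to the origin, then repeatedly orthogonalize against the last vertex
# direction and pick the row with the largest residual norm
inner_simplex_vertices <- function(X) {
  m <- ncol(X)
  ortho <- X
  idx <- integer(m)
  idx[1] <- which.max(rowSums(ortho^2))
  ortho <- sweep(ortho, 2, ortho[idx[1], ])
  for (j in seq_len(m)[-1]) {
    v <- ortho[idx[j - 1], ]
    nv <- sqrt(sum(v^2))
    if (nv > 0) {
      v <- v / nv
      ortho <- ortho - (ortho %*% v) %*% t(v)
    }
    idx[j] <- which.max(rowSums(ortho^2))
  }
  idx
}

#' @export
print.macrostate_model <- function(x, ...) {
  cat(sprintf("macrostate_model: %d macrostates over %d microstates\n",
              x$n_macrostates, nrow(x$chi)))
  cat("  stationary weights:", sprintf("%.4f", x$weights), "\n")
  invisible(x)
}

# microstate mean first passage times (ns) to a target set of local
# (active-set) indices: solve (I - T restricted) m = tau * 1 off the target,
# m = 0 on it
micro_mfpt_to <- function(model, target_loc) {
  n <- model$n_micro
  m <- numeric(n)
  rest <- setdiff(seq_len(n), target_loc)
  if (!length(rest)) return(m)
  Trr <- model$transition_matrix[rest, rest, drop = FALSE]
  rhs <- rep(model$lag_ns, length(rest))
  sol <- tryCatch(solve(diag(length(rest)) - Trr, rhs), error = function(e) NULL)
  if (is.null(sol) || any(!is.finite(sol)) || any(sol < -1e-6)) {
    return(replace(m, rest, Inf))
  }
  m[rest] <- pmax(sol, 0)
  m
}

#' Mean first passage time between two macrostates
#'
#' Microstate MFPTs to the target set solve the linear system
#' \eqn{(I - \tilde{T}) m = \tau \mathbf{1}} with the target rows absorbing
#' (m = 0 there); the macrostate-level MFPT is the stationary-weighted
#' average of the microstate MFPTs over the source's crisp set:
#' \deqn{\mathrm{MFPT}(S \to T) = \sum_{i \in S} \pi_i m_i / \sum_{i \in S} \pi_i.}
#'
#' @param model An \code{msm_model}.
#' @param macro A \code{macrostate_model} for the same model.
#' @param source,target Macrostate indices (source != target).
#' @return MFPT in ns (Inf, with a warning, if the target is unreachable).
#' @export
mfpt <- function(model, macro, source, target) {
  stopifnot(inherits(model, "msm_model"), inherits(macro, "macrostate_model"))
  if (source == target) return(0)
  src <- which(macro$assignment == source)
  tgt <- which(macro$assignment == target)
  if (!length(src) || !length(tgt)) {
    stop("source and target macrostates must be non-empty", call. = FALSE)
  }
  mvec <- micro_mfpt_to(model, tgt)
  if (any(!is.finite(mvec[src]))) {
    warning("target macrostate unreachable from source; MFPT infinite",
            call. = FALSE)
    return(Inf)
  }
  w <- model$stationary[src]
  sum(w * mvec[src]) / sum(w)
}

#' Full macrostate MFPT matrix
#'
#' @inheritParams mfpt
#' @return n_macro x n_macro matrix of MFPTs in ns, zero diagonal.
#' @export
mfpt_matrix <- function(model, macro) {
  m <- macro$n_macrostates
  out <- matrix(0, m, m)
  for (tgt in seq_len(m)) {
    mvec <- micro_mfpt_to(model, which(macro$assignment == tgt))
    for (src in seq_len(m)) {
      if (src == tgt) next
      sel <- which(macro$assignment == src)
      w <- model$stationary[sel]
      out[src, tgt] <- sum(w * mvec[sel]) / sum(w)
    }
  }
  dimnames(out) <- list(source = paste0("S", seq_len(m)),
                        target = paste0("S", seq_len(m)))
  out
}

#' Fold asymmetry between forward and reverse passage times
#'
#' Ratio of the slower to the faster direction between two macrostates, the
#' headline number for association/dissociation asymmetry (a ratio of 1
#' means equally fast binding and unbinding).
#'
#' @param mfpts Either an MFPT matrix (from \code{\link{mfpt_matrix}}) or a
#'   numeric vector of the two directed MFPTs (ns).
#' @param a,b Macrostate indices when \code{mfpts} is a matrix.
#' @return The fold ratio (>= 1).
#' @export
mfpt_fold_asymmetry <- function(mfpts, a = NULL, b = NULL) {
  two <- if (is.matrix(mfpts)) {
    c(mfpts[a, b], mfpts[b, a])
  } else {
    stopifnot(length(mfpts) == 2)
    as.numeric(mfpts)
  }
  if (any(two <= 0)) stop("MFPTs must be positive", call. = FALSE)
  max(two) / min(two)
}

#' Committor probabilities and reactive flux between two microstate sets
#'
#' The forward committor \eqn{q^+_i} is the probability of reaching B before
#' A from microstate i; it is 0 on A, 1 on B and harmonic in between. For a
#' reversible chain the backward committor is \eqn{q^- = 1 - q^+}. The gross
#' reactive flux is \eqn{f_{ij} = \pi_i q^-_i T_{ij} q^+_j} (i != j), the
#' net flux its nonnegative antisymmetric part, and the total A to B
#' reaction rate \eqn{\sum_{i \in A, j \notin A} f^+_{ij} /
#' (\tau \sum_i \pi_i q^-_i)}.
#'
#' @param model An \code{msm_model}.
#' @param A,B Disjoint non-empty microstate index vectors (active-set local
#'   indices).
#' @return List of class \code{kinetics_result}: \code{qplus},
#'   \code{qminus}, \code{flux}, \code{net_flux}, \code{rate_per_ns},
#'   \code{total_flux}.
#' @export
committor_and_flux <- function(model, A, B) {
  stopifnot(inherits(model, "msm_model"))
  A <- as.integer(A); B <- as.integer(B)
  if (!length(A) || !length(B)) stop("A and B must be non-empty", call. = FALSE)
  if (anyNA(A) || anyNA(B) || any(c(A, B) < 1) || any(c(A, B) > model$n_micro)) {
    stop("A and B must be valid microstate indices", call. = FALSE)
  }
  if (length(intersect(A, B))) stop("A and B must be disjoint", call. = FALSE)
  n <- model$n_micro
  T_ <- model$transition_matrix
  C <- setdiff(seq_len(n), union(A, B))
  q <- numeric(n)
  q[B] <- 1
  if (length(C)) {
    Tcc <- T_[C, C, drop = FALSE]
    rhs <- rowSums(T_[C, B, drop = FALSE])
    q[C] <- solve(diag(length(C)) - Tcc, rhs)
    q[C] <- pmin(pmax(q[C], 0), 1)
  }
  qm <- 1 - q  # backward committor of a reversible chain
  pi_ <- model$stationary
  f <- outer(pi_ * qm, q) * T_
  diag(f) <- 0
  fnet <- pmax(f - t(f), 0)
  notA <- setdiff(seq_len(n), A)
  total <- sum(fnet[A, notA, drop = FALSE])
  denom <- model$lag_ns * sum(pi_ * qm)
  structure(list(qplus = q, qminus = qm, flux = f, net_flux = fnet,
                 total_flux = total,
                 rate_per_ns = if (denom > 0) total / denom else NA_real_,
                 A = A, B = B, lag_ns = model$lag_ns),
            class = "kinetics_result")
}

#' Coarse transition network between macrostates
#'
#' Stationary-weighted aggregation of the microstate transition matrix over
#' the crisp macrostate sets:
#' \deqn{P_{IJ} = \sum_{i \in I, j \in J} \pi_i T_{ij} / \sum_{i \in I} \pi_i.}
#' Rows sum to one. Returned both as a matrix and as an edge-list table for
#' plotting a network whose node sizes are the stationary weights and edge
#' widths the transition probabilities.
#'
#' @inheritParams mfpt
#' @return List with \code{P} (n_macro x n_macro), \code{weights}, and
#'   \code{edges} (data frame from, to, probability, from_weight).
#' @export
coarse_transition_network <- function(model, macro) {
  stopifnot(inherits(model, "msm_model"), inherits(macro, "macrostate_model"))
  m <- macro$n_macrostates
  P <- matrix(0, m, m)
  pi_ <- model$stationary
  T_ <- model$transition_matrix
  for (I in seq_len(m)) {
    si <- which(macro$assignment == I)
    wi <- sum(pi_[si])
    for (J in seq_len(m)) {
      sj <- which(macro$assignment == J)
      P[I, J] <- sum(pi_[si] * rowSums(T_[si, sj, drop = FALSE])) / wi
    }
  }
  edges <- data.frame(
    from = rep(seq_len(m), each = m), to = rep(seq_len(m), m),
    probability = as.vector(t(P)),
    from_weight = rep(macro$weights, each = m))
  list(P = P, weights = macro$weights, edges = edges)
}

#' Exact macrostate MFPTs of a ground-truth chain
#'
#' Computes the macrostate-to-macrostate MFPT directly from a known
#' transition matrix (stationary-weighted over the source set), providing
#' the analytic reference for pipeline recovery tests.
#'
#' @param chain A \code{ground_truth_chain} (or a row-stochastic matrix).
#' @param source,target State index vectors defining the two groups.
#' @param lag_step_ns Time per step when a bare matrix is given.
#' @return MFPT in ns.
#' @export
true_mfpt <- function(chain, source, target, lag_step_ns = NULL) {
  if (inherits(chain, "ground_truth_chain")) {
    P <- chain$transition_matrix
    tau <- chain$lag_step_ns
  } else {
    P <- as.matrix(chain)
    tau <- lag_step_ns %||% 1
  }
  n <- nrow(P)
  pi_ <- stationary_distribution(P)
  rest <- setdiff(seq_len(n), target)
  mvec <- numeric(n)
  mvec[rest] <- solve(diag(length(rest)) - P[rest, rest, drop = FALSE],
                      rep(tau, length(rest)))
  w <- pi_[source]
  sum(w * mvec[source]) / sum(w)
}
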