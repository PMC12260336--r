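#' Stationary distribution of a row-stochastic matrix
#'
#' Computes the left Perron eigenvector of a transition matrix, normalized to
#' sum to one. For an irreducible chain this is the unique equilibrium
#' distribution.
#'
#' @param P Square row-stochastic matrix.
#' @param tol Tolerance used to verify that rows sum to one.
#' @return Numeric vector of stationary probabilities.
#' @export
stationary_distribution <- function(P, tol = 1e-8) {
  check_stochastic(P, tol = tol)
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  if (sum(v) < 0) v <- -v
  v[v < 0] <- 0
  v / sum(v)
}

# validate a row-stochastic matrix; stops with a descriptive error
check_stochastic <- function(P, tol = 1e-12, arg = "transition_matrix") {
  if (!is.matrix(P) || nrow(P) != ncol(P)) {
    stop(sprintf("'%s' must be a square matrix", arg), call. = FALSE)
  }
  if (any(!is.finite(P)) || any(P < 0)) {
    stop(sprintf("'%s' must have finite, nonnegative entries", arg),
         call. = FALSE)
  }
  rs <- rowSums(P)
  if (any(abs(rs - 1) > max(tol, 1e-12))) {
    stop(sprintf("rows of '%s' must sum to 1 (max deviation %.3g)",
                 arg, max(abs(rs - 1))), call. = FALSE)
  }
  invisible(P)
}

# nm <-> Angstrom; PDB files carry Angstrom, the package works in nm
NM_PER_ANGSTROM <- 0.1

# gas constant in kJ/(mol K); k_B * T in kJ/mol is R * T / 1000 with R in J
GAS_CONSTANT_KJ <- 8.314462618e-3

`%||%` <- function(a, b) if (is.null(a)) b else a

# k-th power of a square matrix by repeated squaring
matrix_power <- function(M, k) {
  stopifnot(k >= 1)
  out <- NULL
  base <- M
  while (k > 0) {
    if (k %% 2 == 1) out <- if (is.null(out)) base else out %*% base
    base <- base %*% base
    k <- k %/% 2
  }
  out
}

# convert a lag in ns to frames, rounding to the nearest frame with a
# warning when the lag is not an integer multiple of the frame interval
lag_to_frames <- function(lag_ns, frame_interval_ns) {
  lf <- lag_ns / frame_interval_ns
  lfr <- max(1L, as.integer(round(lf)))
  if (abs(lf - round(lf)) > 1e-9) {
    warning(sprintf(
      "lag %.4g ns is not a multiple of the frame interval %.4g ns; using %d frames (%.4g ns)",
      lag_ns, frame_interval_ns, lfr, lfr * frame_interval_ns), call. = FALSE)
  }
  lfr
}
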