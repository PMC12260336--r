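#' Fit time-lagged independent component analysis
#'
#' Estimates the slow linear collective modes of a feature time series by
#' solving the generalized eigenproblem \eqn{\bar{C}_\tau v = \lambda C_0 v},
#' where \eqn{C_0} is the instantaneous covariance and \eqn{\bar{C}_\tau} the
#' symmetrized time-lagged covariance, both pooled over replicas and never
#' across replica boundaries. The symmetrized (reversible) estimator
#' guarantees real eigenvalues. Components are kept until the cumulative
#' kinetic variance, defined through squared eigenvalues as
#' \eqn{\lambda_i^2 / \sum_j \lambda_j^2}, reaches \code{variance_cutoff}.
#'
#' \eqn{C_0} is regularized by discarding directions whose \eqn{C_0}
#' eigenvalue is below 1e-10 times the largest, so degenerate (constant or
#' collinear) features cannot break the solve.
#'
#' @param features A \code{feature_set} (list of T x d matrices with a frame
#'   interval attribute) or a plain list of matrices plus
#'   \code{frame_interval_ns}.
#' @param lag_ns TICA lag time in ns; rounded to the nearest whole frame
#'   with a warning if not a multiple of the frame interval.
#' @param variance_cutoff Fraction of kinetic variance to preserve, in
#'   (0, 1].
#' @param frame_interval_ns Frame interval override when \code{features}
#'   carries none.
#' @return Object of class \code{tica_model} with the mean vector, C0,
#'   symmetrized Ctau, sorted eigenvalues, eigenvectors (columns),
#'   cumulative kinetic variance fractions and the number of components
#'   kept.
#' @export
fit_tica <- function(features, lag_ns, variance_cutoff = 0.95,
                     frame_interval_ns = NULL) {
  fi <- frame_interval_ns %||% attr(features, "frame_interval_ns")
  if (is.null(fi)) stop("frame interval unknown; pass 'frame_interval_ns'",
                        call. = FALSE)
  if (variance_cutoff <= 0 || variance_cutoff > 1) {
    stop("'variance_cutoff' must be in (0, 1]", call. = FALSE)
  }
  lagf <- lag_to_frames(lag_ns, fi)
  mats <- lapply(features, function(x) as.matrix(x))
  d <- ncol(mats[[1]])
  short <- vapply(mats, nrow, 1L) <= lagf
  if (all(short)) stop("every replica is shorter than the lag", call. = FALSE)
  if (any(short)) {
    warning(sprintf("%d replica(s) shorter than the lag were skipped",
                    sum(short)), call. = FALSE)
    mats <- mats[!short]
  }
  # pooled mean over both the instantaneous and lagged windows
  n_pairs <- 0
  sums <- numeric(d)
  for (x in mats) {
    T_ <- nrow(x)
    idx0 <- seq_len(T_ - lagf)
    sums <- sums + colSums(x[idx0, , drop = FALSE]) +
      colSums(x[idx0 + lagf, , drop = FALSE])
    n_pairs <- n_pairs + length(idx0)
  }
  mu <- sums / (2 * n_pairs)
  C0 <- matrix(0, d, d)
  Ct <- matrix(0, d, d)
  for (x in mats) {
    T_ <- nrow(x)
    idx0 <- seq_len(T_ - lagf)
    x0 <- sweep(x[idx0, , drop = FALSE], 2, mu)
    xt <- sweep(x[idx0 + lagf, , drop = FALSE], 2, mu)
    C0 <- C0 + crossprod(x0) + crossprod(xt)
    Ct <- Ct + crossprod(x0, xt) + crossprod(xt, x0)
  }
  C0 <- C0 / (2 * n_pairs)
  Ct <- Ct / (2 * n_pairs)
  Ct <- (Ct + t(Ct)) / 2
  # whiten C0 with an eigenvalue floor
  e0 <- eigen(C0, symmetric = TRUE)
  keep <- e0$values > 1e-10 * max(e0$values)
  if (!all(keep)) {
    message(sprintf("TICA: discarding %d degenerate feature direction(s)",
                    sum(!keep)))
  }
  W <- e0$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(e0$values[keep]), sum(keep))
  M <- crossprod(W, Ct %*% W)
  M <- (M + t(M)) / 2
  em <- eigen(M, symmetric = TRUE)
  ord <- order(em$values, decreasing = TRUE)
  lam <- em$values[ord]
  V <- W %*% em$vectors[, ord, drop = FALSE]
  kv <- lam^2 / sum(lam^2)
  cumkv <- cumsum(kv)
  n_keep <- which(cumkv >= variance_cutoff - 1e-12)[1]
  structure(list(mean = mu, C0 = C0, Ctau = Ct, eigenvalues = lam,
                 eigenvectors = V, lag_frames = lagf, lag_ns = lagf * fi,
                 frame_interval_ns = fi,
                 kinetic_variance_fractions = cumkv,
                 n_components_kept = n_keep,
                 variance_cutoff = variance_cutoff),
            class = "tica_model")
}

#' @export
print.tica_model <- function(x, ...) {
  cat(sprintf("tica_model: lag %.3g ns (%d frames), %d/%d components kept (cumulative kinetic variance %.3f)\n",
              x$lag_ns, x$lag_frames, x$n_components_kept,
              length(x$eigenvalues),
              x$kinetic_variance_fractions[x$n_components_kept]))
  cat("  eigenvalues:", sprintf("%.4f", x$eigenvalues), "\n")
  invisible(x)
}

#' Project features onto the kept TICA components
#'
#' Mean-centres each frame and maps it through the kept eigenvectors,
#' preserving the replica structure and frame interval.
#'
#' @param model A \code{tica_model}.
#' @param features A feature set with the same feature dimension the model
#'   was fitted on.
#' @param n_components Number of components to project on (default: the
#'   model's kept components).
#' @return List of T x m projection matrices, class \code{feature_set}.
#' @export
project_tica <- function(model, features, n_components = NULL) {
  stopifnot(inherits(model, "tica_model"))
  m <- n_components %||% model$n_components_kept
  V <- model$eigenvectors[, seq_len(m), drop = FALSE]
  out <- lapply(features, function(x) {
    x <- as.matrix(x)
    if (ncol(x) != length(model$mean)) {
      stop(sprintf("feature dimension %d does not match the model (%d)",
                   ncol(x), length(model$mean)), call. = FALSE)
    }
    y <- sweep(x, 2, model$mean) %*% V
    colnames(y) <- paste0("IC", seq_len(m))
    y
  })
  new_feature_set(out, frame_interval_ns = attr(features, "frame_interval_ns") %||%
                    model$frame_interval_ns)
}

#' @rdname project_tica
#' @param object,newdata,... \code{predict} method arguments mapping to
#'   \code{model} and \code{features}.
#' @export
predict.tica_model <- function(object, newdata, ...) {
  project_tica(object, newdata, ...)
}
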