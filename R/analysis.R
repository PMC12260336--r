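#' Detect binding and unbinding events with hysteresis thresholds
#'
#' Two-threshold state machine on a monomer-monomer COM distance series:
#' the system enters the bound (dimeric) state when the distance drops below
#' \code{bound_thr} and the unbound (monomeric) state when it rises above
#' \code{unbound_thr}; frames inside the band keep the previous state, which
#' suppresses threshold chatter. Frames before the first crossing are
#' labelled "intermediate". Defaults follow the dimeric (< 6 nm) and
#' monomeric (> 7 nm) distance conventions.
#'
#' @param distance Numeric vector (one replica) or list of vectors, nm.
#' @param bound_thr Bound (dimeric) threshold, nm.
#' @param unbound_thr Unbound (monomeric) threshold, nm; must exceed
#'   \code{bound_thr}.
#' @param frame_interval_ns Frame interval (ns); taken from the input's
#'   attribute when present.
#' @return Object of class \code{event_series}: per-replica segment tables
#'   (state, start_ns, end_ns) and total binding/unbinding counts.
#' @export
detect_association_events <- function(distance, bound_thr = 6, unbound_thr = 7,
                                      frame_interval_ns = NULL) {
  if (unbound_thr <= bound_thr) {
    stop("'unbound_thr' must exceed 'bound_thr' (hysteresis band)",
         call. = FALSE)
  }
  fi <- frame_interval_ns %||% attr(distance, "frame_interval_ns") %||% 1
  series <- if (is.list(distance)) distance else list(distance)
  segments <- vector("list", length(series))
  n_bind <- 0L
  n_unbind <- 0L
  for (r in seq_along(series)) {
    d <- as.numeric(series[[r]])
    state <- ifelse(d < bound_thr, "bound",
                    ifelse(d > unbound_thr, "unbound", NA))
    # in-band frames inherit the previous state; leading ones stay
    # "intermediate" until the first crossing
    for (t in seq_along(state)) {
      if (is.na(state[t])) {
        state[t] <- if (t == 1L) "intermediate" else state[t - 1L]
      }
    }
    runs <- rle(state)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    segments[[r]] <- data.frame(
      replica = r, state = runs$values,
      start_ns = (starts - 1L) * fi, end_ns = ends * fi,
      dwell_ns = runs$lengths * fi)
    sv <- runs$values[runs$values != "intermediate"]
    if (length(sv) > 1) {
      n_bind <- n_bind + sum(sv[-1] == "bound" & sv[-length(sv)] == "unbound")
      n_unbind <- n_unbind + sum(sv[-1] == "unbound" & sv[-length(sv)] == "bound")
    }
  }
  structure(list(segments = do.call(rbind, segments),
                 n_binding = n_bind, n_unbinding = n_unbind,
                 bound_thr = bound_thr, unbound_thr = unbound_thr,
                 frame_interval_ns = fi),
            class = "event_series")
}

#' @export
print.event_series <- function(x, ...) {
  cat(sprintf("event_series: %d binding, %d unbinding event(s) (thresholds %.3g/%.3g nm)\n",
              x$n_binding, x$n_unbinding, x$bound_thr, x$unbound_thr))
  invisible(x)
}

#' Distance population histogram and bound/unbound fractions
#'
#' Pools all frames and reports the normalized distance histogram together
#' with the fraction of dimeric conformations P(d < bound_thr), monomeric
#' conformations P(d > unbound_thr), and the in-band remainder; the three
#' sum to one.
#'
#' @param distance Numeric vector or list of vectors (nm), pooled.
#' @param bound_thr,unbound_thr Thresholds in nm.
#' @param bin_width Histogram bin width, nm (> 0).
#' @return List: histogram data frame (mid, density, fraction),
#'   bound_fraction, unbound_fraction, intermediate_fraction, n_frames.
#' @export
population_fractions <- function(distance, bound_thr = 6, unbound_thr = 7,
                                 bin_width = 0.1) {
  if (bin_width <= 0) stop("'bin_width' must be positive", call. = FALSE)
  d <- unlist(distance, use.names = FALSE)
  if (!length(d)) stop("empty distance series", call. = FALSE)
  breaks <- seq(0, max(d) + bin_width, by = bin_width)
  h <- graphics::hist(d, breaks = breaks, plot = FALSE)
  hist_df <- data.frame(mid = h$mids, density = h$density,
                        fraction = h$counts / length(d))
  bound <- mean(d < bound_thr)
  unbound <- mean(d > unbound_thr)
  list(histogram = hist_df, bound_fraction = bound,
       unbound_fraction = unbound,
       intermediate_fraction = 1 - bound - unbound,
       n_frames = length(d))
}

#' Inter-chain residue contact map over a trajectory
#'
#' A residue pair (a in chain A, b in chain B) is in contact in a frame when
#' the minimum distance between any of their atoms/beads is below
#' \code{cutoff}; the contact fraction is the fraction of frames in contact.
#' Pairs exceeding \code{fraction_threshold} form the filtered persistent
#' contact list. Defaults: 0.45 nm cutoff, 0.75 fraction.
#'
#' @param ensemble A \code{trajectory_ensemble} whose topology has a
#'   \code{residue} column (falls back to one residue per bead).
#' @param cutoff Contact distance cutoff, nm.
#' @param fraction_threshold Persistence filter on the contact fraction.
#' @return Object of class \code{contact_map}: \code{fraction} matrix
#'   (chain A residues x chain B residues) and \code{persistent} pair table.
#' @export
interchain_contact_map <- function(ensemble, cutoff = 0.45,
                                   fraction_threshold = 0.75) {
  stopifnot(inherits(ensemble, "trajectory_ensemble"))
  topo <- ensemble$topology
  if (is.null(topo$residue)) topo$residue <- topo$bead
  selA <- which(topo$chain == "A")
  selB <- which(topo$chain == "B")
  if (!length(selB)) stop("no chain B in the topology", call. = FALSE)
  resA <- sort(unique(topo$residue[selA]))
  resB <- sort(unique(topo$residue[selB]))
  grpA <- lapply(resA, function(rr) selA[topo$residue[selA] == rr])
  grpB <- lapply(resB, function(rr) selB[topo$residue[selB] == rr])
  n_contact <- matrix(0, length(resA), length(resB),
                      dimnames = list(A = resA, B = resB))
  n_frames <- 0L
  for (coords in ensemble$replicas) {
    T_ <- dim(coords)[1]
    n_frames <- n_frames + T_
    for (t in seq_len(T_)) {
      fr <- coords[t, , , drop = TRUE]
      if (is.null(dim(fr))) fr <- matrix(fr, ncol = 3)
      dAB <- as.matrix(stats::dist(rbind(fr[selA, , drop = FALSE],
                                         fr[selB, , drop = FALSE])))
      dAB <- dAB[seq_along(selA), length(selA) + seq_along(selB),
                 drop = FALSE]
      for (ia in seq_along(grpA)) {
        ra <- match(grpA[[ia]], selA)
        for (ib in seq_along(grpB)) {
          rb <- match(grpB[[ib]], selB)
          if (min(dAB[ra, rb]) < cutoff) {
            n_contact[ia, ib] <- n_contact[ia, ib] + 1
          }
        }
      }
    }
  }
  frac <- n_contact / n_frames
  keep <- which(frac > fraction_threshold, arr.ind = TRUE)
  persistent <- data.frame(
    residue_A = resA[keep[, 1]], residue_B = resB[keep[, 2]],
    fraction = frac[keep])
  persistent <- persistent[order(-persistent$fraction), , drop = FALSE]
  rownames(persistent) <- NULL
  structure(list(fraction = frac, persistent = persistent, cutoff = cutoff,
                 fraction_threshold = fraction_threshold,
                 n_frames = n_frames),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("contact_map: %d x %d residue grid over %d frame(s); %d pair(s) above fraction %.2f (cutoff %.3g nm)\n",
              nrow(x$fraction), ncol(x$fraction), x$n_frames,
              nrow(x$persistent), x$fraction_threshold, x$cutoff))
  invisible(x)
}

#' Optimal superposition rotation (Kabsch algorithm)
#'
#' Returns the proper rotation minimizing the RMSD of \code{P} onto
#' \code{Q} after centring, with the determinant sign corrected so that
#' reflections are never returned.
#'
#' @param P,Q n x 3 coordinate matrices.
#' @return List: rotation \code{R} (applied to centred P), centroids, and
#'   the resulting rmsd.
#' @export
kabsch_fit <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (!all(dim(P) == dim(Q))) stop("coordinate sets differ in size",
                                   call. = FALSE)
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp); Q0 <- sweep(Q, 2, cq)
  H <- crossprod(P0, Q0)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  Pr <- P0 %*% t(R)
  list(R = R, centroid_P = cp, centroid_Q = cq,
       rmsd = sqrt(mean(rowSums((Pr - Q0)^2))))
}

#' Per-frame RMSD after optimal superposition
#'
#' Superposes each frame onto the reference with the Kabsch algorithm
#' (proper rotations only) and reports the root-mean-square deviation over
#' the selected beads, in nm.
#'
#' @param reference B x 3 reference coordinates (nm), or a 1-frame slice.
#' @param ensemble A \code{trajectory_ensemble}.
#' @param selection Integer or logical bead selection, or NULL for all
#'   beads.
#' @return List of per-replica numeric RMSD vectors (nm).
#' @export
kabsch_rmsd <- function(reference, ensemble, selection = NULL) {
  stopifnot(inherits(ensemble, "trajectory_ensemble"))
  B <- nrow(ensemble$topology)
  sel <- if (is.null(selection)) seq_len(B) else which(
    if (is.logical(selection)) selection else seq_len(B) %in% selection)
  if (!length(sel)) stop("empty selection", call. = FALSE)
  ref <- as.matrix(reference)
  if (nrow(ref) == B) ref <- ref[sel, , drop = FALSE]
  if (nrow(ref) != length(sel)) {
    stop(sprintf("reference has %d beads but the selection has %d",
                 nrow(ref), length(sel)), call. = FALSE)
  }
  lapply(ensemble$replicas, function(coords) {
    vapply(seq_len(dim(coords)[1]), function(t) {
      fr <- matrix(coords[t, sel, ], ncol = 3)
      kabsch_fit(fr, ref)$rmsd
    }, 0)
  })
}

#' Replica-plan bookkeeping
#'
#' Summarizes a simulation protocol: replica count, per-replica length and
#' aggregate production time.
#'
#' @param n_replicas Number of replicas, or a \code{trajectory_ensemble}
#'   (in which case the remaining arguments are ignored).
#' @param replica_length_ns Length of each replica in ns.
#' @return List: n_replicas, replica_length_ns, aggregate_ns, aggregate_us.
#' @export
protocol_summary <- function(n_replicas, replica_length_ns = NULL) {
  if (inherits(n_replicas, "trajectory_ensemble")) {
    ens <- n_replicas
    lens <- vapply(ens$replicas, function(a) dim(a)[1], 1L) *
      ens$frame_interval_ns
    n_replicas <- length(ens$replicas)
    replica_length_ns <- if (length(unique(lens)) == 1) lens[1] else lens
  }
  agg <- sum(rep_len(replica_length_ns, n_replicas))
  list(n_replicas = n_replicas, replica_length_ns = replica_length_ns,
       aggregate_ns = agg, aggregate_us = agg / 1000)
}
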