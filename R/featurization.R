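feature_names <- function() {
  c("A.Ntd-B.Ntd", "A.Ntd-B.Ctd", "A.Ctd-B.Ntd", "A.Ctd-B.Ctd")
}

new_feature_set <- function(feats, frame_interval_ns) {
  structure(feats, class = "feature_set", frame_interval_ns = frame_interval_ns)
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("feature_set: %d replica(s), %s frames, %d feature(s), frame interval %.3g ns\n",
              length(x), paste(vapply(x, nrow, 1L), collapse = "/"),
              ncol(x[[1]]), attr(x, "frame_interval_ns")))
  invisible(x)
}

#' Multi-replica coordinate trajectory ensemble
#'
#' Container for replica coordinate time series of a two-chain system
#' together with the per-bead topology annotation. Coordinates are in nm and
#' frames are \code{frame_interval_ns} ns apart. All replicas share one
#' topology; both chains A and B must be present with N-terminal (Ntd) and
#' C-terminal (Ctd) domains annotated. Beads annotated "arm" (the terminal
#' extensions) are kept in the coordinates but excluded from domain COMs by
#' default.
#'
#' @param replicas List of T x B x 3 coordinate arrays (nm), one per replica.
#' @param topology Data frame with columns \code{bead}, \code{chain} (A/B),
#'   \code{domain} (Ntd/Ctd/arm), \code{mass}; an optional \code{residue}
#'   column enables residue-level contact maps.
#' @param frame_interval_ns Time between frames, ns (> 0).
#' @return Object of class \code{trajectory_ensemble}.
#' @export
trajectory_ensemble <- function(replicas, topology, frame_interval_ns) {
  if (!is.list(replicas) || !length(replicas)) {
    stop("'replicas' must be a non-empty list of T x B x 3 arrays",
         call. = FALSE)
  }
  if (frame_interval_ns <= 0) {
    stop("'frame_interval_ns' must be positive", call. = FALSE)
  }
  topology <- as.data.frame(topology)
  need <- c("bead", "chain", "domain")
  if (!all(need %in% names(topology))) {
    stop("topology must have columns bead, chain, domain", call. = FALSE)
  }
  if (is.null(topology$mass)) topology$mass <- 1
  if (any(!is.finite(topology$mass)) || any(topology$mass <= 0)) {
    stop("bead masses must be positive and finite", call. = FALSE)
  }
  B <- nrow(topology)
  for (r in seq_along(replicas)) {
    a <- replicas[[r]]
    if (length(dim(a)) != 3 || dim(a)[3] != 3) {
      stop(sprintf("replica %d is not a T x B x 3 array", r), call. = FALSE)
    }
    if (dim(a)[2] != B) {
      stop(sprintf("replica %d has %d beads but the topology annotates %d",
                   r, dim(a)[2], B), call. = FALSE)
    }
    if (any(!is.finite(a))) {
      stop(sprintf("replica %d contains non-finite coordinates", r),
           call. = FALSE)
    }
  }
  for (ch in c("A", "B")) {
    if (!any(topology$chain == ch)) {
      stop(sprintf("chain %s is missing from the topology", ch), call. = FALSE)
    }
    for (dom in c("Ntd", "Ctd")) {
      sel <- topology$chain == ch & topology$domain == dom
      if (!any(sel)) {
        stop(sprintf("chain %s has no beads annotated '%s'", ch, dom),
             call. = FALSE)
      }
      if (sum(topology$mass[sel]) <= 0) {
        stop(sprintf("domain %s.%s has zero total mass", ch, dom),
             call. = FALSE)
      }
    }
  }
  structure(list(replicas = replicas, topology = topology,
                 frame_interval_ns = frame_interval_ns),
            class = "trajectory_ensemble")
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  nf <- vapply(x$replicas, function(a) dim(a)[1], 1L)
  cat(sprintf("trajectory_ensemble: %d replica(s) x %s frames, %d beads, frame interval %.3g ns\n",
              length(x$replicas),
              if (length(unique(nf)) == 1) nf[1] else paste(nf, collapse = "/"),
              nrow(x$topology), x$frame_interval_ns))
  cat(sprintf("  aggregate time: %.4g ns\n", sum(nf) * x$frame_interval_ns))
  invisible(x)
}

#' Write a trajectory ensemble to plain-text files
#'
#' Writes one tab-separated coordinate file per replica (columns
#' \code{x<i> y<i> z<i>} per bead, one row per frame, nm, with the frame
#' interval in a comment header), a PDB topology (nm converted to Angstrom),
#' the 3-column domain annotation table, and a JSON manifest recording the
#' replica plan.
#'
#' @param ensemble A \code{trajectory_ensemble}.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Invisibly, the list of written paths.
#' @export
write_trajectory_ensemble <- function(ensemble, dir, prefix = "traj") {
  stopifnot(inherits(ensemble, "trajectory_ensemble"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  topo <- ensemble$topology
  B <- nrow(topo)
  traj_paths <- character(length(ensemble$replicas))
  for (r in seq_along(ensemble$replicas)) {
    a <- ensemble$replicas[[r]]
    flat <- matrix(aperm(a, c(1, 3, 2)), nrow = dim(a)[1])  # x1 y1 z1 x2 ...
    # 17 significant digits so coordinates round-trip bit-exactly
    flat <- matrix(sprintf("%.17g", flat), nrow = nrow(flat))
    colnames(flat) <- paste0(rep(c("x", "y", "z"), B),
                             rep(seq_len(B), each = 3))
    path <- file.path(dir, sprintf("%s_rep%02d.coords.tsv", prefix, r))
    con <- file(path, "w")
    writeLines(sprintf("# frame_interval_ns: %.10g", ensemble$frame_interval_ns), con)
    writeLines(sprintf("# n_beads: %d", B), con)
    close(con)
    data.table::fwrite(data.table::as.data.table(flat), path, sep = "\t",
                       append = TRUE, col.names = TRUE)
    traj_paths[r] <- path
  }
  ann_path <- file.path(dir, paste0(prefix, "_domains.tsv"))
  utils::write.table(topo[, c("bead", "chain", "domain", "mass")], ann_path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  pdb_path <- file.path(dir, paste0(prefix, "_topology.pdb"))
  xyz_A <- as.vector(t(ensemble$replicas[[1]][1, , ])) / NM_PER_ANGSTROM
  bio3d::write.pdb(file = pdb_path, xyz = xyz_A,
                   chain = topo$chain, resno = topo$bead,
                   resid = substr(toupper(topo$domain), 1, 3),
                   elety = rep("CA", B))
  manifest_path <- file.path(dir, paste0(prefix, "_manifest.json"))
  jsonlite::write_json(list(
    n_replicas = length(ensemble$replicas),
    frames_per_replica = vapply(ensemble$replicas, function(a) dim(a)[1], 1L),
    frame_interval_ns = ensemble$frame_interval_ns,
    n_beads = B,
    topology = pdb_path, annotation = ann_path, trajectories = traj_paths),
    manifest_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(list(topology = pdb_path, annotation = ann_path,
                 trajectories = traj_paths, manifest = manifest_path))
}

#' Load a trajectory ensemble from topology, coordinate files and annotation
#'
#' Reads a PDB topology (Angstrom, converted to nm), tab-separated coordinate
#' files as written by \code{\link{write_trajectory_ensemble}}, and a domain
#' annotation table (columns bead, chain, domain, optional mass). Beads not
#' covered by the annotation are assigned domain "arm" and therefore excluded
#' from domain COMs.
#'
#' @param topology_path PDB file.
#' @param trajectory_paths Character vector of coordinate files, one per
#'   replica.
#' @param domain_map Annotation data frame or path to the TSV table.
#' @return A \code{trajectory_ensemble}.
#' @export
load_trajectories <- function(topology_path, trajectory_paths, domain_map) {
  if (!file.exists(topology_path)) {
    stop(sprintf("topology file not found: %s", topology_path), call. = FALSE)
  }
  missing <- trajectory_paths[!file.exists(trajectory_paths)]
  if (length(missing)) {
    stop(sprintf("trajectory file(s) not found: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  pdb <- bio3d::read.pdb(topology_path)
  B <- nrow(pdb$atom)
  ann <- if (is.character(domain_map)) {
    utils::read.table(domain_map, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  } else {
    as.data.frame(domain_map)
  }
  if (!all(c("bead", "chain", "domain") %in% names(ann))) {
    stop("domain annotation needs columns bead, chain, domain", call. = FALSE)
  }
  topo <- data.frame(bead = seq_len(B),
                     chain = as.character(pdb$atom$chain),
                     domain = "arm", mass = 1, stringsAsFactors = FALSE)
  idx <- match(ann$bead, topo$bead)
  if (any(is.na(idx))) {
    stop("annotation refers to beads absent from the topology", call. = FALSE)
  }
  topo$chain[idx] <- as.character(ann$chain)
  topo$domain[idx] <- as.character(ann$domain)
  if (!is.null(ann$mass)) topo$mass[idx] <- ann$mass
  replicas <- vector("list", length(trajectory_paths))
  n_frames <- integer(length(trajectory_paths))
  fi <- NA_real_
  for (r in seq_along(trajectory_paths)) {
    hdr <- readLines(trajectory_paths[r], n = 2)
    fi_r <- as.numeric(sub("# frame_interval_ns:\\s*", "",
                           grep("frame_interval_ns", hdr, value = TRUE)))
    if (is.na(fi)) fi <- fi_r
    dt <- data.table::fread(trajectory_paths[r], sep = "\t", skip = 2,
                            header = TRUE)
    m <- as.matrix(dt)
    if (ncol(m) != 3L * B) {
      stop(sprintf("frame width mismatch in %s: %d columns for %d beads",
                   trajectory_paths[r], ncol(m), B), call. = FALSE)
    }
    a <- array(NA_real_, c(nrow(m), B, 3L))
    for (k in 1:3) a[, , k] <- m[, seq(k, 3L * B, by = 3L), drop = FALSE]
    replicas[[r]] <- a
    n_frames[r] <- nrow(m)
  }
  trajectory_ensemble(replicas, topo, frame_interval_ns = fi)
}

# per-frame mass-weighted COM of a bead selection: returns T x 3
selection_com <- function(coords, sel, masses, geometric = FALSE) {
  if (!length(sel)) stop("empty bead selection for COM", call. = FALSE)
  w <- if (geometric) rep(1, length(sel)) else masses[sel]
  w <- w / sum(w)
  out <- matrix(0, dim(coords)[1], 3)
  for (k in 1:3) {
    m <- coords[, sel, k, drop = FALSE]
    dim(m) <- dim(m)[1:2]
    out[, k] <- m %*% w
  }
  out
}

#' Inter-monomer domain centre-of-mass distances
#'
#' For every frame, computes the mass-weighted COM of each (chain, domain)
#' and the four Euclidean inter-monomer distances in the fixed column order
#' (A.Ntd-B.Ntd, A.Ntd-B.Ctd, A.Ctd-B.Ntd, A.Ctd-B.Ctd). These distances are
#' the features characterizing protein-protein association. Beads annotated
#' "arm" do not enter any domain COM.
#'
#' @param ensemble A \code{trajectory_ensemble}.
#' @param geometric If TRUE use the unweighted geometric centre instead of
#'   the mass-weighted COM.
#' @return A \code{feature_set}: list of T x 4 matrices (nm).
#' @export
domain_com_distances <- function(ensemble, geometric = FALSE) {
  stopifnot(inherits(ensemble, "trajectory_ensemble"))
  topo <- ensemble$topology
  sels <- list(
    A.Ntd = which(topo$chain == "A" & topo$domain == "Ntd"),
    A.Ctd = which(topo$chain == "A" & topo$domain == "Ctd"),
    B.Ntd = which(topo$chain == "B" & topo$domain == "Ntd"),
    B.Ctd = which(topo$chain == "B" & topo$domain == "Ctd"))
  pairs <- list(c("A.Ntd", "B.Ntd"), c("A.Ntd", "B.Ctd"),
                c("A.Ctd", "B.Ntd"), c("A.Ctd", "B.Ctd"))
  feats <- lapply(ensemble$replicas, function(coords) {
    coms <- lapply(sels, selection_com, coords = coords, masses = topo$mass,
                   geometric = geometric)
    x <- vapply(pairs, function(p) {
      d <- coms[[p[1]]] - coms[[p[2]]]
      sqrt(rowSums(d^2))
    }, numeric(dim(coords)[1]))
    x <- matrix(x, ncol = 4)
    colnames(x) <- feature_names()
    x
  })
  new_feature_set(feats, frame_interval_ns = ensemble$frame_interval_ns)
}

#' Whole-monomer centre-of-mass distance per frame
#'
#' Mass-weighted COM distance between chain A and chain B (all beads of each
#' chain, including arms), the observable used for binding/unbinding event
#' detection and distance population histograms.
#'
#' @inheritParams domain_com_distances
#' @return List of per-replica numeric vectors (nm) with the frame interval
#'   attached.
#' @export
monomer_com_distance <- function(ensemble, geometric = FALSE) {
  stopifnot(inherits(ensemble, "trajectory_ensemble"))
  topo <- ensemble$topology
  selA <- which(topo$chain == "A")
  selB <- which(topo$chain == "B")
  out <- lapply(ensemble$replicas, function(coords) {
    d <- selection_com(coords, selA, topo$mass, geometric) -
      selection_com(coords, selB, topo$mass, geometric)
    sqrt(rowSums(d^2))
  })
  attr(out, "frame_interval_ns") <- ensemble$frame_interval_ns
  out
}
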