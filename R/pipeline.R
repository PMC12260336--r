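#' Save a fitted model to a JSON archive
#'
#' Serializes any of the package's model objects (tica_model, msm_model,
#' macrostate_model, ...) to a single JSON file with full numeric precision;
#' \code{\link{load_model}} restores it.
#'
#' @param model A package model object.
#' @param path Output file.
#' @export
save_model <- function(model, path) {
  payload <- list(class = class(model)[1], fields = unclass(model))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor", null = "null")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  payload <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  structure(payload$fields, class = payload$class)
}

pipeline_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full dimerization MSM pipeline from a config
#'
#' Executes featurization, TICA, microstate clustering, reversible MSM
#' estimation, Chapman-Kolmogorov validation, PCCA++ coarse-graining,
#' macrostate free energies, MFPTs, the coarse transition network and the
#' binding/unbinding distance analyses, writing all report tables (TSV), a
#' run manifest (JSON, capturing config and seeds) and optional figures to
#' the output directory. Reruns with an identical config produce
#' bit-identical tables.
#'
#' The config (YAML file or list) either names input files
#' (\code{input: topology/trajectories/annotation}) or requests synthetic
#' data (\code{simulate:} with a chain preset, replica count and replica
#' length). Defaults follow the coarse-grained association protocol: TICA
#' lag 5 ns preserving 95\% kinetic variance, 250 microstates, MSM lag 5 ns,
#' 6 macrostates, 310 K, 6/7 nm distance thresholds.
#'
#' @param config Path to a YAML config or an equivalent named list.
#' @param output_dir Overrides the config's \code{output_dir}.
#' @return Invisibly, the report: protocol summary, models and tables.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  out_dir <- output_dir %||% cfg$output_dir
  if (is.null(out_dir)) stop("config must set 'output_dir'", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- cfg$seed %||% 1
  seeds <- list(master = seed)

  # --- data -----------------------------------------------------------
  chain <- NULL
  if (!is.null(cfg$simulate)) {
    dat <- pipeline_stage("simulate", {
      sim <- cfg$simulate
      chain <- example_dimer_chain(sim$chain %||% "asymmetric",
                                    lag_step_ns = sim$lag_step_ns %||% 5,
                                    emission_sd = sim$emission_sd %||% 0.35)
      n_rep <- sim$n_replicas %||% 15
      len_ns <- sim$replica_length_ns %||% 5000
      n_steps <- max(2L, round(len_ns / chain$lag_step_ns))
      seeds$chain <- seed
      seeds$emission <- seed + 1L
      labels <- simulate_markov_chain(chain, n_steps, n_rep, seed = seed,
                                      start = sim$start %||% "stationary")
      feats <- emit_distance_trajectories(labels, chain, seed = seed + 1L)
      mono <- lapply(feats, rowMeans)
      attr(mono, "frame_interval_ns") <- chain$lag_step_ns
      list(features = feats, monomer = mono, labels = labels,
           protocol = protocol_summary(n_rep, len_ns))
    })
  } else if (!is.null(cfg$input)) {
    dat <- pipeline_stage("featurization", {
      ens <- load_trajectories(cfg$input$topology,
                               unlist(cfg$input$trajectories),
                               cfg$input$annotation)
      mono <- monomer_com_distance(ens)
      list(features = domain_com_distances(ens), monomer = mono,
           ensemble = ens, protocol = protocol_summary(ens))
    })
  } else {
    stop("config must provide either 'simulate' or 'input'", call. = FALSE)
  }

  # --- models ---------------------------------------------------------
  tica <- pipeline_stage("tica", fit_tica(
    dat$features, lag_ns = cfg$tica$lag_ns %||% 5,
    variance_cutoff = cfg$tica$kinetic_variance %||% 0.95))
  proj <- pipeline_stage("tica", project_tica(tica, dat$features))
  seeds$cluster <- cfg$cluster$seed %||% (seed + 2L)
  disc <- pipeline_stage("clustering", cluster_microstates(
    proj, k = cfg$cluster$n_microstates %||% 250, seed = seeds$cluster,
    fit_frames = cfg$cluster$fit_frames))
  model <- pipeline_stage("msm", estimate_msm(
    disc, lag_ns = cfg$msm$lag_ns %||% 5))
  macro <- pipeline_stage("pcca", pcca_plus(
    model, cfg$macrostates$n %||% 6))
  ck <- pipeline_stage("ck_test", ck_test(
    model, disc, macro, factors = cfg$ck$factors %||% 1:5))
  dG <- pipeline_stage("free_energies", macrostate_free_energies(
    model$stationary, macro, temperature_K = cfg$temperature_K %||% 310))
  mfpts <- pipeline_stage("mfpt", mfpt_matrix(model, macro))
  net <- pipeline_stage("network", coarse_transition_network(model, macro))
  thr_b <- cfg$thresholds$bound_nm %||% 6
  thr_u <- cfg$thresholds$unbound_nm %||% 7
  events <- pipeline_stage("events", detect_association_events(
    dat$monomer, thr_b, thr_u))
  pops <- pipeline_stage("populations", population_fractions(
    dat$monomer, thr_b, thr_u, bin_width = cfg$bin_width %||% 0.1))

  # --- report ---------------------------------------------------------
  wt <- function(x, f) utils::write.table(
    x, file.path(out_dir, f), sep = "\t", row.names = FALSE, quote = FALSE)
  proto <- dat$protocol
  wt(data.frame(n_replicas = proto$n_replicas,
                replica_length_ns = mean(proto$replica_length_ns),
                aggregate_ns = proto$aggregate_ns,
                aggregate_us = proto$aggregate_us), "protocol.tsv")
  wt(dG, "free_energies.tsv")
  mf_df <- as.data.frame(as.table(mfpts))
  names(mf_df) <- c("source", "target", "mfpt_ns")
  wt(mf_df, "mfpt.tsv")
  wt(net$edges, "coarse_network.tsv")
  wt(as.data.frame(ck), "ck_test.tsv")
  wt(events$segments, "events.tsv")
  wt(pops$histogram, "distance_histogram.tsv")
  wt(data.frame(bound_fraction = pops$bound_fraction,
                unbound_fraction = pops$unbound_fraction,
                intermediate_fraction = pops$intermediate_fraction,
                n_binding = events$n_binding,
                n_unbinding = events$n_unbinding), "populations.tsv")
  save_model(model, file.path(out_dir, "msm_model.json"))
  save_model(tica, file.path(out_dir, "tica_model.json"))
  jsonlite::write_json(list(
    config = cfg, seeds = seeds,
    package_version = as.character(utils::packageVersion("dimerMSM")),
    n_microstates_active = model$n_micro, coverage = model$coverage),
    file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null")

  if (isTRUE(cfg$figures %||% TRUE)) {
    pipeline_stage("figures", pipeline_figures(out_dir, pops, ck, net, thr_b,
                                               thr_u))
  }

  invisible(list(protocol = proto, tica = tica, discretization = disc,
                 msm = model, macrostates = macro, ck = ck,
                 free_energies = dG, mfpt = mfpts, network = net,
                 events = events, populations = pops, chain = chain,
                 seeds = seeds, output_dir = out_dir))
}

# basic renderings: distance populations, CK curves, coarse network
pipeline_figures <- function(out_dir, pops, ck, net, thr_b, thr_u) {
  grDevices::pdf(file.path(out_dir, "report_figures.pdf"), width = 7,
                 height = 5)
  on.exit(grDevices::dev.off())
  with(pops$histogram, {
    graphics::plot(mid, fraction, type = "h", lwd = 3, col = "grey40",
                   xlab = "monomer-monomer COM distance (nm)",
                   ylab = "fraction of frames",
                   main = "Distance populations")
    graphics::abline(v = c(thr_b, thr_u), lty = 2, col = "red")
  })
  sets <- unique(ck$set)
  graphics::par(mfrow = c(1, min(3, length(sets))))
  for (si in sets[seq_len(min(3, length(sets)))]) {
    sub <- ck[ck$set == si, ]
    graphics::plot(sub$lag_ns, sub$predicted, type = "b", ylim = c(0, 1),
                   xlab = "lag (ns)", ylab = "residence probability",
                   main = sprintf("CK test, set %d", si))
    graphics::arrows(sub$lag_ns, sub$estimated - 1.96 * sub$se,
                     sub$lag_ns, sub$estimated + 1.96 * sub$se,
                     angle = 90, code = 3, length = 0.03, col = "blue")
    graphics::points(sub$lag_ns, sub$estimated, col = "blue", pch = 4)
  }
  graphics::par(mfrow = c(1, 1))
  m <- length(net$weights)
  ang <- 2 * pi * seq_len(m) / m
  xy <- cbind(cos(ang), sin(ang))
  graphics::plot(xy, cex = 1 + 14 * net$weights, pch = 21, bg = "steelblue",
                 xlim = c(-1.4, 1.4), ylim = c(-1.4, 1.4), axes = FALSE,
                 xlab = "", ylab = "", main = "Coarse transition network")
  for (e in seq_len(nrow(net$edges))) {
    i <- net$edges$from[e]; j <- net$edges$to[e]
    p <- net$edges$probability[e]
    if (i != j && p > 1e-4) {
      graphics::arrows(xy[i, 1], xy[i, 2], xy[j, 1], xy[j, 2],
                       lwd = 0.5 + 8 * p, length = 0.08,
                       col = grDevices::grey(0.2))
    }
  }
  graphics::text(xy[, 1] * 1.2, xy[, 2] * 1.2, paste0("S", seq_len(m)))
  invisible(NULL)
}
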