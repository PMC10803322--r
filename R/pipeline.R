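#' Trial-averaged nodal strengths for a whole cohort
#'
#' Runs the preprocessing chain (gap interpolation, axis remapping,
#' zero-phase low-pass filtering, heel-strike segmentation, double
#' differentiation) and the kinectome construction for every trial of
#' every subject and condition, computes nodal strength per axis and
#' averages it across trials.
#'
#' @param trajectories Nested list `[[subject]][[condition]][[trial]]` of
#'   raw [trajectory_set()]s (as in a `kinectome_cohort` or read back by
#'   [read_cohort_fixture()]).
#' @param definition A [marker_set_definition()].
#' @param max_gap,cutoff,order,min_length_s Passed to the preprocessing
#'   stages.
#' @param events Optional nested list of curated [gait_events()] mirroring
#'   `trajectories`.
#' @return A list with `strengths` (long-format [strength_table()] of
#'   trial-averaged profiles), `kinectomes` (per subject/condition list
#'   of per-trial axis kinectomes), and `log` (data frame of rejected
#'   trials with reasons).
#' @export
cohort_strengths <- function(trajectories,
                             definition = marker_set_definition(),
                             max_gap = 10, cutoff = 10, order = 4,
                             min_length_s = 0.5, events = NULL) {
  axes <- c("ML", "AP", "VT")
  profiles <- list()
  kin_store <- list()
  rejects <- list()
  for (sid in names(trajectories)) {
    for (cond in names(trajectories[[sid]])) {
      per_axis <- stats::setNames(vector("list", 3), axes)
      trials <- trajectories[[sid]][[cond]]
      n_expected <- length(trials)
      for (tr in seq_along(trials)) {
        ev <- if (!is.null(events)) events[[sid]][[cond]][[tr]] else NULL
        acc <- tryCatch(
          preprocess_trial(trials[[tr]], events = ev, max_gap = max_gap,
                           cutoff = cutoff, order = order,
                           min_length_s = min_length_s,
                           definition = definition),
          error = function(e) e)
        if (inherits(acc, "error")) {
          rejects[[length(rejects) + 1L]] <- data.frame(
            subject = sid, condition = cond, trial = tr,
            reason = conditionMessage(acc), stringsAsFactors = FALSE)
          next
        }
        ks <- kinectome_set(acc)
        kin_store[[sid]][[cond]][[length(kin_store[[sid]][[cond]]) + 1L]] <- ks
        for (a in axes)
          per_axis[[a]][[length(per_axis[[a]]) + 1L]] <- nodal_strength(ks[[a]])
      }
      for (a in axes) {
        if (!length(per_axis[[a]])) next
        profiles[[length(profiles) + 1L]] <-
          average_over_trials(per_axis[[a]], n_expected = n_expected)
      }
    }
  }
  list(strengths = strength_table(profiles),
       kinectomes = kin_store,
       log = if (length(rejects)) do.call(rbind, rejects) else
         data.frame(subject = character(0), condition = character(0),
                    trial = integer(0), reason = character(0)))
}

#' Run the full kinectome analysis pipeline
#'
#' Orchestrates simulate (or load) - preprocess - build - compare -
#' predict as one reproducible run. Every stage's outputs are written
#' under `out_dir` and listed, with MD5 checksums, in the returned run
#' manifest (also written as `manifest.json`).
#'
#' @param config A list (or path to a YAML file) with entries:
#'   \describe{
#'     \item{input_dir}{fixture directory to read, or `NULL` to simulate;}
#'     \item{simulate}{list of [cohort_config()] overrides used when
#'       `input_dir` is `NULL`;}
#'     \item{out_dir}{output directory (required);}
#'     \item{filter}{list with `cutoff_hz` (10) and `order` (4);}
#'     \item{gaps}{list with `max_frames` (10);}
#'     \item{alpha}{significance level (0.05);}
#'     \item{fdr_family}{`"axis"` or `"pooled"`;}
#'     \item{nodes}{regression node selection (default the limb-coupling
#'       arm nodes RLELB, LLELB, RWRB, LWRB);}
#'     \item{axis}{regression axis ("AP");}
#'     \item{cv}{list with `k` (5) and `repetitions` (100);}
#'     \item{seed}{global seed (1);}
#'     \item{render_figure}{logical (FALSE): write the network figure.}
#'   }
#' @return The run manifest (list), invisibly. Key counts: trials read,
#'   trials rejected (with reasons in the preprocessing log), subjects
#'   modelled, tests performed.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(list(
    input_dir = NULL, simulate = list(), out_dir = NULL,
    filter = list(cutoff_hz = 10, order = 4), gaps = list(max_frames = 10),
    alpha = 0.05, fdr_family = "axis",
    nodes = c("RLELB", "LLELB", "RWRB", "LWRB"), axis = "AP",
    cv = list(k = 5, repetitions = 100), seed = 1, render_figure = FALSE),
    config)
  # fail-fast validation before any computation
  if (is.null(cfg$out_dir)) stop("config error: out_dir is required")
  if (!is.null(cfg$input_dir) && !dir.exists(cfg$input_dir))
    stop("config error: input_dir does not exist: ", cfg$input_dir)
  if (!all(cfg$nodes %in% kinectome_markers()))
    stop("config error: unknown node(s): ",
         paste(setdiff(cfg$nodes, kinectome_markers()), collapse = ", "))
  if (!cfg$axis %in% c("ML", "AP", "VT"))
    stop("config error: axis must be ML, AP or VT")
  stopifnot(cfg$filter$cutoff_hz > 0, cfg$filter$order >= 1,
            cfg$gaps$max_frames >= 0, cfg$alpha > 0, cfg$alpha < 1,
            cfg$cv$k >= 2, cfg$cv$repetitions >= 1)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  # stage 1: simulate or load
  if (is.null(cfg$input_dir)) {
    sim_cfg <- do.call(cohort_config, c(cfg$simulate, list(seed = cfg$seed)))
    cohort <- generate_cohort(sim_cfg)
    trajectories <- cohort$trajectories
    clinical <- cohort$clinical
  } else {
    fx <- read_cohort_fixture(cfg$input_dir)
    trajectories <- fx$trajectories
    clinical <- fx$clinical
  }
  n_trials_read <- sum(vapply(trajectories, function(s)
    sum(lengths(s)), integer(1)))

  # stage 2 + 3: preprocess and build kinectomes / nodal strengths
  cs <- cohort_strengths(trajectories,
                         max_gap = cfg$gaps$max_frames,
                         cutoff = cfg$filter$cutoff_hz,
                         order = cfg$filter$order)
  utils::write.csv(cs$strengths,
                   file.path(cfg$out_dir, "nodal_strength.csv"),
                   row.names = FALSE)
  utils::write.csv(cs$log, file.path(cfg$out_dir, "rejected_trials.csv"),
                   row.names = FALSE)
  n_kinectomes <- 0L
  for (sid in names(cs$kinectomes))
    for (cond in names(cs$kinectomes[[sid]]))
      for (ks in cs$kinectomes[[sid]][[cond]])
        for (a in names(ks)) {
          n_kinectomes <- n_kinectomes + 1L
        }

  # stage 4: paired comparison with FDR control
  comparison <- compare_conditions(cs$strengths, alpha = cfg$alpha,
                                   fdr_family = cfg$fdr_family)
  utils::write.csv(comparison, file.path(cfg$out_dir, "comparison.csv"),
                   row.names = FALSE)

  # stage 5: clinical prediction
  deltas <- assemble_deltas(cs$strengths, clinical, cfg$nodes, cfg$axis)
  model <- fit_multilinear(deltas)
  cv <- crossvalidate(deltas, k = cfg$cv$k,
                      repetitions = cfg$cv$repetitions, seed = cfg$seed)
  utils::write.csv(model$coefficients,
                   file.path(cfg$out_dir, "model_coefficients.csv"),
                   row.names = FALSE)
  utils::write.csv(cv$per_repetition,
                   file.path(cfg$out_dir, "cv_repetitions.csv"),
                   row.names = FALSE)

  if (isTRUE(cfg$render_figure)) {
    k1 <- cs$kinectomes[[1]][["off"]][[1]][["ML"]]
    render_network_figure(comparison, k1,
                          file = file.path(cfg$out_dir, "network.pdf"))
  }

  out_files <- list.files(cfg$out_dir, full.names = FALSE)
  out_files <- setdiff(out_files, "manifest.json")
  manifest <- list(
    package_version = as.character(utils::packageVersion("kinectome")),
    seed = cfg$seed,
    counts = list(trials_read = n_trials_read,
                  trials_rejected = nrow(cs$log),
                  kinectomes_built = n_kinectomes,
                  tests_performed = nrow(comparison),
                  subjects_modelled = model$n),
    model = list(r_squared = model$r_squared,
                 cv_mean_cor = cv$mean_cor, cv_mean_rmse = cv$mean_rmse),
    files = lapply(stats::setNames(out_files, out_files), function(f)
      unname(tools::md5sum(file.path(cfg$out_dir, f)))))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Render the kinematic network on a body schematic
#'
#' Draws the 21 nodes on a static body-schematic layout, coloured by the
#' direction of the significant condition difference (blue off>on, red
#' on>off, grey none), sized by median off-condition nodal strength, with
#' only the top fraction of edges by absolute weight drawn. Purely
#' presentational: the statistics never threshold edges.
#'
#' @param comparison Output of [compare_conditions()] (rows of the
#'   kinectome's axis are used).
#' @param kinectome A `kinectome` supplying the edge weights.
#' @param edge_fraction Fraction of ordered edges drawn (default 0.15;
#'   `round(fraction * N(N-1))` ordered edges, i.e. the ceiling half of
#'   that many undirected edges, ties broken by matrix order).
#' @param file Output file (`.pdf` or `.png`).
#' @return Invisibly, the number of undirected edges drawn.
#' @export
render_network_figure <- function(comparison, kinectome, edge_fraction = 0.15,
                                  file) {
  stopifnot(inherits(kinectome, "kinectome"))
  lay <- body_layout()
  W <- kinectome$W
  n <- nrow(W)
  idx <- which(upper.tri(W), arr.ind = TRUE)
  wts <- abs(W[idx])
  k_ordered <- round(edge_fraction * n * (n - 1))
  k_undir <- min(length(wts), as.integer(ceiling(k_ordered / 2)))
  keep <- order(wts, decreasing = TRUE)[seq_len(k_undir)]
  comp <- comparison[comparison$axis == kinectome$axis, ]
  dir_of <- stats::setNames(comp$direction, comp$node)
  size_of <- stats::setNames(comp$median_off, comp$node)
  cols <- vapply(lay$marker, function(m) {
    d <- dir_of[m]
    if (is.na(d) || d == "none") "grey70"
    else if (d == "off>on") "steelblue" else "firebrick"
  }, character(1))
  ext <- tolower(tools::file_ext(file))
  if (ext == "png") grDevices::png(file, 800, 1000) else
    grDevices::pdf(file, 6, 7.5)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(1, 1, 3, 1))
  graphics::plot(NA, xlim = c(-0.5, 0.5), ylim = c(-0.05, 1.1),
                 axes = FALSE, xlab = "", ylab = "", asp = 1,
                 main = sprintf("Kinematic network, %s axis (top %d%% of edges)",
                                kinectome$axis, round(edge_fraction * 100)))
  li <- match(kinectome$labels, lay$marker)
  for (e in keep) {
    i <- idx[e, 1]; j <- idx[e, 2]
    graphics::segments(lay$x[li[i]], lay$y[li[i]],
                       lay$x[li[j]], lay$y[li[j]],
                       col = grDevices::adjustcolor("black", 0.25 + 0.6 *
                                                      wts[e] / max(wts)),
                       lwd = 0.5 + 2.5 * wts[e] / max(wts))
  }
  sz <- size_of[lay$marker]
  sz[!is.finite(sz)] <- mean(sz[is.finite(sz)])
  if (all(!is.finite(sz))) sz[] <- 1
  cex <- 1 + 2 * (sz - min(sz)) / max(1e-9, diff(range(sz)))
  graphics::points(lay$x, lay$y, pch = 21, bg = cols, cex = cex)
  graphics::text(lay$x, lay$y - 0.035, lay$marker, cex = 0.55)
  invisible(k_undir)
}
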