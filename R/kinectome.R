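#' Build a kinectome for one axis
#'
#' The kinectome is the whole-body kinematic network of one trial on one
#' movement axis: an `N x N` symmetric matrix of Pearson correlation
#' coefficients between the acceleration time series of each pair of the
#' `N` markers (N = 21 for the canonical set, giving `N(N-1) = 420`
#' ordered off-diagonal edges). The diagonal is exactly 1.
#'
#' @param acc An [acceleration_set()] over the segmented trial window.
#' @param axis `"ML"`, `"AP"` or `"VT"`.
#' @return An object of class `kinectome` with fields `subject_id`,
#'   `condition`, `axis`, `trial_index`, `labels` and the matrix `W`.
#' @export
build_kinectome <- function(acc, axis = c("ML", "AP", "VT")) {
  stopifnot(inherits(acc, "acceleration_set"))
  axis <- match.arg(axis)
  x <- axis_matrix(acc, axis)
  if (nrow(x) < 10) stop("need at least 10 frames to correlate")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance acceleration series (degenerate correlation) for ",
         "marker(s): ", paste(colnames(x)[sds == 0], collapse = ", "))
  W <- stats::cor(x)
  diag(W) <- 1
  structure(list(subject_id = acc$subject_id, condition = acc$condition,
                 axis = axis, trial_index = acc$trial_index,
                 labels = colnames(x), W = W),
            class = "kinectome")
}

#' @export
print.kinectome <- function(x, ...) {
  n <- nrow(x$W)
  cat(sprintf("<kinectome> subject %s, %s, %s axis, trial %d: %d nodes, %d ordered edges\n",
              x$subject_id, x$condition, x$axis, x$trial_index, n, n * (n - 1)))
  invisible(x)
}

#' Number of off-diagonal edges of a kinectome
#'
#' @param k A `kinectome`.
#' @param ordered If `TRUE` (default) count ordered pairs, `N(N-1)`
#'   (420 for 21 markers); otherwise unique undirected pairs `N(N-1)/2`.
#' @return Integer edge count.
#' @export
n_edges <- function(k, ordered = TRUE) {
  n <- nrow(k$W)
  if (ordered) n * (n - 1L) else (n * (n - 1L)) %/% 2L
}

#' Kinectomes for all three axes of one trial
#'
#' @param acc An [acceleration_set()].
#' @return Named list of three `kinectome` objects (`ML`, `AP`, `VT`);
#'   over a subject's two medication conditions this yields the six
#'   kinectome types (2 conditions x 3 axes).
#' @export
kinectome_set <- function(acc) {
  axes <- c("ML", "AP", "VT")
  stats::setNames(lapply(axes, function(a) build_kinectome(acc, a)), axes)
}

#' Nodal strength of a kinectome
#'
#' The nodal strength of node i is the sum of the absolute weights of all
#' edges incident to it, `S_i = sum_{j != i} |W_ij|`; the self-correlation
#' on the diagonal is excluded. It measures how synchronised one body
#' landmark's acceleration is with the rest of the body, and is bounded
#' by `N - 1`.
#'
#' @param k A `kinectome`.
#' @return An object of class `nodal_strength` with the named vector `S`.
#' @export
nodal_strength <- function(k) {
  stopifnot(inherits(k, "kinectome"))
  A <- abs(k$W)
  diag(A) <- 0
  structure(list(subject_id = k$subject_id, condition = k$condition,
                 axis = k$axis, S = rowSums(A), n_trials_averaged = 1L),
            class = "nodal_strength")
}

#' Average nodal strength across trials
#'
#' Element-wise arithmetic mean of nodal-strength profiles from repeated
#' trials of the same subject, condition and axis.
#'
#' @param profiles List of `nodal_strength` objects sharing subject,
#'   condition and axis.
#' @param n_expected Expected number of trials (default `NULL`); a
#'   warning is raised if fewer profiles are supplied (e.g. a rejected
#'   trial).
#' @return A `nodal_strength` with `n_trials_averaged` recorded.
#' @export
average_over_trials <- function(profiles, n_expected = NULL) {
  if (!length(profiles)) stop("no profiles to average")
  stopifnot(all(vapply(profiles, inherits, logical(1), "nodal_strength")))
  meta <- unique(t(vapply(profiles, function(p)
    c(p$subject_id, p$condition, p$axis), character(3))))
  if (nrow(meta) != 1)
    stop("profiles mix subjects, conditions or axes; cannot average")
  if (!is.null(n_expected) && length(profiles) < n_expected)
    warning("averaging over ", length(profiles), " trials where ",
            n_expected, " were expected (subject ", meta[1, 1], ", ",
            meta[1, 2], ", ", meta[1, 3], ")")
  S <- Reduce(`+`, lapply(profiles, `[[`, "S")) / length(profiles)
  structure(list(subject_id = meta[1, 1], condition = meta[1, 2],
                 axis = meta[1, 3], S = S,
                 n_trials_averaged = length(profiles)),
            class = "nodal_strength")
}

#' Long-format nodal-strength table
#'
#' @param profiles List of `nodal_strength` objects.
#' @return A data frame with columns `subject`, `condition`, `axis`,
#'   `node`, `strength`, `n_trials`.
#' @export
strength_table <- function(profiles) {
  do.call(rbind, lapply(profiles, function(p)
    data.frame(subject = p$subject_id, condition = p$condition,
               axis = p$axis, node = names(p$S), strength = unname(p$S),
               n_trials = p$n_trials_averaged,
               stringsAsFactors = FALSE, row.names = NULL)))
}

#' Write a kinectome matrix as delimited text
#'
#' Square matrix with marker labels as header row and first column, plus
#' a YAML sidecar with subject, condition, axis and trial metadata.
#'
#' @param k A `kinectome`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_kinectome <- function(k, path) {
  stopifnot(inherits(k, "kinectome"))
  df <- data.frame(marker = k$labels, k$W, check.names = FALSE)
  data.table::fwrite(df, path)
  yaml::write_yaml(list(subject_id = k$subject_id, condition = k$condition,
                        axis = k$axis, trial_index = k$trial_index),
                   sidecar_path(path))
  invisible(path)
}

#' Read a kinectome written by [write_kinectome()]
#'
#' @param path Path to the matrix file.
#' @return A `kinectome`.
#' @export
read_kinectome <- function(path) {
  meta <- yaml::read_yaml(sidecar_path(path))
  df <- data.table::fread(path, data.table = FALSE)
  labels <- df$marker
  W <- as.matrix(df[, -1, drop = FALSE])
  rownames(W) <- labels
  structure(list(subject_id = meta$subject_id, condition = meta$condition,
                 axis = meta$axis, trial_index = meta$trial_index,
                 labels = labels, W = W),
            class = "kinectome")
}
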