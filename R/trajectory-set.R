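#' Construct a trajectory set
#'
#' A trajectory set holds the 3-D position time series of a collection of
#' markers for one trial of one subject in one condition. Positions are in
#' millimetres, sampled at `sampling_rate` frames per second. Each marker
#' track is an `n_frames x 3` matrix whose columns follow the set's axis
#' labels; an occlusion mask flags frames where the marker was not seen.
#'
#' @param subject_id Subject identifier (character).
#' @param condition Condition label, `"off"` or `"on"`.
#' @param trial_index Trial number within the condition (1-based).
#' @param sampling_rate Sampling rate in frames per second (> 0).
#' @param data Named list of `n x 3` numeric matrices, one per marker.
#' @param occlusion Optional named list of logical vectors (length `n`),
#'   `TRUE` where the marker is missing. Defaults to all-`FALSE`.
#' @param axis_names Length-3 character vector labelling the three
#'   position components, e.g. `c("X","Y","Z")` or `c("ML","AP","VT")`.
#' @param axis_convention Named character vector mapping the anatomical
#'   axes `ML`, `AP`, `VT` to (possibly sign-prefixed) entries of
#'   `axis_names`, e.g. `c(ML = "X", AP = "Y", VT = "Z")`. `NULL` if the
#'   set is already expressed in `ML`/`AP`/`VT`.
#' @return An object of class `trajectory_set`.
#' @export
trajectory_set <- function(subject_id, condition, trial_index, sampling_rate,
                           data, occlusion = NULL,
                           axis_names = c("ML", "AP", "VT"),
                           axis_convention = NULL) {
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1 ||
      !is.finite(sampling_rate) || sampling_rate <= 0)
    stop("sampling_rate must be a single positive number")
  if (!is.list(data) || is.null(names(data)) || any(names(data) == ""))
    stop("data must be a named list of n x 3 matrices")
  if (anyDuplicated(names(data)))
    stop("marker labels must be unique within a trajectory set")
  nf <- vapply(data, nrow, integer(1))
  if (length(unique(nf)) != 1L) {
    bad <- names(data)[nf != nf[1]]
    stop("inconsistent frame counts across markers: ",
         paste(bad, collapse = ", "))
  }
  for (m in names(data)) {
    if (!is.matrix(data[[m]]) || ncol(data[[m]]) != 3L)
      stop("marker '", m, "' is not an n x 3 matrix")
  }
  n <- nf[[1]]
  if (is.null(occlusion))
    occlusion <- lapply(data, function(x) rep(FALSE, n))
  occlusion <- occlusion[names(data)]
  for (m in names(data)) {
    occ <- occlusion[[m]]
    if (length(occ) != n) stop("occlusion mask length mismatch for '", m, "'")
    if (any(!is.finite(data[[m]][!occ, ])))
      stop("non-finite position outside occluded frames for marker '", m, "'")
  }
  structure(list(subject_id = as.character(subject_id),
                 condition = match.arg(condition, c("off", "on")),
                 trial_index = as.integer(trial_index),
                 sampling_rate = sampling_rate,
                 data = data, occlusion = occlusion,
                 axis_names = axis_names,
                 axis_convention = axis_convention),
            class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat(sprintf(
    "<trajectory_set> subject %s, %s, trial %d: %d markers x %d frames @ %g Hz [%s]\n",
    x$subject_id, x$condition, x$trial_index, length(x$data),
    n_frames(x), x$sampling_rate, paste(x$axis_names, collapse = ",")))
  invisible(x)
}

n_frames <- function(x) nrow(x$data[[1]])

marker_labels <- function(x) names(x$data)

# replace the per-marker data of a trajectory/acceleration set, keeping
# metadata; occlusion reset to all-clear unless supplied
replace_data <- function(x, data, occlusion = NULL) {
  x$data <- data
  n <- nrow(data[[1]])
  x$occlusion <- if (is.null(occlusion))
    lapply(data, function(d) rep(FALSE, n)) else occlusion
  x
}

#' Construct an acceleration set
#'
#' Same structure as [trajectory_set()] but per-frame values are
#' accelerations in mm/s^2 and the axes are always `ML`, `AP`, `VT`.
#'
#' @inheritParams trajectory_set
#' @return An object of class `acceleration_set`.
#' @export
acceleration_set <- function(subject_id, condition, trial_index,
                             sampling_rate, data) {
  obj <- trajectory_set(subject_id, condition, trial_index, sampling_rate,
                        data, axis_names = c("ML", "AP", "VT"))
  for (m in names(data))
    if (any(!is.finite(data[[m]])))
      stop("non-finite acceleration for marker '", m, "'")
  class(obj) <- c("acceleration_set", "trajectory_set")
  obj
}

#' @export
print.acceleration_set <- function(x, ...) {
  cat(sprintf(
    "<acceleration_set> subject %s, %s, trial %d: %d markers x %d frames @ %g Hz\n",
    x$subject_id, x$condition, x$trial_index, length(x$data),
    n_frames(x), x$sampling_rate))
  invisible(x)
}

# extract an n_frames x n_markers matrix for one axis
axis_matrix <- function(x, axis) {
  idx <- match(axis, x$axis_names)
  if (is.na(idx)) stop("axis '", axis, "' not present (axes: ",
                       paste(x$axis_names, collapse = ", "), ")")
  out <- vapply(x$data, function(d) d[, idx], numeric(n_frames(x)))
  colnames(out) <- marker_labels(x)
  out
}
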