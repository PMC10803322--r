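#' Write a trajectory set to the tabular dialect
#'
#' The canonical on-disk form of a trial is a delimited text file with one
#' row per frame and columns `<label>_<axis>` for each marker and axis
#' (e.g. `T10_X`), plus a YAML sidecar (same path with extension
#' `.yaml`) carrying `subject_id`, `condition`, `trial_index`,
#' `sampling_rate`, `axis_names` and `axis_convention`. Occluded frames
#' are written as empty cells and read back as occlusions.
#'
#' @param t A [trajectory_set()].
#' @param path Output file path (conventionally `.csv`).
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(t, path) {
  stopifnot(inherits(t, "trajectory_set"))
  cols <- list()
  for (m in marker_labels(t)) {
    d <- t$data[[m]]
    d[t$occlusion[[m]], ] <- NA_real_
    for (k in 1:3)
      cols[[paste0(m, "_", t$axis_names[k])]] <- d[, k]
  }
  df <- data.table::as.data.table(cols)
  data.table::fwrite(df, path, na = "")
  meta <- list(subject_id = t$subject_id, condition = t$condition,
               trial_index = t$trial_index, sampling_rate = t$sampling_rate,
               axis_names = as.list(t$axis_names))
  if (!is.null(t$axis_convention))
    meta$axis_convention <- as.list(t$axis_convention)
  yaml::write_yaml(meta, sidecar_path(path))
  invisible(path)
}

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".yaml")

#' Read marker trajectories
#'
#' Reads one trial of marker trajectories. The tabular dialect (see
#' [write_trajectories()]) is the canonical format; blank or `NA` cells
#' mark occluded frames. C3D files are not parsed by this package: export
#' to the tabular dialect first.
#'
#' @param source Path to a trajectory file.
#' @param format_hint Either `"tabular"` (default) or `"c3d"`.
#' @return A [trajectory_set()].
#' @export
read_trajectories <- function(source, format_hint = c("tabular", "c3d")) {
  format_hint <- match.arg(format_hint)
  if (format_hint == "c3d")
    stop("C3D reading is not supported; export the trial to the tabular ",
         "trajectory dialect (see write_trajectories) and read that instead")
  if (!file.exists(source)) stop("trajectory file not found: ", source)
  meta_path <- sidecar_path(source)
  if (!file.exists(meta_path))
    stop("missing metadata sidecar: ", meta_path)
  meta <- yaml::read_yaml(meta_path)
  df <- data.table::fread(source, na.strings = c("", "NA"), data.table = FALSE)
  axis_names <- unlist(meta$axis_names)
  parts <- strsplit(names(df), "_(?=[^_]+$)", perl = TRUE)
  lab <- vapply(parts, `[`, "", 1)
  ax  <- vapply(parts, `[`, "", 2)
  if (!all(ax %in% axis_names))
    stop("column axis suffixes do not match sidecar axis_names")
  markers <- unique(lab)
  data <- list(); occlusion <- list()
  for (m in markers) {
    sel <- vapply(axis_names, function(a) {
      j <- which(lab == m & ax == a)
      if (length(j) != 1)
        stop("marker '", m, "' lacks a unique column for axis ", a)
      j
    }, integer(1))
    mat <- as.matrix(df[, sel, drop = FALSE])
    dimnames(mat) <- NULL
    occ <- apply(is.na(mat), 1, any)
    mat[occ, ] <- 0  # placeholder under the mask
    data[[m]] <- mat
    occlusion[[m]] <- occ
  }
  trajectory_set(meta$subject_id, meta$condition, meta$trial_index,
                 meta$sampling_rate, data, occlusion,
                 axis_names = axis_names,
                 axis_convention = if (!is.null(meta$axis_convention))
                   unlist(meta$axis_convention) else NULL)
}

#' Select and order the canonical 21 analysis markers
#'
#' Restricts a trajectory set to the 21 canonical anatomical markers, in
#' the fixed canonical order (see [kinectome_markers()]), resolving vendor
#' labels through the definition's alias map. All other markers are
#' dropped. The operation is idempotent.
#'
#' @param raw A [trajectory_set()].
#' @param definition A [marker_set_definition()].
#' @return A `trajectory_set` with exactly 21 markers in canonical order.
#' @export
select_markers <- function(raw, definition = marker_set_definition()) {
  stopifnot(inherits(raw, "trajectory_set"),
            inherits(definition, "marker_set_definition"))
  present <- marker_labels(raw)
  resolved <- present
  if (!is.null(definition$aliases)) {
    hit <- match(present, names(definition$aliases))
    resolved[!is.na(hit)] <- unname(definition$aliases[hit[!is.na(hit)]])
  }
  canon <- definition$canonical_labels
  idx <- match(canon, resolved)
  if (anyNA(idx))
    stop("markers missing from trajectory set: ",
         paste(canon[is.na(idx)], collapse = ", "))
  raw$data <- stats::setNames(raw$data[idx], canon)
  raw$occlusion <- stats::setNames(raw$occlusion[idx], canon)
  raw
}

#' Re-express a trajectory set in anatomical axes
#'
#' Maps laboratory axes onto the anatomical axes mediolateral (ML),
#' anteroposterior (AP) and vertical (VT). The convention is a named
#' character vector such as `c(ML = "X", AP = "-Y", VT = "Z")`: names are
#' the anatomical axes, values the (optionally sign-prefixed) laboratory
#' axis labels. The mapping must use each laboratory axis exactly once.
#'
#' @param t A [trajectory_set()] whose axes are laboratory axes.
#' @param convention Named character vector as above. Defaults to the
#'   set's stored `axis_convention`.
#' @return A `trajectory_set` with `axis_names = c("ML","AP","VT")`.
#' @export
remap_axes <- function(t, convention = t$axis_convention) {
  stopifnot(inherits(t, "trajectory_set"))
  if (identical(t$axis_names, c("ML", "AP", "VT")) && is.null(convention))
    return(t)
  if (is.null(convention))
    stop("no axis convention stored or supplied")
  target <- c("ML", "AP", "VT")
  if (!setequal(names(convention), target))
    stop("axis convention must name exactly ML, AP and VT")
  signs <- stats::setNames(ifelse(grepl("^-", convention), -1, 1),
                           names(convention))
  labs <- sub("^[+-]", "", convention)
  idx <- match(labs[target], t$axis_names)
  if (anyNA(idx) || anyDuplicated(idx))
    stop("axis convention is not a bijection onto the set's axes (",
         paste(t$axis_names, collapse = ","), ")")
  sgn <- signs[target]
  t$data <- lapply(t$data, function(d)
    sweep(d[, idx, drop = FALSE], 2, sgn, `*`))
  t$axis_names <- target
  t$axis_convention <- NULL
  t
}
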