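#' Interpolate short occlusion gaps
#'
#' Fills occluded runs of at most `max_gap` frames by cubic-spline
#' interpolation through the valid frames of each axis (Forsythe/Malcolm/
#' Moler end conditions, exact for polynomials up to cubic). Longer gaps,
#' and gaps touching the first or last frame (which would require
#' extrapolation), reject the trial.
#'
#' @param t A [trajectory_set()].
#' @param max_gap Maximum fillable gap length in frames (default 10).
#' @return The trajectory set with gaps filled and occlusion cleared.
#' @export
interpolate_gaps <- function(t, max_gap = 10) {
  stopifnot(inherits(t, "trajectory_set"))
  n <- n_frames(t)
  for (m in marker_labels(t)) {
    occ <- t$occlusion[[m]]
    if (!any(occ)) next
    r <- rle(occ)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    gaps <- which(r$values)
    for (g in gaps) {
      if (starts[g] == 1L || ends[g] == n)
        stop("occlusion gap touches trial boundary for marker ", m,
             " (frames ", starts[g], "-", ends[g], "); cannot extrapolate")
      if (r$lengths[g] > max_gap)
        stop("occlusion gap of ", r$lengths[g], " frames exceeds max_gap = ",
             max_gap, " for marker ", m,
             " (frames ", starts[g], "-", ends[g], "); trial rejected")
    }
    valid <- which(!occ)
    fill <- which(occ)
    d <- t$data[[m]]
    for (k in 1:3)
      d[fill, k] <- stats::spline(valid, d[valid, k], xout = fill,
                                  method = "fmm")$y
    t$data[[m]] <- d
    t$occlusion[[m]] <- rep(FALSE, n)
  }
  t
}

#' Gait events
#'
#' Per-side heel-strike frame indices, either detected from heel-marker
#' kinematics or provided from a curated event file.
#'
#' @param left,right Strictly increasing integer frame indices of left and
#'   right heel strikes.
#' @param source `"detected"` or `"provided"`.
#' @return An object of class `gait_events`.
#' @export
gait_events <- function(left, right, source = c("detected", "provided")) {
  source <- match.arg(source)
  for (s in list(left = left, right = right)) {
    if (length(s) && (any(s < 1) || is.unsorted(s, strictly = TRUE)))
      stop("heel strike frames must be strictly increasing and positive")
  }
  structure(list(left = as.integer(left), right = as.integer(right),
                 source = source), class = "gait_events")
}

#' Read a curated gait-event file
#'
#' Delimited table with header columns `side` (`left`/`right`) and
#' `frame`. Supplying curated events bypasses [detect_heel_strikes()].
#'
#' @param path Path to the event table.
#' @return A [gait_events()] with `source = "provided"`.
#' @export
read_gait_events <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("side", "frame") %in% names(tab)))
    stop("event file must have columns 'side' and 'frame'")
  gait_events(sort(tab$frame[tab$side == "left"]),
              sort(tab$frame[tab$side == "right"]),
              source = "provided")
}

#' Detect heel-strike events
#'
#' Algorithmic stand-in for visual heel-strike identification: for each
#' side, candidate events are local minima of the heel marker's vertical
#' (VT) coordinate that coincide, within `tolerance` frames, with the
#' heel's anteroposterior (AP) velocity crossing from positive to
#' non-positive (the forward motion of the heel stopping at ground
#' contact). Candidates closer than the refractory period are merged,
#' keeping the lower minimum. Curated events can be supplied instead via
#' [read_gait_events()].
#'
#' @param t A [trajectory_set()] in anatomical axes (`ML`,`AP`,`VT`)
#'   containing `LHEEL` and `RHEEL` and at least one second of data.
#' @param tolerance Coincidence window in frames (default 5).
#' @param refractory_s Minimum separation between events in seconds
#'   (default 0.4).
#' @return A [gait_events()] with `source = "detected"`.
#' @export
detect_heel_strikes <- function(t, tolerance = 5, refractory_s = 0.4) {
  stopifnot(inherits(t, "trajectory_set"))
  if (!identical(t$axis_names, c("ML", "AP", "VT")))
    stop("trajectory set must be in anatomical axes; run remap_axes first")
  missing_heels <- setdiff(c("LHEEL", "RHEEL"), marker_labels(t))
  if (length(missing_heels))
    stop("heel markers missing: ", paste(missing_heels, collapse = ", "))
  if (n_frames(t) < t$sampling_rate)
    stop("need at least one second of data for heel-strike detection")
  refractory <- round(refractory_s * t$sampling_rate)
  one_side <- function(marker) {
    vt <- t$data[[marker]][, 3]
    ap <- t$data[[marker]][, 2]
    n <- length(vt)
    i <- 2:(n - 1)
    minima <- i[vt[i] < vt[i - 1] & vt[i] <= vt[i + 1]]
    vel <- gradient_1d(ap) * t$sampling_rate
    cross <- which(vel[-n] > 0 & vel[-1] <= 0)
    if (!length(minima) || !length(cross)) return(integer(0))
    keep <- minima[vapply(minima, function(f)
      any(abs(cross - f) <= tolerance), logical(1))]
    if (!length(keep)) return(integer(0))
    # merge events within the refractory period, keeping the lower minimum
    merged <- integer(0)
    for (f in keep) {
      if (length(merged) && f - merged[length(merged)] < refractory) {
        if (vt[f] < vt[merged[length(merged)]])
          merged[length(merged)] <- f
      } else merged <- c(merged, f)
    }
    merged
  }
  left <- one_side("LHEEL"); right <- one_side("RHEEL")
  if (!length(left) && !length(right))
    stop("no heel-strike candidates detected; supply a curated event file ",
         "(read_gait_events) if events are known")
  gait_events(left, right, source = "detected")
}

#' Segment a trial into one complete gait cycle per leg
#'
#' The analysis window runs from the first heel strike of the leading
#' foot to the second subsequent heel strike of the contralateral foot,
#' which yields exactly one complete gait cycle for each leg.
#'
#' @param t A [trajectory_set()].
#' @param events A [gait_events()].
#' @param leading `"left"`, `"right"`, or `NULL` (default) for the side of
#'   the earliest detected strike.
#' @param min_length_s Minimum admissible segment length in seconds
#'   (default 0.5).
#' @return An object of class `segment` with fields `start_frame`
#'   (inclusive), `end_frame` (exclusive) and `description`.
#' @export
segment_trial <- function(t, events, leading = NULL, min_length_s = 0.5) {
  stopifnot(inherits(t, "trajectory_set"), inherits(events, "gait_events"))
  if (is.null(leading)) {
    firsts <- c(left = if (length(events$left)) events$left[1] else Inf,
                right = if (length(events$right)) events$right[1] else Inf)
    leading <- names(which.min(firsts))
  }
  leading <- match.arg(leading, c("left", "right"))
  lead <- events[[leading]]
  other <- events[[setdiff(c("left", "right"), leading)]]
  if (!length(lead))
    stop("no heel strikes on leading side (", leading, ")")
  start <- lead[1]
  contra <- other[other > start]
  if (length(contra) < 2)
    stop("need two contralateral heel strikes after the leading strike; ",
         "found ", length(contra))
  end <- contra[2]
  if (end > n_frames(t) + 1L)
    stop("segment end beyond trial bounds")
  if ((end - start) < min_length_s * t$sampling_rate)
    stop("segment shorter than ", min_length_s, " s")
  structure(list(start_frame = as.integer(start), end_frame = as.integer(end),
                 description = sprintf(
                   "%s heel strike at frame %d to second %s strike at frame %d",
                   leading, start, setdiff(c("left", "right"), leading), end)),
            class = "segment")
}

#' Crop a trajectory or acceleration set to a segment
#'
#' @param t A [trajectory_set()] or acceleration set.
#' @param seg A `segment` from [segment_trial()].
#' @return The set restricted to frames `[start_frame, end_frame)`.
#' @export
crop_segment <- function(t, seg) {
  stopifnot(inherits(t, "trajectory_set"), inherits(seg, "segment"))
  idx <- seq.int(seg$start_frame, seg$end_frame - 1L)
  t$data <- lapply(t$data, function(d) d[idx, , drop = FALSE])
  t$occlusion <- lapply(t$occlusion, function(o) o[idx])
  t
}

#' Zero-phase low-pass Butterworth filter
#'
#' Filters every axis of every marker with a Butterworth low-pass design
#' of the stated nominal order and cutoff, applied forward and backward
#' (zero phase, squared magnitude response). Edges are padded by odd
#' reflection of length three times the filter order and each pass starts
#' from the steady state of its first padded sample, so constant signals
#' pass through unchanged.
#'
#' @param t A [trajectory_set()] with no remaining occlusions.
#' @param cutoff Cutoff frequency in Hz (default 10).
#' @param order Filter order per pass (default 4).
#' @return The filtered trajectory set (same length).
#' @export
lowpass_filter <- function(t, cutoff = 10, order = 4) {
  stopifnot(inherits(t, "trajectory_set"))
  if (cutoff >= t$sampling_rate / 2)
    stop("cutoff (", cutoff, " Hz) must be below the Nyquist frequency (",
         t$sampling_rate / 2, " Hz)")
  if (any(vapply(t$occlusion, any, logical(1))))
    stop("trajectory set still contains occlusions; interpolate gaps first")
  filt <- signal::butter(order, cutoff / (t$sampling_rate / 2), "low")
  t$data <- lapply(t$data, function(d) {
    for (k in 1:3) d[, k] <- filtfilt_refl(filt$b, filt$a, d[, k], order)
    d
  })
  t
}

# one causal IIR pass starting from the steady state of the first sample
# (valid because the low-pass DC gain is 1); moving-average and recursive
# parts both run in C via stats::filter
iir_pass <- function(b, a, x) {
  nb <- length(b)
  xx <- c(rep(x[1], nb - 1), x)
  ma <- stats::filter(xx, b / a[1], sides = 1)[nb:(nb + length(x) - 1)]
  as.numeric(stats::filter(ma, -a[-1] / a[1], method = "recursive",
                           init = rep(x[1], length(a) - 1)))
}

# forward-backward filtering with odd-reflection edge padding; the pad
# spans several filter time constants so each pass settles before the
# retained samples (required for the zero-phase time-reversal symmetry)
filtfilt_refl <- function(b, a, x, order) {
  n <- length(x)
  np <- min(30L * order, n - 1L)
  front <- 2 * x[1] - x[seq(np + 1, 2)]
  back  <- 2 * x[n] - x[seq(n - 1, n - np)]
  xp <- c(front, x, back)
  y <- iir_pass(b, a, xp)
  y <- rev(iir_pass(b, a, rev(y)))
  y[(np + 1):(np + n)]
}

# first derivative on a uniform grid: central differences inside,
# second-order one-sided differences at the endpoints
gradient_1d <- function(x) {
  n <- length(x)
  g <- numeric(n)
  g[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / 2
  g[1] <- (-3 * x[1] + 4 * x[2] - x[3]) / 2
  g[n] <- (3 * x[n] - 4 * x[n - 1] + x[n - 2]) / 2
  g
}

#' Double differentiation to accelerations
#'
#' Applies a first-derivative operator twice (central differences at
#' interior frames, second-order one-sided differences at the endpoints,
#' step `1/sampling_rate`), converting positions in mm to accelerations
#' in mm/s^2. Output length equals input length; the scheme is exact for
#' quadratic trajectories.
#'
#' @param t A [trajectory_set()] in anatomical axes with at least 5
#'   frames and no occlusions.
#' @return An [acceleration_set()].
#' @export
differentiate_twice <- function(t) {
  stopifnot(inherits(t, "trajectory_set"))
  if (n_frames(t) < 5) stop("need at least 5 frames to differentiate twice")
  if (!identical(t$axis_names, c("ML", "AP", "VT")))
    stop("trajectory set must be in anatomical axes; run remap_axes first")
  if (any(vapply(t$occlusion, any, logical(1))))
    stop("cannot differentiate across occluded frames; interpolate first")
  fs <- t$sampling_rate
  acc <- lapply(t$data, function(d) {
    for (k in 1:3) d[, k] <- gradient_1d(gradient_1d(d[, k]) * fs) * fs
    d
  })
  acceleration_set(t$subject_id, t$condition, t$trial_index, fs, acc)
}

#' Preprocess one trial end to end
#'
#' Fixed pipeline order: gap interpolation, axis remapping, zero-phase
#' low-pass filtering of the whole trial, heel-strike based segmentation,
#' then double differentiation of the segmented window.
#'
#' @param t A raw [trajectory_set()].
#' @param events Optional curated [gait_events()]; if `NULL`, events are
#'   detected with [detect_heel_strikes()].
#' @param max_gap,cutoff,order,min_length_s See the stage functions.
#' @param definition A [marker_set_definition()] used to restrict to the
#'   21 canonical markers.
#' @return An [acceleration_set()] over the segmented window.
#' @export
preprocess_trial <- function(t, events = NULL, max_gap = 10, cutoff = 10,
                             order = 4, min_length_s = 0.5,
                             definition = marker_set_definition()) {
  t <- select_markers(t, definition)
  t <- interpolate_gaps(t, max_gap = max_gap)
  t <- remap_axes(t)
  t <- lowpass_filter(t, cutoff = cutoff, order = order)
  if (is.null(events)) events <- detect_heel_strikes(t)
  seg <- segment_trial(t, events, min_length_s = min_length_s)
  differentiate_twice(crop_segment(t, seg))
}
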