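# stride phase (radians) at which a heel strikes the ground in the
# synthetic waveform model: the downward zero-crossing of heel AP
# velocity v*(1 + 1.3*cos(theta)), i.e. acos(-1/1.3)
.THETA0 <- acos(-1 / 1.3)

#' Synthetic gait cohort configuration
#'
#' Parameters of the synthetic marker-trajectory generator. Each marker's
#' position per axis is a deterministic gait waveform (sinusoid at the
#' subject's stride frequency plus its first harmonic, with anatomically
#' motivated phase offsets: left and right limbs anti-phase, arms
#' anti-phase to the ipsilateral leg), plus a coupling-weighted shared
#' latent component for two body groups (trunk markers HE/C7/T10/LAC/RAC
#' on the ML axis; elbow/wrist/knee markers on the AP axis), plus white
#' measurement noise. The defaults emulate the study conditions: 23
#' subjects, two medication conditions (off/on), four trials per
#' condition of two consecutive gait cycles at 120 frames/s, with strong
#' trunk ML coupling in the off state relaxing in the on state and the
#' reverse pattern for limb AP coupling.
#'
#' @param n_subjects Number of subjects (default 23).
#' @param n_trials Trials per condition (default 4).
#' @param sampling_rate Frames per second (default 120).
#' @param stride_range Subject-level stride frequency range in Hz
#'   (default 0.8-1.1; drawn uniformly per subject).
#' @param n_cycles_per_trial Gait cycles per trial (default 2; one extra
#'   cycle of recording margin is added around them).
#' @param trunk_coupling Named vector `c(off=, on=)` in `[0,1]`: weight of
#'   the shared trunk component on the ML axis per condition.
#' @param limb_coupling Named vector `c(off=, on=)` in `[0,1]`: weight of
#'   the shared limb component on the AP axis per condition.
#' @param coupling_jitter_sd SD of the per-subject, per-condition,
#'   per-marker Gaussian jitter added to the coupling weight (clipped to
#'   `[0,1]`; default 0.15). This is the between-subject heterogeneity
#'   that the clinical regression feeds on.
#' @param noise_sd White measurement noise SD in mm (default 0.3,
#'   about 2% of a typical waveform amplitude).
#' @param shared_amp Amplitude scale of the shared latent component, mm
#'   at 1 Hz (each of its sinusoidal components contributes equal
#'   acceleration amplitude; default 10).
#' @param n_shared_components Sinusoids per shared latent (default 5).
#' @param shared_freq_range Frequency range of the shared latent in Hz
#'   (default 0.6-5).
#' @param progression_speed Forward walking speed in mm/s applied on the
#'   AP axis (default 1100).
#' @param private_scale Global multiplier on all private waveform
#'   amplitudes (default 1; 0 isolates the shared components).
#' @param private_amp_jitter SD of the per-subject log-normal amplitude
#'   jitter on private waveforms (default 0.1).
#' @param clinical_effect Named coefficient vector linking the true
#'   nodal-strength deltas (off - on) of designated nodes to the
#'   UPDRS-III change (default `c(RLELB = -1.0, LLELB = -0.8,
#'   RWRB = 0.9)`).
#' @param clinical_axis Axis of the designated nodes (default `"AP"`).
#' @param clinical_intercept Baseline UPDRS-III change in points added to
#'   the coefficient term (default 10), so score levels match a
#'   realistic levodopa response.
#' @param clinical_noise_sd SD of the Gaussian noise on the UPDRS-III
#'   change, in UPDRS points (default 0.8).
#' @param seed Integer seed; identical seed and config give a
#'   bit-identical cohort.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 23, n_trials = 4, sampling_rate = 120,
                          stride_range = c(0.8, 1.1),
                          n_cycles_per_trial = 2,
                          trunk_coupling = c(off = 0.9, on = 0.3),
                          limb_coupling = c(off = 0.3, on = 0.9),
                          coupling_jitter_sd = 0.15,
                          noise_sd = 0.3,
                          shared_amp = 10,
                          n_shared_components = 5,
                          shared_freq_range = c(0.6, 5),
                          progression_speed = 1100,
                          private_scale = 1,
                          private_amp_jitter = 0.1,
                          clinical_effect = c(RLELB = -1.0, LLELB = -0.8,
                                              RWRB = 0.9),
                          clinical_axis = "AP",
                          clinical_intercept = 10,
                          clinical_noise_sd = 0.8,
                          seed = 1L) {
  cfg <- list(n_subjects = n_subjects, n_trials = n_trials,
              sampling_rate = sampling_rate, stride_range = stride_range,
              n_cycles_per_trial = n_cycles_per_trial,
              trunk_coupling = trunk_coupling, limb_coupling = limb_coupling,
              coupling_jitter_sd = coupling_jitter_sd, noise_sd = noise_sd,
              shared_amp = shared_amp,
              n_shared_components = n_shared_components,
              shared_freq_range = shared_freq_range,
              progression_speed = progression_speed,
              private_scale = private_scale,
              private_amp_jitter = private_amp_jitter,
              clinical_effect = clinical_effect,
              clinical_axis = clinical_axis,
              clinical_intercept = clinical_intercept,
              clinical_noise_sd = clinical_noise_sd,
              seed = as.integer(seed))
  for (f in setdiff(names(cfg), c("clinical_axis"))) {
    v <- cfg[[f]]
    if (!is.numeric(v) || any(!is.finite(v)))
      stop("config field '", f, "' must be finite numeric")
  }
  for (f in c("trunk_coupling", "limb_coupling")) {
    v <- cfg[[f]]
    if (!all(c("off", "on") %in% names(v)))
      stop("config field '", f, "' must be named c(off=, on=)")
    if (any(v < 0) || any(v > 1))
      stop("config field '", f, "' must lie in [0, 1]")
  }
  if (sampling_rate <= 0) stop("config field 'sampling_rate' must be positive")
  if (n_cycles_per_trial < 1)
    stop("config field 'n_cycles_per_trial' must be at least 1")
  if (n_subjects < 1) stop("config field 'n_subjects' must be at least 1")
  if (noise_sd < 0) stop("config field 'noise_sd' must be non-negative")
  if (is.null(names(clinical_effect)) ||
      !all(names(clinical_effect) %in% kinectome_markers()))
    stop("config field 'clinical_effect' must be named by canonical markers")
  structure(cfg, class = "cohort_config")
}

clip01 <- function(x) pmin(1, pmax(0, x))

# private waveform components for one marker/axis: data.frame(mult, amp,
# phase) where mult multiplies the stride frequency and phase is in
# stride-phase radians. v = progression speed, f = stride frequency.
private_components <- function(marker, axis, f, v) {
  th <- .THETA0
  left <- substr(marker, 1, 1) == "L" && marker != "LAC"
  side <- if (left) 0 else pi  # midline markers use 0
  comp <- function(mult, amp, phase, jit = TRUE)
    data.frame(mult = mult, amp = amp, phase = phase, jit = jit)
  # stride-locked amplitude: fixed by speed and cadence, so exempt from
  # anatomical amplitude jitter (keeps the heel AP velocity zero-crossing
  # phase-locked to the planted heel-strike phase)
  stride_amp <- function(fac) fac * v / (2 * pi * f)
  trunk <- c(HE = 0, C7 = 0.1, T10 = -0.1, LAC = 0.2, RAC = -0.2)
  if (axis == "ML") {
    if (marker %in% names(trunk)) return(comp(1, 2.5, trunk[[marker]]))
    switch(sub("^[LR]", "", marker),
      "LELB" = comp(1, 6, if (left) pi / 2 else -pi / 2),
      "WRB"  = comp(1, 7, if (left) pi / 2 + 0.1 else -pi / 2 - 0.1),
      "IC"   = comp(2, 8, if (left) 0.30 else 0.35),
      "GT"   = comp(2, 7, if (left) 0.50 else 0.55),
      "LK"   = comp(2, 5, side),
      "LA"   = comp(2, 5, 0.2 + side),
      "HEEL" = comp(2, 4, 0.4 + side),
      "FT5"  = comp(2, 4, 0.6 + side))
  } else if (axis == "AP") {
    if (marker %in% names(trunk)) return(comp(2, 6, 1.0 + trunk[[marker]] / 2))
    switch(sub("^[LR]", "", marker),
      "LELB" = comp(1, 5, side + pi),
      "WRB"  = comp(1, 6, side + pi + 0.15),
      "IC"   = comp(2, 5, 1.3),
      "GT"   = comp(2, 5, 1.4),
      "LK"   = comp(1, 5, side),
      "LA"   = comp(1, stride_amp(1.20), side + 0.05, jit = FALSE),
      "HEEL" = comp(1, stride_amp(1.30), side, jit = FALSE),
      "FT5"  = comp(1, stride_amp(1.35), side - 0.1, jit = FALSE))
  } else {  # VT
    if (marker %in% names(trunk)) return(comp(2, 15, -0.5 + trunk[[marker]]))
    switch(sub("^[LR]", "", marker),
      "LELB" = comp(1, 8, side + pi),
      "WRB"  = comp(1, 10, side + pi + 0.2),
      "IC"   = comp(2, 12, -0.2),
      "GT"   = comp(2, 12, -0.1),
      "LK"   = comp(1, 25, side + 2.0),
      "LA"   = comp(1, 30, side + 2.3),
      "HEEL" = comp(1, 30, side - th - pi / 2),
      "FT5"  = comp(1, 15, side - th - 0.9 - pi / 2))
  }
}

#' Generate a synthetic gait cohort
#'
#' Simulates the full study design: `n_subjects` subjects, each recorded
#' in the off and on conditions with `n_trials` trials per condition.
#' Marker positions follow the waveform model of [cohort_config()];
#' ground-truth nodal strengths are computed analytically from the
#' noise-free acceleration signals, and the per-subject UPDRS-III change
#' is generated from the true strength deltas of the designated nodes.
#'
#' @param config A [cohort_config()].
#' @param include_trajectories If `FALSE`, skip materialising the noisy
#'   position time series (ground truth and clinical table only); useful
#'   for large replicate studies that operate on true strengths.
#' @return An object of class `kinectome_cohort`: `config`,
#'   `trajectories` (nested list `[[subject]][[condition]][[trial]]` of
#'   [trajectory_set()]s, axes labelled X/Y/Z with the stored convention
#'   ML=X, AP=Y, VT=Z), `clinical` (data frame with `subject_id`, `age`,
#'   `gender`, `education_years`, `disease_duration_months`, `updrs_off`,
#'   `updrs_on`), and `ground_truth` (`couplings`, trial-averaged
#'   `true_strengths` in [strength_table()] format, `true_deltas`,
#'   `clinical_effect`, `clinical_axis`).
#' @export
generate_cohort <- function(config = cohort_config(),
                            include_trajectories = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  # measurement noise lives on its own derived sub-stream so that the
  # structural randomness (and hence ground truth and clinical table) is
  # identical whether or not trajectories are materialised
  noise_base <- sample.int(2^31 - 10000L, 1)
  trial_counter <- 0L
  fs <- config$sampling_rate
  markers <- kinectome_markers()
  axes <- c("ML", "AP", "VT")
  conditions <- c("off", "on")
  groups <- list(trunk = list(markers = trunk_group(), axis = "ML",
                              weights = config$trunk_coupling),
                 limb = list(markers = limb_group(), axis = "AP",
                             weights = config$limb_coupling))
  subject_ids <- sprintf("S%02d", seq_len(config$n_subjects))

  trajectories <- if (include_trajectories)
    stats::setNames(vector("list", config$n_subjects), subject_ids) else NULL
  coup_rows <- list()
  true_rows <- list()

  for (si in seq_along(subject_ids)) {
    sid <- subject_ids[si]
    f <- stats::runif(1, config$stride_range[1], config$stride_range[2])
    n <- round(fs * (config$n_cycles_per_trial + 1) / f)
    tt <- (seq_len(n) - 1) / fs
    # per-subject anatomical amplitude jitter, shared across conditions
    amp_jit <- matrix(exp(stats::rnorm(length(markers) * 3, 0,
                                       config$private_amp_jitter)),
                      length(markers), 3,
                      dimnames = list(markers, axes))
    # private waveforms are trial-invariant: evaluate once per subject
    pos_priv <- lapply(axes, function(a) matrix(0, n, length(markers),
                                                dimnames = list(NULL, markers)))
    names(pos_priv) <- axes
    acc_priv <- pos_priv
    for (m in markers) {
      for (a in axes) {
        pc <- private_components(m, a, f, config$progression_speed)
        pc$amp <- pc$amp * config$private_scale *
          ifelse(pc$jit, amp_jit[m, a], 1)
        pos <- numeric(n); acc <- numeric(n)
        for (k in seq_len(nrow(pc))) {
          s <- sin(2 * pi * pc$mult[k] * f * tt + pc$phase[k])
          pos <- pos + pc$amp[k] * s
          acc <- acc - pc$amp[k] * (2 * pi * pc$mult[k] * f)^2 * s
        }
        if (a == "AP") pos <- pos + config$progression_speed * tt
        pos_priv[[a]][, m] <- pos
        acc_priv[[a]][, m] <- acc
      }
    }

    if (include_trajectories) trajectories[[sid]] <- list()
    for (cond in conditions) {
      # per-marker coupling weights for this subject and condition
      w <- list()
      for (g in names(groups)) {
        gm <- groups[[g]]$markers
        w[[g]] <- stats::setNames(
          clip01(groups[[g]]$weights[[cond]] +
                   stats::rnorm(length(gm), 0, config$coupling_jitter_sd)),
          gm)
        coup_rows[[length(coup_rows) + 1L]] <- data.frame(
          subject = sid, condition = cond, group = g, marker = gm,
          weight = unname(w[[g]]), stringsAsFactors = FALSE)
      }
      trial_strengths <- vector("list", config$n_trials)
      if (include_trajectories) trajectories[[sid]][[cond]] <- list()
      for (tr in seq_len(config$n_trials)) {
        # shared latent components, one per coupled (group, axis)
        latent_pos <- list(); latent_acc <- list()
        for (g in names(groups)) {
          gf <- stats::runif(config$n_shared_components,
                             config$shared_freq_range[1],
                             config$shared_freq_range[2])
          gp <- stats::runif(config$n_shared_components, 0, 2 * pi)
          pos <- numeric(n); acc <- numeric(n)
          for (k in seq_along(gf)) {
            s <- sin(2 * pi * gf[k] * tt + gp[k])
            a_k <- config$shared_amp / gf[k]^2  # equal acceleration weight
            pos <- pos + a_k * s
            acc <- acc - a_k * (2 * pi * gf[k])^2 * s
          }
          latent_pos[[g]] <- pos; latent_acc[[g]] <- acc
        }
        pos_ax <- pos_priv
        acc_ax <- acc_priv
        for (g in names(groups)) {
          a <- groups[[g]]$axis
          gm <- groups[[g]]$markers
          pos_ax[[a]][, gm] <- pos_ax[[a]][, gm] +
            tcrossprod(latent_pos[[g]], w[[g]])
          acc_ax[[a]][, gm] <- acc_ax[[a]][, gm] +
            tcrossprod(latent_acc[[g]], w[[g]])
        }
        # true nodal strengths from the noise-free accelerations; a
        # degenerate all-zero series (private_scale = 0 diagnostics)
        # contributes no strength
        S_true <- lapply(axes, function(a) {
          W <- suppressWarnings(stats::cor(acc_ax[[a]]))
          W[!is.finite(W)] <- 0
          diag(W) <- 0
          rowSums(abs(W))
        })
        names(S_true) <- axes
        trial_strengths[[tr]] <- S_true
        trial_counter <- trial_counter + 1L
        if (include_trajectories) {
          noise <- with_local_seed(noise_base + trial_counter,
            matrix(stats::rnorm(n * length(markers) * 3, 0,
                                config$noise_sd), n))
          data <- list()
          for (mi in seq_along(markers)) {
            m <- markers[mi]
            data[[m]] <- cbind(pos_ax$ML[, m] + noise[, 3 * mi - 2],
                               pos_ax$AP[, m] + noise[, 3 * mi - 1],
                               pos_ax$VT[, m] + noise[, 3 * mi])
          }
          trajectories[[sid]][[cond]][[tr]] <- trajectory_set(
            sid, cond, tr, fs, data,
            axis_names = c("X", "Y", "Z"),
            axis_convention = c(ML = "X", AP = "Y", VT = "Z"))
        }
      }
      # trial-averaged true strengths
      for (a in axes) {
        S_bar <- Reduce(`+`, lapply(trial_strengths, `[[`, a)) /
          config$n_trials
        true_rows[[length(true_rows) + 1L]] <- data.frame(
          subject = sid, condition = cond, axis = a, node = markers,
          strength = unname(S_bar), n_trials = config$n_trials,
          stringsAsFactors = FALSE)
      }
    }
  }

  true_strengths <- do.call(rbind, true_rows)
  couplings <- do.call(rbind, coup_rows)

  # clinical table: UPDRS change generated from the true strength deltas
  eff <- config$clinical_effect
  deltas <- sapply(names(eff), function(nd) {
    s <- true_strengths[true_strengths$axis == config$clinical_axis &
                          true_strengths$node == nd, ]
    off <- s$strength[s$condition == "off"][
      match(subject_ids, s$subject[s$condition == "off"])]
    on <- s$strength[s$condition == "on"][
      match(subject_ids, s$subject[s$condition == "on"])]
    off - on
  })
  deltas <- matrix(deltas, ncol = length(eff),
                   dimnames = list(subject_ids, names(eff)))
  delta_updrs <- config$clinical_intercept +
    as.numeric(deltas %*% eff) +
    stats::rnorm(config$n_subjects, 0, config$clinical_noise_sd)
  updrs_on <- pmax(0, stats::rnorm(config$n_subjects, 17, 8))
  updrs_off <- updrs_on + delta_updrs
  shift <- pmax(0, -updrs_off)  # keep both scores non-negative, delta intact
  updrs_off <- updrs_off + shift
  updrs_on <- updrs_on + shift
  clinical <- data.frame(
    subject_id = subject_ids,
    age = round(pmin(88, pmax(45, stats::rnorm(config$n_subjects, 65.3, 11.58)))),
    gender = stats::rbinom(config$n_subjects, 1, 17 / 23),
    education_years = round(pmin(20, pmax(3, stats::rnorm(config$n_subjects,
                                                          10.73, 3.84)))),
    disease_duration_months = round(pmin(119, pmax(6, stats::rnorm(
      config$n_subjects, 81.78, 49.92)))),
    updrs_off = updrs_off, updrs_on = updrs_on,
    stringsAsFactors = FALSE)

  structure(list(config = config, trajectories = trajectories,
                 clinical = clinical,
                 ground_truth = list(couplings = couplings,
                                     true_strengths = true_strengths,
                                     true_deltas = deltas,
                                     clinical_effect = eff,
                                     clinical_axis = config$clinical_axis)),
            class = "kinectome_cohort")
}

#' @export
print.kinectome_cohort <- function(x, ...) {
  cat(sprintf(
    "<kinectome_cohort> %d subjects x 2 conditions x %d trials (seed %d)%s\n",
    x$config$n_subjects, x$config$n_trials, x$config$seed,
    if (is.null(x$trajectories)) " [ground truth only]" else ""))
  invisible(x)
}

#' Write a cohort to disk as a fixture
#'
#' Serialises every trial in the tabular trajectory dialect plus the
#' clinical covariate table, and writes a manifest listing every file
#' with its MD5 checksum.
#'
#' @param cohort A `kinectome_cohort` with trajectories.
#' @param destination Directory (created if needed).
#' @return Invisibly, the manifest data frame (`file`, `md5`).
#' @export
write_fixture <- function(cohort, destination) {
  stopifnot(inherits(cohort, "kinectome_cohort"))
  if (is.null(cohort$trajectories))
    stop("cohort was generated without trajectories")
  dir.create(destination, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(destination)) stop("cannot create directory: ", destination)
  files <- character(0)
  for (sid in names(cohort$trajectories)) {
    for (cond in names(cohort$trajectories[[sid]])) {
      for (tr in seq_along(cohort$trajectories[[sid]][[cond]])) {
        fn <- sprintf("%s_%s_trial%d.csv", sid, cond, tr)
        write_trajectories(cohort$trajectories[[sid]][[cond]][[tr]],
                           file.path(destination, fn))
        files <- c(files, fn, sub("\\.csv$", ".yaml", fn))
      }
    }
  }
  utils::write.csv(cohort$clinical, file.path(destination, "clinical.csv"),
                   row.names = FALSE)
  files <- c(files, "clinical.csv")
  md5 <- tools::md5sum(file.path(destination, files))
  manifest <- data.frame(file = files, md5 = unname(md5),
                         stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(destination, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Verify a fixture against its manifest
#'
#' @param destination Fixture directory written by [write_fixture()].
#' @return `TRUE` if all checksums match; otherwise stops, naming the
#'   first mismatching file.
#' @export
verify_fixture <- function(destination) {
  manifest <- utils::read.csv(file.path(destination, "manifest.csv"),
                              stringsAsFactors = FALSE)
  md5 <- unname(tools::md5sum(file.path(destination, manifest$file)))
  bad <- which(is.na(md5) | md5 != manifest$md5)
  if (length(bad))
    stop("fixture checksum mismatch: ",
         paste(manifest$file[bad], collapse = ", "))
  TRUE
}

#' Read a cohort fixture from disk
#'
#' @param source Directory written by [write_fixture()].
#' @return A list with `trajectories` (nested subject/condition/trial)
#'   and `clinical`.
#' @export
read_cohort_fixture <- function(source) {
  manifest <- utils::read.csv(file.path(source, "manifest.csv"),
                              stringsAsFactors = FALSE)
  traj_files <- grep("_trial[0-9]+\\.csv$", manifest$file, value = TRUE)
  trajectories <- list()
  for (fn in traj_files) {
    t <- read_trajectories(file.path(source, fn))
    trajectories[[t$subject_id]][[t$condition]][[t$trial_index]] <- t
  }
  clinical <- utils::read.csv(file.path(source, "clinical.csv"),
                              stringsAsFactors = FALSE)
  list(trajectories = trajectories, clinical = clinical)
}
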