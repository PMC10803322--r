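ts_from <- function(mats, fs = 120, axes = c("ML", "AP", "VT"),
                    occ = NULL) {
  trajectory_set("S01", "off", 1L, fs, mats, occlusion = occ,
                 axis_names = axes)
}

one_marker <- function(x, y = NULL, z = NULL, fs = 120, label = "M1", ...) {
  n <- length(x)
  if (is.null(y)) y <- seq_len(n) / 10
  if (is.null(z)) z <- rev(seq_len(n)) / 10
  ts_from(stats::setNames(list(cbind(x, y, z, deparse.level = 0)), label),
          fs = fs, ...)
}

test_that("short gaps are spline-filled exactly on smooth signals", {
  n <- 100
  ramp <- 3 * seq_len(n) + 2          # linear
  cubic <- (seq_len(n) / 20)^3 - seq_len(n)  # cubic
  occ <- rep(FALSE, n); occ[41:43] <- TRUE
  t <- ts_from(list(M1 = cbind(ramp, cubic, ramp + 1)),
               occ = list(M1 = occ))
  t$data$M1[occ, ] <- 0
  out <- interpolate_gaps(t)
  expect_false(any(out$occlusion$M1))
  expect_lt(max(abs(out$data$M1[, 1] - ramp)), 1e-9)
  expect_lt(max(abs(out$data$M1[, 2] - cubic)), 1e-9)
})

test_that("gap policy rejects long and boundary gaps, passes clean input", {
  n <- 100
  x <- sin(seq_len(n) / 5)
  long_occ <- rep(FALSE, n); long_occ[20:30] <- TRUE  # 11 frames
  t <- one_marker(x, occ = list(M1 = long_occ))
  expect_error(interpolate_gaps(t), "max_gap")
  expect_error(interpolate_gaps(t), "M1")
  edge_occ <- rep(FALSE, n); edge_occ[1:2] <- TRUE
  t2 <- one_marker(x, occ = list(M1 = edge_occ))
  expect_error(interpolate_gaps(t2), "boundary")
  t3 <- one_marker(x)
  expect_identical(interpolate_gaps(t3), t3)
})

test_that("zero-phase filter: DC exact, passband preserved, stopband crushed", {
  fs <- 120
  n <- 1200
  tt <- (seq_len(n) - 1) / fs
  # constant unchanged
  t_const <- one_marker(rep(7, n))
  out <- lowpass_filter(t_const)
  expect_lt(max(abs(out$data$M1[, 1] - 7)), 1e-9)
  # 1 Hz tone: amplitude within 1%, zero lag
  tone <- sin(2 * pi * 1 * tt)
  out1 <- lowpass_filter(one_marker(tone))$data$M1[, 1]
  mid <- 200:1000
  expect_lt(abs(max(out1[mid]) - 1), 0.01)
  cc <- stats::ccf(out1[mid], tone[mid], lag.max = 5, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  # 30 Hz tone: attenuation beyond 40 dB (4th order, two passes)
  tone30 <- sin(2 * pi * 30 * tt)
  out30 <- lowpass_filter(one_marker(tone30))$data$M1[, 1]
  atten_db <- 20 * log10(max(abs(out30[mid])) / 1)
  expect_lt(atten_db, -40)
})

test_that("filtering commutes with time reversal (zero-phase contract)", {
  withr::local_seed(7)
  n <- 600
  x <- cumsum(rnorm(n)) + 5 * sin(seq_len(n) / 9)
  fwd <- lowpass_filter(one_marker(x))$data$M1[, 1]
  rev_in <- lowpass_filter(one_marker(rev(x)))$data$M1[, 1]
  expect_lt(max(abs(rev(rev_in) - fwd)), 1e-6 * diff(range(x)))
})

test_that("filter configuration errors are caught", {
  t <- one_marker(sin(1:100))
  expect_error(lowpass_filter(t, cutoff = 60), "Nyquist")
  occ <- rep(FALSE, 100); occ[5] <- TRUE
  t2 <- one_marker(sin(1:100), occ = list(M1 = occ))
  expect_error(lowpass_filter(t2), "occlusion")
})

test_that("double differentiation is exact for quadratics and accurate for tones", {
  fs <- 120
  tt <- (0:599) / fs
  # p(t) = t^2 -> a = 2 everywhere (exact, including endpoints)
  t_quad <- one_marker(tt^2)
  a <- differentiate_twice(t_quad)$data$M1[, 1]
  expect_lt(max(abs(a - 2)), 1e-6)
  # linear ramp -> zero acceleration
  a_lin <- differentiate_twice(one_marker(5 * tt + 3))$data$M1[, 1]
  expect_lt(max(abs(a_lin)), 1e-9)
  # sinusoid: matches -(2*pi)^2 sin within 0.1% of amplitude (interior)
  x <- sin(2 * pi * tt)
  a_sin <- differentiate_twice(one_marker(x))$data$M1[, 1]
  truth <- -(2 * pi)^2 * sin(2 * pi * tt)
  interior <- 3:597
  expect_lt(max(abs(a_sin[interior] - truth[interior])),
            0.001 * (2 * pi)^2)
  expect_error(differentiate_twice(one_marker(c(1, 2, 3, 4))), "5 frames")
})

test_that("heel strikes are recovered at planted frames", {
  fs <- 120
  n <- 480
  tt <- (seq_len(n) - 1) / fs
  f <- 1  # one strike per second per side
  th <- 2 * pi * f * tt
  plant <- function(phase) {
    ap <- 1100 * tt + 1.3 * 1100 / (2 * pi * f) * sin(th + phase)
    vt <- -30 * cos(th + phase - acos(-1 / 1.3)) + 50
    ml <- 5 * sin(th / 2 + phase)
    cbind(ml, ap, vt, deparse.level = 0)
  }
  mats <- list(LHEEL = plant(0), RHEEL = plant(pi))
  t <- ts_from(mats, fs = fs)
  ev <- detect_heel_strikes(t)
  expect_identical(ev$source, "detected")
  # expected strike frames: theta + phase = acos(-1/1.3) (mod 2pi)
  th0 <- acos(-1 / 1.3)
  expect_left <- round((th0 + 2 * pi * (0:3)) / (2 * pi * f) * fs) + 1
  expect_right <- round((th0 + pi + 2 * pi * (0:3)) / (2 * pi * f) * fs) + 1
  expect_left <- expect_left[expect_left <= n - 1]
  expect_right <- expect_right[expect_right <= n - 1]
  expect_equal(length(ev$left), length(expect_left))
  expect_true(all(abs(ev$left - expect_left) <= 1))
  expect_true(all(abs(ev$right - expect_right) <= 1))
})

test_that("constant trajectories yield a detection error; files bypass detection", {
  n <- 240
  mats <- list(LHEEL = matrix(1, n, 3), RHEEL = matrix(2, n, 3))
  t <- ts_from(mats)
  expect_error(detect_heel_strikes(t), "no heel-strike candidates")
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("side,frame", "left,60", "left,180", "right,120", "right,240"), f)
  ev <- read_gait_events(f)
  expect_identical(ev$source, "provided")
  expect_equal(ev$left, c(60L, 180L))
})

test_that("segmentation follows the leading-foot rule", {
  t <- one_marker(sin((1:400) / 20))
  ev <- gait_events(left = c(100, 220), right = c(160, 280))
  seg <- segment_trial(t, ev, leading = "left")
  expect_equal(seg$start_frame, 100L)
  expect_equal(seg$end_frame, 280L)
  # leading side defaults to the earliest strike
  seg2 <- segment_trial(t, ev)
  expect_equal(seg2$start_frame, 100L)
  # forced right lead
  ev3 <- gait_events(left = c(110, 230), right = c(50, 170))
  seg3 <- segment_trial(t, ev3, leading = "right")
  expect_equal(seg3$start_frame, 50L)
  expect_equal(seg3$end_frame, 230L)
  # one contralateral strike only -> error
  ev4 <- gait_events(left = 100, right = 160)
  expect_error(segment_trial(t, ev4, leading = "left"), "contralateral")
  # cropping honours [start, end)
  cropped <- crop_segment(t, seg)
  expect_equal(kinectome:::n_frames(cropped), 180)
  expect_equal(cropped$data$M1[1, 1], t$data$M1[100, 1])
})

test_that("filtering before differentiation suppresses high-frequency acceleration noise", {
  withr::local_seed(11)
  fs <- 120
  n <- 600
  tt <- (seq_len(n) - 1) / fs
  x <- 30 * sin(2 * pi * tt) + rnorm(n, 0, 0.5)
  raw_acc <- differentiate_twice(one_marker(x))$data$M1[, 1]
  filt_acc <- differentiate_twice(lowpass_filter(one_marker(x)))$data$M1[, 1]
  expect_lt(stats::var(filt_acc) / stats::var(raw_acc), 1)
})

test_that("marker selection commutes with segmentation and differentiation", {
  coh <- generate_cohort(cohort_config(n_subjects = 1, n_trials = 1, seed = 21))
  raw <- coh$trajectories[[1]][["off"]][[1]]
  def <- marker_set_definition()
  ev <- detect_heel_strikes(lowpass_filter(remap_axes(select_markers(raw, def))))
  path_a <- differentiate_twice(crop_segment(
    lowpass_filter(remap_axes(select_markers(raw, def))),
    segment_trial(raw, ev)))
  full <- lowpass_filter(remap_axes(raw))
  path_b_ts <- crop_segment(full, segment_trial(raw, ev))
  path_b <- select_markers(differentiate_twice(path_b_ts), def)
  expect_equal(path_a$data, path_b$data, tolerance = 1e-9)
})
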