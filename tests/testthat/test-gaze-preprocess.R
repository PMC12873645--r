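make_trace <- function(pitch, fs = 120, valid = TRUE) {
  gaze_trace(t = seq_along(pitch) / fs, pitch = pitch, valid = valid,
             sample_rate = fs)
}

test_that("filtering preserves DC and removes singleton spikes", {
  tr <- make_trace(rep(5, 60))
  out <- filter_trace(tr)
  expect_equal(out$pitch, rep(5, 60), tolerance = 1e-9)
  spiky <- rep(2, 61)
  spiky[31] <- 12
  med_only <- stats::runmed(spiky, 3, endrule = "keep")
  expect_true(all(med_only == 2))
  out2 <- filter_trace(make_trace(spiky))
  expect_lt(max(abs(out2$pitch - 2)), 0.05)
})

test_that("a 30 Hz sinusoid at 120 Hz sampling is attenuated below half", {
  t <- seq(0, 2, by = 1 / 120)
  x <- sin(2 * pi * 30 * t)
  out <- filter_trace(gaze_trace(t + 1e-9 * 0, x + 10, sample_rate = 120))
  core <- out$pitch[30:(length(t) - 30)] - 10
  expect_lt(max(abs(core)), 0.5)
})

test_that("invalid samples are excluded from filtering and stay flagged", {
  pitch <- c(rep(1, 30), rep(NA, 5), rep(3, 30))
  valid <- !is.na(pitch)
  pitch[!valid] <- 99
  out <- filter_trace(make_trace(pitch, valid = valid))
  expect_identical(out$valid, valid)
  expect_equal(out$pitch[31:35], rep(99, 5))   # untouched
  expect_lt(max(abs(out$pitch[1:29] - 1)), 1e-6)
  expect_lt(max(abs(out$pitch[38:60] - 3)), 1e-6)
})

test_that("filtering rejects sampling below the Nyquist requirement", {
  expect_error(filter_trace(make_trace(rnorm(50), fs = 25)), "cutoff")
})

test_that("filtering is idempotent on band-limited signals", {
  # monotone drift with a slow modulation far below the cutoff; the
  # median stage is exactly idempotent on monotone signals and the
  # Butterworth response is flat to ~1e-8 at these frequencies
  t <- seq(0, 3, by = 1 / 120)
  x <- 10 + 0.3 * t + 0.05 * sin(2 * pi * 0.3 * t)
  once <- filter_trace(gaze_trace(t, x, sample_rate = 120))
  twice <- filter_trace(once)
  core <- 40:(length(t) - 40)             # away from edge transients
  expect_lt(max(abs(twice$pitch[core] - once$pitch[core])), 1e-6)
})

test_that("dispersion fixation detection matches its specification", {
  fs <- 100
  # constant 200 ms trace: one fixation spanning it
  fx <- detect_fixations(make_trace(rep(1, 21), fs = fs))
  expect_equal(nrow(fx), 1)
  expect_equal(fx$t_start, 1 / fs)
  expect_equal(fx$t_end, 21 / fs)
  expect_equal(fx$mean_pitch, 1)
  # two 150 ms plateaus separated by a fast 5-degree saccade: exactly two
  p <- c(rep(0, 16), 2.5, rep(5, 16))
  fx2 <- detect_fixations(make_trace(p, fs = fs))
  expect_equal(nrow(fx2), 2)
  expect_lt(fx2$mean_pitch[1], 0.2)
  expect_gt(fx2$mean_pitch[2], 4.8)
  # a fast ramp never stays within the dispersion long enough
  ramp <- seq(0, 40, length.out = 101)    # 40 deg/s
  expect_equal(nrow(detect_fixations(make_trace(ramp, fs = fs))), 0)
})

test_that("fixation detection equals the brute-force window scan", {
  for (s in 1:25) {
    set.seed(s)
    n <- sample(50:500, 1)
    fs <- 100
    # piecewise-constant plateaus plus noise emulate fixations/saccades
    p <- rep(cumsum(rnorm(8, 0, 4)), length.out = n)[
      rep(seq_len(8), times = diff(floor(seq(0, n, length.out = 9))))]
    p <- p + rnorm(n, 0, 0.5)
    valid <- runif(n) > 0.05
    tr <- gaze_trace(seq_len(n) / fs, p, valid, sample_rate = fs)
    got <- detect_fixations(tr)
    want <- brute_force_fixations(tr$t, tr$pitch, tr$valid)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got)) {
      expect_equal(got$t_start, want$t_start, tolerance = 1e-12)
      expect_equal(got$t_end, want$t_end, tolerance = 1e-12)
      expect_equal(got$mean_pitch, want$mean_pitch, tolerance = 1e-12)
    }
  }
})

test_that("pitch at bounce uses closed intervals and flags misses", {
  fx <- tibble::tibble(t_start = c(0.1, 0.5), t_end = c(0.3, 0.8),
                       duration = c(0.2, 0.3), mean_pitch = c(4, 9))
  expect_equal(pitch_at_bounce(fx, 0.2), 4)
  expect_equal(pitch_at_bounce(fx, 0.3), 4)   # end boundary inclusive
  expect_equal(pitch_at_bounce(fx, 0.5), 9)   # start boundary inclusive
  expect_true(is.na(pitch_at_bounce(fx, 0.4)))
})

test_that("quality control applies the trial, outlier and participant rules", {
  clean <- tibble::tibble(pitch = rnorm(100, 10, 2), prop_missing = 0,
                          max_gap = 0)
  qc <- apply_qc(clean)
  expect_false(any(qc$excluded))
  expect_false(attr(qc, "participant_excluded"))

  set.seed(1)
  pitch <- rnorm(100)
  pitch[50] <- mean(pitch[-50]) + 5 * sd(pitch[-50])
  qc2 <- apply_qc(tibble::tibble(pitch = pitch, prop_missing = 0, max_gap = 0))
  expect_true(qc2$outlier[50])
  expect_equal(qc2$reason[50], "outlier>3.29SD")
  expect_equal(sum(qc2$outlier), 1)

  # per-trial exclusion reasons
  tr <- tibble::tibble(pitch = c(rnorm(8), NA, rnorm(1)),
                       prop_missing = c(0.5, rep(0, 9)),
                       max_gap = c(0, 0.2, rep(0, 8)))
  qc3 <- apply_qc(tr)
  expect_true(qc3$excluded[1])
  expect_equal(qc3$reason[1], "missing>20%")
  expect_true(qc3$excluded[2])
  expect_equal(qc3$reason[2], "gap>100ms")
  expect_true(qc3$excluded[9])

  # participant flag at > 15% bad trials (16 of 100)
  tr4 <- tibble::tibble(pitch = c(rep(NA, 16), rnorm(84)),
                        prop_missing = 0, max_gap = 0)
  qc4 <- apply_qc(tr4)
  expect_true(attr(qc4, "participant_excluded"))
  # 15 of 100 stays in
  tr5 <- tibble::tibble(pitch = c(rep(NA, 15), rnorm(85)),
                        prop_missing = 0, max_gap = 0)
  expect_false(attr(apply_qc(tr5), "participant_excluded"))

  # all-missing series excludes the participant outright
  qc6 <- apply_qc(tibble::tibble(pitch = rep(NA_real_, 10)))
  expect_true(attr(qc6, "participant_excluded"))
  expect_match(attr(qc6, "participant_reason"), "missing")
})

test_that("dichotomization thresholds shifts and carries forward", {
  # suprathreshold shifts separated by holds alternate the response
  # (holds keep the SD of the changes below the shift size)
  p <- rep(c(0, 10, 10, 0), 5)
  y <- dichotomize(p)$y
  expect_equal(y, rep(c(0, 1, 1, 0), 5))
  # sub-threshold wobble carries the previous response forward
  p2 <- c(0, 10, 10.01, 10.02, 0.5, 0.4)
  y2 <- dichotomize(p2)$y
  expect_equal(y2, c(0, 1, 1, 1, 0, 0))
  # shift invariance
  expect_equal(dichotomize(p2 + 57)$y, y2)
  # constant series has no defined threshold
  expect_error(dichotomize(rep(3, 10)), "zero variance")
})

test_that("noise-free gaze from a single belief reversal dichotomizes to one
          transition", {
  des <- generate_design(task_config(n_sessions = 1, trials_per_session = 60,
                                     switches_per_session = 1,
                                     block_len_range = c(30, 30), seed = 2,
                                     p_consistent = 1))
  # a crisp switching belief: context network in its demonstration regime
  net <- do.call(build_network, c(list("context"), context_demo_params()))
  traj <- run_forward(net, des)
  g <- generate_gaze(des, traj, gain = 20, baseline = 10, noise_sd = 0)
  # score shifts per colour stream to avoid colour-driven alternation
  green <- des$ball_color == "green"
  yg <- dichotomize(g$pitch[green])$y
  expect_equal(sum(abs(diff(yg))), 1)
  expect_equal(unique(yg[des$true_state[green] == 1]),
               unique(1 - yg[des$true_state[green] == 0]))
})

test_that("gaze traces round-trip through CSV", {
  tr <- make_trace(rnorm(30))
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::as_tibble(tr), path)
  back <- read_gaze_trace(path, sample_rate = 120)
  expect_equal(back$pitch, tr$pitch)
  expect_equal(attr(back, "sample_rate"), 120)
})
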