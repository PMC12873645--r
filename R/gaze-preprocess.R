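# Turning raw gaze traces into per-trial gaze pitch angles and binary
# responses: median + zero-phase Butterworth smoothing, dispersion-based
# fixation detection, quality control, and dichotomization of
# trial-to-trial shifts. Angles are in degrees, pitch positive upward;
# all intervals are closed at both ends unless noted.

#' Construct a gaze trace
#'
#' @param t Sample times in seconds, strictly increasing.
#' @param pitch Gaze-head pitch angle in degrees per sample.
#' @param valid Logical per sample: tracking present (default all).
#' @param sample_rate Sampling rate in Hz; inferred from the median time
#'   step when omitted.
#' @return A `gaze_trace` tibble (`t`, `pitch`, `valid`) with the rate in
#'   attribute `"sample_rate"`.
#' @export
gaze_trace <- function(t, pitch, valid = TRUE, sample_rate = NULL) {
  stopifnot(length(t) == length(pitch), all(diff(t) > 0))
  valid <- rep_len(valid, length(t))
  if (is.null(sample_rate)) sample_rate <- 1 / median(diff(t))
  stopifnot(sample_rate > 0)
  out <- tibble::tibble(t = t, pitch = pitch, valid = valid)
  attr(out, "sample_rate") <- sample_rate
  class(out) <- c("gaze_trace", class(out))
  out
}

#' Read a gaze trace from CSV (columns `t`, `pitch`, `valid`)
#'
#' @param path CSV path.
#' @inheritParams gaze_trace
#' @export
read_gaze_trace <- function(path, sample_rate = NULL) {
  df <- readr::read_csv(path, col_types = readr::cols(
    t = "d", pitch = "d", valid = "l"
  ))
  gaze_trace(df$t, df$pitch, df$valid, sample_rate)
}

#' Smooth a gaze trace (median then zero-phase Butterworth filter)
#'
#' Applies a three-sample median filter followed by a second-order
#' low-pass Butterworth filter (default cutoff 15 Hz at the trace's
#' sample rate), run forward-backward (zero phase) since the analysis is
#' offline. Invalid samples are excluded: each contiguous run of valid
#' samples is filtered on its own, runs too short for the Butterworth
#' stage (under 7 samples) receive only the median stage, and invalid
#' samples pass through unchanged and stay flagged.
#'
#' @param trace A [gaze_trace()].
#' @param cutoff Low-pass cutoff in Hz (default 15).
#' @return The filtered `gaze_trace`.
#' @export
filter_trace <- function(trace, cutoff = 15) {
  fs <- attr(trace, "sample_rate")
  if (is.null(fs)) stop("trace has no sample_rate", call. = FALSE)
  if (fs <= 2 * cutoff) {
    stop("sample_rate (", fs, " Hz) must exceed twice the cutoff (",
         cutoff, " Hz)", call. = FALSE)
  }
  stopifnot(sum(trace$valid) >= 7)
  bf <- signal::butter(2, cutoff / (fs / 2), type = "low")
  pitch <- trace$pitch
  runs <- rle(trace$valid)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  for (i in seq_along(runs$values)) {
    if (!runs$values[i]) next
    idx <- starts[i]:ends[i]
    seg <- pitch[idx]
    if (length(seg) >= 3) {
      seg <- stats::runmed(seg, 3, endrule = "keep")
    }
    if (length(seg) >= 7) {
      seg <- zero_phase_filter(bf, seg)
    }
    pitch[idx] <- seg
  }
  out <- trace
  out$pitch <- pitch
  out
}

# Forward-backward IIR filtering with odd-reflection padding and
# steady-history initial conditions, so constant segments pass through
# exactly and edge transients stay out of the retained samples.
zero_phase_filter <- function(bf, x) {
  n <- length(x)
  np <- min(n - 1, 12)
  xp <- c(2 * x[1] - x[(np + 1):2], x, 2 * x[n] - x[(n - 1):(n - np)])
  pass <- function(z) {
    as.numeric(signal::filter(bf$b, bf$a, z,
                              init.x = rep(z[1], 2), init.y = rep(z[1], 2)))
  }
  y <- rev(pass(rev(pass(xp))))
  y[(np + 1):(np + n)]
}

#' Detect fixations with a greedy dispersion algorithm
#'
#' Grows a window left to right over the valid samples while the pitch
#' dispersion (max - min) stays within `dispersion` degrees (boundary
#' inclusive); when the window can grow no further it is emitted as a
#' fixation if it lasts at least `min_duration` seconds (inclusive),
#' otherwise the window start advances by one sample. Emitted windows do
#' not overlap, and invalid samples break windows.
#'
#' @param trace A (filtered) [gaze_trace()].
#' @param dispersion Maximal within-fixation dispersion in degrees
#'   (default 3).
#' @param min_duration Minimal fixation duration in seconds (default
#'   0.1).
#' @return Tibble of fixations: `t_start`, `t_end`, `duration`,
#'   `mean_pitch` (possibly zero rows).
#' @export
detect_fixations <- function(trace, dispersion = 3, min_duration = 0.1) {
  t <- trace$t
  p <- trace$pitch
  ok <- trace$valid
  n <- length(t)
  fix <- list()
  i <- 1
  while (i <= n) {
    if (!ok[i]) {
      i <- i + 1
      next
    }
    j <- i
    lo <- hi <- p[i]
    while (j < n && ok[j + 1]) {
      nlo <- min(lo, p[j + 1])
      nhi <- max(hi, p[j + 1])
      if (nhi - nlo > dispersion) break
      lo <- nlo
      hi <- nhi
      j <- j + 1
    }
    if (t[j] - t[i] >= min_duration) {
      fix[[length(fix) + 1]] <- tibble::tibble(
        t_start = t[i], t_end = t[j], duration = t[j] - t[i],
        mean_pitch = mean(p[i:j])
      )
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  if (length(fix) == 0) {
    return(tibble::tibble(t_start = numeric(0), t_end = numeric(0),
                          duration = numeric(0), mean_pitch = numeric(0)))
  }
  dplyr::bind_rows(fix)
}

#' Pitch of the fixation active at ball bounce
#'
#' Returns the mean pitch of the fixation whose (closed) interval
#' contains `bounce_time`; a fixation ending exactly at the bounce is
#' included. `NA` when no fixation is active.
#'
#' @param fixations Tibble from [detect_fixations()].
#' @param bounce_time Time of ball bounce in seconds.
#' @return Mean pitch in degrees, or `NA`.
#' @export
pitch_at_bounce <- function(fixations, bounce_time) {
  hit <- fixations$t_start <= bounce_time & fixations$t_end >= bounce_time
  if (!any(hit)) return(NA_real_)
  fixations$mean_pitch[which(hit)[1]]
}

#' Per-trial and per-participant quality control
#'
#' Excludes trials with more than 20% missing samples or any tracking
#' gap over 100 ms; flags outliers beyond 3.29 standard deviations from
#' the mean of the participant's remaining (non-missing, non-excluded)
#' pitch values; and flags the participant when more than 15% of trials
#' are missing/excluded or outlying.
#'
#' @param trials Tibble with one row per trial: `pitch` (`NA` when no
#'   fixation was available), `prop_missing` (fraction of missing
#'   samples, default 0) and `max_gap` (longest tracking gap in seconds,
#'   default 0).
#' @param missing_max Missingness threshold (default 0.2).
#' @param gap_max Gap threshold in seconds (default 0.1).
#' @param outlier_sd Outlier threshold in standard deviations (default
#'   3.29, two-sided p < 0.001).
#' @param participant_max Participant-level threshold on the fraction of
#'   missing/outlier trials (default 0.15).
#' @return A `qc_report`: tibble with `trial`, `pitch`, `excluded`,
#'   `outlier`, `reason`; attributes `participant_excluded` and
#'   `participant_reason`.
#' @export
apply_qc <- function(trials, missing_max = 0.2, gap_max = 0.1,
                     outlier_sd = 3.29, participant_max = 0.15) {
  stopifnot(is.data.frame(trials), "pitch" %in% names(trials))
  n <- nrow(trials)
  pitch <- trials$pitch
  prop_missing <- if ("prop_missing" %in% names(trials)) {
    trials$prop_missing
  } else {
    rep(0, n)
  }
  max_gap <- if ("max_gap" %in% names(trials)) trials$max_gap else rep(0, n)
  if (sum(!is.na(pitch)) < 2) {
    out <- tibble::tibble(trial = seq_len(n), pitch = pitch,
                          excluded = TRUE, outlier = FALSE,
                          reason = "missing>20%")
    attr(out, "participant_excluded") <- TRUE
    attr(out, "participant_reason") <- "all trials missing"
    class(out) <- c("qc_report", class(out))
    return(out)
  }
  reason <- rep(NA_character_, n)
  excluded <- rep(FALSE, n)
  excluded[is.na(pitch) | prop_missing > missing_max] <- TRUE
  reason[is.na(pitch) | prop_missing > missing_max] <- "missing>20%"
  gap_bad <- !excluded & max_gap > gap_max
  excluded[gap_bad] <- TRUE
  reason[gap_bad] <- "gap>100ms"
  keep <- !excluded & !is.na(pitch)
  mu <- mean(pitch[keep])
  sdv <- sd(pitch[keep])
  outlier <- rep(FALSE, n)
  if (is.finite(sdv) && sdv > 0) {
    outlier <- keep & abs(pitch - mu) > outlier_sd * sdv
  }
  reason[outlier] <- "outlier>3.29SD"
  bad_frac <- mean(excluded | outlier)
  out <- tibble::tibble(trial = seq_len(n), pitch = pitch,
                        excluded = excluded, outlier = outlier,
                        reason = reason)
  attr(out, "participant_excluded") <- bad_frac > participant_max
  attr(out, "participant_reason") <-
    if (bad_frac > participant_max) {
      sprintf(">15%% of trials missing or outliers (%.1f%%)", 100 * bad_frac)
    } else {
      NA_character_
    }
  class(out) <- c("qc_report", class(out))
  out
}

#' Dichotomize per-trial gaze pitch into binary responses
#'
#' Codes a shift toward expecting a higher bounce: the trial-to-trial
#' change is thresholded at one standard deviation of all changes for
#' the participant, `y = 1` for an above-threshold upward shift, `y = 0`
#' for a downward one, and sub-threshold trials carry the previous
#' response forward. The first response is 1 when the first pitch lies
#' above the participant's median pitch. The output is invariant to
#' adding a constant to the whole series.
#'
#' @param pitch Numeric per-trial pitch series (QC-passed, no `NA`).
#' @param threshold_sd Threshold in SDs of the trial-to-trial change
#'   (default 1).
#' @return Tibble with `trial` and binary `y`.
#' @export
dichotomize <- function(pitch, threshold_sd = 1) {
  stopifnot(is.numeric(pitch), !anyNA(pitch), length(pitch) >= 2)
  dg <- diff(pitch)
  thr <- threshold_sd * sd(dg)
  if (!is.finite(thr) || thr == 0) {
    stop("dichotomize: trial-to-trial changes have zero variance; ",
         "inspect the pitch series", call. = FALSE)
  }
  y <- integer(length(pitch))
  y[1] <- as.integer(pitch[1] > median(pitch))
  for (k in 2:length(pitch)) {
    y[k] <- if (dg[k - 1] > thr) 1L else if (dg[k - 1] < -thr) 0L else y[k - 1]
  }
  tibble::tibble(trial = seq_along(pitch), y = y)
}
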