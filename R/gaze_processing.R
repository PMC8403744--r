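# Offline gaze analysis: saccade detection (velocity/acceleration
# thresholds), the online 2-degree trigger, per-trial eye-movement measures
# and the trial-exclusion rules.

# run-length encode a logical vector into (start, end) index pairs
.runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  cbind(start = starts[keep], end = ends[keep])
}

#' Detect saccades in a gaze trace
#'
#' Velocity-/acceleration-based event detection on a uniformly sampled
#' 1000 Hz trace: velocities from central differences smoothed with a
#' 5-sample running mean, speed and absolute acceleration thresholded at
#' `vel_thresh` (deg/s) or `acc_thresh` (deg/s^2). Contiguous
#' suprathreshold runs closer than `merge_gap_ms` are merged and events
#' shorter than `min_duration_ms` discarded. Samples flagged as blinks are
#' excluded from the velocity computation.
#'
#' @param trace a `gaze_trace` tibble (`t_ms`, `x_deg`, `y_deg`, `blink`).
#' @param vel_thresh velocity threshold (deg/s), default 22.
#' @param acc_thresh acceleration threshold (deg/s^2), default 3800.
#' @param min_duration_ms minimum event duration (ms), default 4.
#' @param merge_gap_ms events separated by less than this are merged,
#'   default 20.
#' @return A tibble with one row per saccade: `onset_ms`, `offset_ms`,
#'   `peak_velocity`, `amplitude_deg` (horizontal, signed). Zero rows for a
#'   degenerate or motionless trace.
#' @export
detect_saccades <- function(trace, vel_thresh = 22, acc_thresh = 3800,
                            min_duration_ms = 4, merge_gap_ms = 20) {
  empty <- tibble::tibble(onset_ms = numeric(0), offset_ms = numeric(0),
                          peak_velocity = numeric(0), amplitude_deg = numeric(0))
  n <- nrow(trace)
  if (is.null(n) || n < 7) return(empty)
  x <- trace$x_deg
  y <- trace$y_deg
  dt_s <- 1e-3  # uniform 1 kHz sampling

  cdiff <- function(v) {
    d <- c(NA, (v[-(1:2)] - v[1:(length(v) - 2)]) / 2, NA)
    d
  }
  vx <- cdiff(x) / dt_s
  vy <- cdiff(y) / dt_s
  k <- rep(1 / 5, 5)
  vx <- as.numeric(stats::filter(vx, k, sides = 2))
  vy <- as.numeric(stats::filter(vy, k, sides = 2))
  speed <- sqrt(vx^2 + vy^2)
  acc <- abs(c(NA, (speed[-(1:2)] - speed[1:(n - 2)]) / 2, NA)) / dt_s

  supra <- (speed > vel_thresh) | (acc > acc_thresh)
  supra[is.na(supra)] <- FALSE
  supra[trace$blink] <- FALSE
  if (!any(supra)) return(empty)

  ev <- .runs(supra)
  # merge events separated by short gaps
  if (nrow(ev) > 1) {
    merged <- list(ev[1, ])
    for (i in 2:nrow(ev)) {
      last <- merged[[length(merged)]]
      if (ev[i, "start"] - last["end"] - 1 < merge_gap_ms) {
        last["end"] <- ev[i, "end"]
        merged[[length(merged)]] <- last
      } else merged[[length(merged) + 1L]] <- ev[i, ]
    }
    ev <- do.call(rbind, merged)
  }
  dur <- trace$t_ms[ev[, "end"]] - trace$t_ms[ev[, "start"]]
  ev <- ev[dur >= min_duration_ms, , drop = FALSE]
  if (nrow(ev) == 0) return(empty)

  tibble::tibble(
    onset_ms = trace$t_ms[ev[, "start"]],
    offset_ms = trace$t_ms[ev[, "end"]],
    peak_velocity = vapply(seq_len(nrow(ev)), function(i)
      max(speed[ev[i, "start"]:ev[i, "end"]], na.rm = TRUE), numeric(1)),
    amplitude_deg = x[ev[, "end"]] - x[ev[, "start"]])
}

#' Online saccade-trigger time
#'
#' The gaze-contingent display switch from adaptation to test stimulus fires
#' at the first sample whose radial gaze eccentricity from screen centre
#' exceeds `threshold_deg` (2 degrees in all designs).
#'
#' @param trace a `gaze_trace` tibble.
#' @param threshold_deg trigger eccentricity (deg).
#' @return Trigger time in ms, or `NA` if the threshold is never exceeded
#'   ("no-switch").
#' @export
online_trigger_time <- function(trace, threshold_deg = 2) {
  ecc <- sqrt(trace$x_deg^2 + trace$y_deg^2)
  i <- which(ecc > threshold_deg)[1]
  if (is.na(i)) return(NA_real_)
  trace$t_ms[i]
}

#' Saccade-amplitude validity via the wavelength ratio
#'
#' The ratio `f_corr = |amplitude| / lambda_corr` must land near a natural
#' number for the postsaccadic retinal input to stay correlated /
#' anticorrelated as designed. `integer_distance` is the absolute distance
#' of `f_corr` to its nearest non-negative integer (bounded by 0.5, the
#' worst case, where the gratings swap roles); trials with distance at or
#' above 0.25 are invalid.
#'
#' @param amplitude_deg horizontal saccade amplitude (deg, sign ignored).
#' @param lambda_corr correlated-grating wavelength (deg, > 0).
#' @param boundary exclusion boundary on the integer distance (default 0.25).
#' @return A list with `f_corr`, `integer_distance` and `valid`.
#' @export
amplitude_validity <- function(amplitude_deg, lambda_corr, boundary = 0.25) {
  if (any(lambda_corr <= 0)) stop("lambda_corr must be positive")
  f_corr <- abs(amplitude_deg) / lambda_corr
  dist <- abs(f_corr - round(f_corr))
  list(f_corr = f_corr, integer_distance = dist, valid = dist < boundary)
}

#' Compute the per-trial eye-movement measures
#'
#' Follows the offline analysis definitions: the trial's saccade is the
#' first detected event with onset after saccade-target onset; latency is
#' onset minus target onset (1 ms resolution); presaccadic fixation
#' position is the mean horizontal gaze between adaptation onset and
#' saccade onset, postsaccadic fixation position the mean between saccade
#' offset and mask onset; amplitude is their difference; adaptation
#' duration is saccade onset minus adaptation onset; fixation stability is
#' the SD of horizontal gaze over the presaccadic window. Mask onset is the
#' online trigger time plus blank plus test duration (for the design
#' without a mask this is the test-offset grey screen, which bounds the
#' same windows).
#'
#' @param trace a `gaze_trace` tibble.
#' @param adaptation_onset_ms,target_onset_ms stimulus onsets (ms).
#' @param blank_ms postsaccadic blank duration (ms).
#' @param test_duration_ms test-stimulus duration (ms).
#' @param trigger_threshold_deg online trigger eccentricity (deg).
#' @return A list of measures (`latency_ms`, `amplitude_deg`,
#'   `adaptation_ms`, `fixation_sd`, `pre_fix_deg`, `post_fix_deg`,
#'   `trigger_ms`, `mask_onset_ms`, `switch_within_saccade`,
#'   `blink_in_window`, `saccade_onset_ms`, `saccade_offset_ms`,
#'   `n_saccades`).
#' @export
compute_trial_measures <- function(trace, adaptation_onset_ms, target_onset_ms,
                                   blank_ms = 0, test_duration_ms = 400,
                                   trigger_threshold_deg = 2) {
  sac <- detect_saccades(trace)
  trigger <- online_trigger_time(trace, trigger_threshold_deg)
  main <- sac[sac$onset_ms > target_onset_ms, , drop = FALSE]
  has_sac <- nrow(main) > 0
  onset <- if (has_sac) main$onset_ms[1] else NA_real_
  offset <- if (has_sac) main$offset_ms[1] else NA_real_
  mask_onset <- if (!is.na(trigger)) trigger + blank_ms + test_duration_ms
                else max(trace$t_ms)

  t <- trace$t_ms
  pre_idx <- t >= adaptation_onset_ms & t < ifelse(has_sac, onset, Inf)
  post_idx <- if (has_sac) t > offset & t <= mask_onset else rep(FALSE, length(t))
  pre_fix <- if (any(pre_idx)) mean(trace$x_deg[pre_idx]) else NA_real_
  post_fix <- if (any(post_idx)) mean(trace$x_deg[post_idx]) else NA_real_

  list(
    latency_ms = if (has_sac) onset - target_onset_ms else NA_real_,
    saccade_onset_ms = onset,
    saccade_offset_ms = offset,
    pre_fix_deg = pre_fix,
    post_fix_deg = post_fix,
    amplitude_deg = post_fix - pre_fix,
    adaptation_ms = if (has_sac) onset - adaptation_onset_ms else NA_real_,
    fixation_sd = if (sum(pre_idx) > 1) stats::sd(trace$x_deg[pre_idx]) else NA_real_,
    trigger_ms = trigger,
    mask_onset_ms = mask_onset,
    switch_within_saccade =
      has_sac && !is.na(trigger) && trigger >= onset && trigger <= offset,
    blink_in_window = any(trace$blink[t >= 0 & t <= mask_onset]),
    n_saccades = nrow(sac))
}

#' Apply the trial-exclusion rules
#'
#' Evaluates every applicable rule (none short-circuit) and reports all
#' violations as reason codes:
#' \itemize{
#'   \item `blink` — a blink between trial initiation and mask onset;
#'   \item `switch_outside_saccade` — the adaptation-to-test switch did not
#'     fall within the saccade (or no saccade / no switch);
#'   \item `fixation_unstable` — SD of horizontal gaze during the
#'     adaptation phase above 0.5 deg;
#'   \item `amplitude_invalid` — integer distance of
#'     `|amplitude| / lambda_corr` at or above 0.25;
#'   \item `latency_too_long` — latency above 600 ms (full-display
#'     overlap designs, Experiments 1, 4 and 5 only);
#'   \item `adaptation_duration_deviant` — adaptation duration more than
#'     100 ms away from the intended 1.5 s (Experiment 3 only).
#' }
#'
#' @param measures list from [compute_trial_measures()].
#' @param lambda_corr correlated-grating wavelength of the trial (deg).
#' @param spec the [experiment_spec()] (selects the applicable rules).
#' @param fixation_sd_limit stability limit (deg), default 0.5.
#' @return A list with `valid`, character vector `reasons`, `f_corr` and
#'   `integer_distance`.
#' @export
validate_trial <- function(measures, lambda_corr, spec,
                           fixation_sd_limit = 0.5) {
  reasons <- character(0)
  if (isTRUE(measures$blink_in_window)) reasons <- c(reasons, "blink")
  if (!isTRUE(measures$switch_within_saccade))
    reasons <- c(reasons, "switch_outside_saccade")
  if (is.na(measures$fixation_sd) || measures$fixation_sd > fixation_sd_limit)
    reasons <- c(reasons, "fixation_unstable")

  if (is.na(measures$amplitude_deg)) {
    f_corr <- NA_real_; idist <- NA_real_
    reasons <- c(reasons, "amplitude_invalid")
  } else {
    av <- amplitude_validity(measures$amplitude_deg, lambda_corr)
    f_corr <- av$f_corr; idist <- av$integer_distance
    if (!av$valid) reasons <- c(reasons, "amplitude_invalid")
  }

  if (!is.na(spec$latency_limit_ms) &&
      (is.na(measures$latency_ms) || measures$latency_ms > spec$latency_limit_ms))
    reasons <- c(reasons, "latency_too_long")
  if (!is.na(spec$adaptation_deviation_limit_ms) &&
      (is.na(measures$adaptation_ms) ||
       abs(measures$adaptation_ms - spec$intended_adaptation_ms) >
         spec$adaptation_deviation_limit_ms))
    reasons <- c(reasons, "adaptation_duration_deviant")

  list(valid = length(reasons) == 0, reasons = reasons,
       f_corr = f_corr, integer_distance = idist)
}
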