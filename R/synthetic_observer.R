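# Generative observer: adaptation dynamics (build-up and decay of the PSE
# shift), 2AFC contrast judgments, and 1000 Hz gaze traces with realistic
# saccade latencies, landing errors, fixation jitter and blinks.

#' Parameters of the generative observer
#'
#' The observer's point of subjective equality (PSE, in contrast-difference
#' units) builds up with adaptation duration as a saturating exponential
#' towards `pse_max` and decays over a postsaccadic blank following a
#' logarithmic curve (see [true_pse()]). Responses are drawn from a
#' lapse-bounded cumulative-Gaussian psychometric function with spread
#' `jnd`. Oculomotor behaviour: saccade latency is shifted-gamma
#' distributed, landing error and fixation jitter are Gaussian, blinks occur
#' with a per-trial probability.
#'
#' Default dynamics are calibrated so that roughly 1.7 s of adaptation with
#' no blank yields a PSE near -0.14 and 1.5 s of adaptation followed by a
#' 1.6 s blank yields a PSE near -0.06, with discrimination spread (JND)
#' 0.077 — the group-level magnitudes the simulated designs are meant to
#' reproduce.
#'
#' @param pse_max asymptotic PSE shift (delta-c units, <= 0 for an adapting
#'   observer). Default -0.14.
#' @param tau_build build-up time constant (s). Default 0.23.
#' @param decay_A,decay_B log-decay parameters of the relative decay factor
#'   `decay_A * log(blank_ms) + decay_B`, applied for blanks >= 100 ms and
#'   clamped to `[0, 1]`; the factor is 1 at blank 0 and linearly
#'   interpolated on (0, 100) ms.
#' @param jnd psychometric spread (delta-c units, > 0). Default 0.077.
#' @param lapse_rate stimulus-independent error rate in `[0, 0.1]`.
#' @param latency_shift_ms,latency_shape,latency_scale shifted-gamma saccade
#'   latency: `shift + Gamma(shape, scale)` ms. Defaults give a median near
#'   191 ms.
#' @param landing_error_sd SD of the horizontal saccade landing error (deg).
#' @param fixation_jitter_sd SD of (smoothed) fixational gaze jitter (deg).
#' @param blink_prob probability that a trial contains one blink.
#' @param position_bias additive PSE offset applied when the correlated
#'   grating is in the lower half (models the visual-field asymmetry;
#'   default 0, i.e. not generated).
#' @param slice_gain named numeric, multiplicative PSE gain for the
#'   Experiment 4 slice conditions.
#' @return An object of class `observer_params`.
#' @export
observer_params <- function(pse_max = -0.14, tau_build = 0.23,
                            decay_A = -0.103, decay_B = 1.188,
                            jnd = 0.077, lapse_rate = 0.02,
                            latency_shift_ms = 80, latency_shape = 8,
                            latency_scale = 14.5,
                            landing_error_sd = 0.75,
                            fixation_jitter_sd = 0.05,
                            blink_prob = 0.04,
                            position_bias = 0,
                            slice_gain = c(center = 0.79, periphery = 0.21)) {
  stopifnot(jnd > 0, pse_max <= 0, lapse_rate >= 0, lapse_rate <= 0.1,
            landing_error_sd >= 0, fixation_jitter_sd >= 0,
            blink_prob >= 0, blink_prob <= 1, tau_build > 0)
  structure(
    list(pse_max = pse_max, tau_build = tau_build,
         decay_A = decay_A, decay_B = decay_B,
         jnd = jnd, lapse_rate = lapse_rate,
         latency_shift_ms = latency_shift_ms, latency_shape = latency_shape,
         latency_scale = latency_scale,
         landing_error_sd = landing_error_sd,
         fixation_jitter_sd = fixation_jitter_sd,
         blink_prob = blink_prob, position_bias = position_bias,
         slice_gain = slice_gain),
    class = "observer_params")
}

#' @export
print.observer_params <- function(x, ...) {
  cat(sprintf(
    "<observer_params> pse_max %.3f, tau %.2fs, jnd %.3f, lapse %.3f\n",
    x$pse_max, x$tau_build, x$jnd, x$lapse_rate))
  invisible(x)
}

#' Generative PSE as a function of adaptation and blank duration
#'
#' Build-up: `pse_max * (1 - exp(-t_adapt / tau_build))`. Decay over a
#' postsaccadic blank: the build-up value is multiplied by a factor that is
#' 1 at blank 0, follows `decay_A * log(blank_ms) + decay_B` (clamped to
#' `[0, 1]`) for blanks of at least 100 ms, and is linearly interpolated in
#' between. The natural-log decay mirrors the analysis-side model, which is
#' undefined at 0 and therefore anchored at the no-blank PSE.
#'
#' @param t_adapt_s adaptation duration in seconds (>= 0), vectorised.
#' @param t_blank_s postsaccadic blank duration in seconds (>= 0).
#' @param params an [observer_params()].
#' @return PSE in contrast-difference units (<= 0).
#' @export
true_pse <- function(t_adapt_s, t_blank_s = 0, params = observer_params()) {
  stopifnot(all(t_adapt_s >= 0), all(t_blank_s >= 0))
  build <- params$pse_max * (1 - exp(-t_adapt_s / params$tau_build))
  blank_ms <- t_blank_s * 1000
  g100 <- min(max(params$decay_A * log(100) + params$decay_B, 0), 1)
  g <- ifelse(blank_ms >= 100,
              pmin(pmax(params$decay_A * log(pmax(blank_ms, 100)) +
                          params$decay_B, 0), 1),
              1 + (g100 - 1) * blank_ms / 100)
  build * g
}

#' Probability of an "anticorrelated higher" response
#'
#' Lapse-bounded cumulative Gaussian:
#' `P = lapse/2 + (1 - lapse) * pnorm((delta_c - pse) / jnd)`.
#'
#' @param delta_c tested contrast difference (c_anti - c_corr).
#' @param pse the observer's current PSE.
#' @param jnd psychometric spread (> 0).
#' @param lapse lapse rate in `[0, 1]`.
#' @return Probability in `[lapse/2, 1 - lapse/2]`.
#' @export
response_probability <- function(delta_c, pse, jnd, lapse = 0) {
  stopifnot(jnd > 0)
  lapse / 2 + (1 - lapse) * stats::pnorm((delta_c - pse) / jnd)
}

#' Draw a 2AFC contrast judgment
#'
#' Bernoulli draw of "anticorrelated grating perceived higher in contrast"
#' at the trial's contrast difference, given the realized PSE.
#'
#' @param delta_c tested contrast difference.
#' @param realized_pse the observer's PSE on this trial.
#' @param params an [observer_params()].
#' @param seed integer seed for the draw.
#' @return `TRUE` for anticorrelated-higher, `FALSE` for correlated-higher.
#' @export
simulate_response <- function(delta_c, realized_pse, params = observer_params(),
                              seed = 1L) {
  p <- response_probability(delta_c, realized_pse, params$jnd, params$lapse_rate)
  rng <- local_rng(seed)
  as.logical(rng$bernoulli(length(p), p))
}

# minimum-jerk position profile on [0, 1]
.minjerk <- function(u) 10 * u^3 - 15 * u^4 + 6 * u^5

# Gaussian-smoothed positional jitter with target SD (deg); smoothing keeps
# sample-to-sample velocity/acceleration far below the saccade-detection
# thresholds.
.smooth_jitter <- function(n, sd_deg, rng, kernel_sd_ms = 10) {
  if (sd_deg <= 0 || n == 0) return(numeric(n))
  half <- 3 * kernel_sd_ms
  k <- stats::dnorm(seq(-half, half), sd = kernel_sd_ms)
  k <- k / sum(k)
  raw <- rng$normal(n + 2 * half)
  sm <- stats::filter(raw, k, sides = 2)
  sm <- as.numeric(sm[(half + 1):(half + n)])
  sm / sqrt(sum(k^2)) * sd_deg
}

#' Simulate a 1000 Hz gaze trace for one trial
#'
#' Timeline (ms after trial initiation): fixation at screen centre with
#' smoothed Gaussian jitter; after saccade-target onset, a saccade starts at
#' a shifted-gamma latency, follows a minimum-jerk position profile whose
#' duration obeys the main-sequence rule `21 + 2.2 * amplitude` ms, and
#' lands at the target eccentricity plus Gaussian landing error. A blink
#' (contiguous flagged run of 100-300 ms) occurs with probability
#' `blink_prob`. The trace extends past mask onset so all analysis windows
#' are covered. Ground truth (saccade onset/offset/latency, amplitude,
#' landing error) is attached as the `"truth"` attribute.
#'
#' @param target_onset_ms saccade-target onset (ms after trial initiation).
#' @param target_eccentricity_deg signed target position (deg).
#' @param blank_ms postsaccadic blank duration (ms).
#' @param params an [observer_params()].
#' @param seed integer seed.
#' @param test_duration_ms,mask_duration_ms postsaccadic test and mask
#'   durations (ms).
#' @return A tibble of class `gaze_trace` with columns `t_ms`, `x_deg`,
#'   `y_deg`, `blink`, and attribute `truth`.
#' @export
simulate_gaze <- function(target_onset_ms, target_eccentricity_deg,
                          blank_ms = 0, params = observer_params(), seed = 1L,
                          test_duration_ms = 400, mask_duration_ms = 300) {
  rng <- local_rng(seed)
  latency <- params$latency_shift_ms +
    rng$gamma(1, shape = params$latency_shape, scale = params$latency_scale)
  latency <- round(latency)
  landing_err <- rng$normal(1, sd = params$landing_error_sd)
  amplitude <- target_eccentricity_deg + landing_err
  dur <- max(10, round(21 + 2.2 * abs(amplitude)))
  onset <- round(target_onset_ms + latency)
  offset <- onset + dur
  n <- offset + blank_ms + test_duration_ms + mask_duration_ms + 100
  t_ms <- seq_len(n) - 1

  x <- numeric(n)
  sacc_idx <- which(t_ms >= onset & t_ms <= offset)
  u <- (t_ms[sacc_idx] - onset) / dur
  x[sacc_idx] <- amplitude * .minjerk(u)
  x[t_ms > offset] <- amplitude
  x <- x + .smooth_jitter(n, params$fixation_jitter_sd, rng)
  y <- .smooth_jitter(n, params$fixation_jitter_sd, rng)

  blink <- rep(FALSE, n)
  if (as.logical(rng$bernoulli(1, params$blink_prob))) {
    bdur <- round(rng$unif(1, 100, 300))
    bstart <- round(rng$unif(1, 1, max(1, n - bdur)))
    idx <- bstart:min(n, bstart + bdur)
    blink[idx] <- TRUE
    x[idx] <- x[max(1, bstart - 1)]   # signal freezes during a blink
    y[idx] <- y[max(1, bstart - 1)]
  }

  out <- tibble::tibble(t_ms = t_ms, x_deg = x, y_deg = y, blink = blink)
  attr(out, "truth") <- list(
    latency_ms = latency, onset_ms = onset, offset_ms = offset,
    amplitude_deg = amplitude, landing_error_deg = landing_err,
    duration_ms = dur)
  class(out) <- c("gaze_trace", class(out))
  out
}

# Effective PSE on one trial of a given design row (ground-truth adaptation
# duration in ms); applies Experiment 4 slice gains, the Experiment 5
# test-contrast scaling and the optional position bias.
.trial_pse <- function(row, adaptation_ms, params, spec) {
  pse <- true_pse(adaptation_ms / 1000, row$blank_ms / 1000, params)
  if (!is.null(spec$slice_conditions) && !is.na(row$slice_condition))
    pse <- pse * params$slice_gain[[row$slice_condition]]
  if (spec$experiment == 5) {
    # perceived contrast-difference shift scales inversely with the test
    # stimulus mean contrast (Weber-like); reference is the 0.15 used in
    # the full-display designs
    pse <- pse * 0.15 / row$adaptation_contrast
  }
  if (identical(row$correlated_position, "lower"))
    pse <- pse + params$position_bias
  pse
}

#' Generate a complete synthetic dataset for one or more participants
#'
#' For each participant: builds a randomized schedule, runs the
#' gaze-contingent timing engine (adaptive latency predictor for Experiments
#' 2 and 3), simulates a gaze trace per trial, processes it offline
#' (saccade detection, trial measures, exclusion rules) and draws the 2AFC
#' response from the generative observer at the trial's ground-truth
#' adaptation duration. Reproducible from `master_seed`.
#'
#' @param spec an [experiment_spec()].
#' @param n_participants number of simulated participants.
#' @param params a single [observer_params()] or a list of one per
#'   participant.
#' @param master_seed integer master seed.
#' @param keep_traces if `TRUE`, gaze traces are returned in the
#'   `"traces"` attribute (memory-heavy; default `FALSE`).
#' @return A tibble of trial records: design columns plus gaze-derived
#'   measures (`latency_ms`, `amplitude_deg`, `adaptation_ms`,
#'   `fixation_sd`, ...), validity (`valid`, `reasons`, `f_corr`,
#'   `integer_distance`), the ground-truth generative PSE (`true_pse`) and
#'   the response (`response`, `TRUE` = anticorrelated judged higher).
#' @export
generate_dataset <- function(spec, n_participants = 1,
                             params = observer_params(),
                             master_seed = 1L, keep_traces = FALSE) {
  stopifnot(inherits(spec, "experiment_spec"))
  if (inherits(params, "observer_params"))
    params <- rep(list(params), n_participants)
  stopifnot(length(params) == n_participants)

  all_rows <- vector("list", n_participants)
  traces <- if (keep_traces) list() else NULL
  for (p in seq_len(n_participants)) {
    pp <- params[[p]]
    sched <- build_schedule(spec, seed = derive_seed(master_seed, paste0("schedule", p)))
    n_tr <- nrow(sched)
    latency_history <- numeric(0)
    rows <- vector("list", n_tr)
    for (i in seq_len(n_tr)) {
      row <- as.list(sched[i, ])
      pred <- predict_latency(latency_history)
      if (spec$experiment == 2) {
        on <- schedule_onsets_exp2(row$intended_adaptation_ms, pred)
      } else if (spec$experiment == 3) {
        on <- schedule_onsets_exp3(pred, spec$fixation_to_target_range_s[1] * 1000)
      } else {
        on <- c(adaptation_onset = 0,
                target_onset = row$fixation_to_target_s * 1000)
      }
      trace <- simulate_gaze(
        target_onset_ms = on[["target_onset"]],
        target_eccentricity_deg = row$target_eccentricity,
        blank_ms = row$blank_ms, params = pp,
        seed = derive_seed(master_seed, paste0("gaze", p, "_", i)),
        test_duration_ms = spec$test_duration_ms,
        mask_duration_ms = spec$mask_duration_ms)
      truth <- attr(trace, "truth")
      meas <- compute_trial_measures(
        trace, adaptation_onset_ms = on[["adaptation_onset"]],
        target_onset_ms = on[["target_onset"]], blank_ms = row$blank_ms,
        test_duration_ms = spec$test_duration_ms)
      status <- validate_trial(meas, lambda_corr = row$lambda_corr, spec = spec)
      latency_history <- c(latency_history, truth$latency_ms)

      true_adapt_ms <- truth$onset_ms - on[["adaptation_onset"]]
      pse_i <- .trial_pse(row, true_adapt_ms, pp, spec)
      resp <- simulate_response(
        row$delta_c, pse_i, pp,
        seed = derive_seed(master_seed, paste0("resp", p, "_", i)))

      rows[[i]] <- tibble::tibble(
        participant = p, experiment = spec$experiment, trial = row$trial,
        delta_c = row$delta_c, correlated_position = row$correlated_position,
        f_anti = row$f_anti, saccade_direction = row$saccade_direction,
        lambda_corr = row$lambda_corr, common_phase = row$common_phase,
        target_eccentricity = row$target_eccentricity,
        adaptation_contrast = row$adaptation_contrast,
        intended_adaptation_ms = row$intended_adaptation_ms,
        blank_ms = row$blank_ms, slice_condition = row$slice_condition,
        adaptation_onset_ms = on[["adaptation_onset"]],
        target_onset_ms = on[["target_onset"]],
        predicted_latency_ms = pred,
        true_latency_ms = truth$latency_ms,
        true_onset_ms = truth$onset_ms,
        true_amplitude_deg = truth$amplitude_deg,
        latency_ms = meas$latency_ms,
        amplitude_deg = meas$amplitude_deg,
        adaptation_ms = meas$adaptation_ms,
        fixation_sd = meas$fixation_sd,
        trigger_ms = meas$trigger_ms,
        blink_in_window = meas$blink_in_window,
        valid = status$valid,
        reasons = paste(status$reasons, collapse = ";"),
        f_corr = status$f_corr,
        integer_distance = status$integer_distance,
        true_pse = pse_i,
        response = resp)
      if (keep_traces) traces[[length(traces) + 1L]] <- trace
    }
    all_rows[[p]] <- do.call(rbind, rows)
  }
  out <- do.call(rbind, all_rows)
  if (keep_traces) attr(out, "traces") <- traces
  out
}

#' Write / read trial records as CSV
#'
#' @param records trial-record tibble from [generate_dataset()].
#' @param path file path.
#' @return `read_trial_records` returns the records tibble.
#' @export
write_trial_records <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_records
#' @export
read_trial_records <- function(path) {
  out <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  for (col in c("slice_condition", "reasons"))
    if (col %in% names(out)) out[[col]] <- as.character(out[[col]])
  out
}

#' Write a gaze trace as CSV
#'
#' @param trace a `gaze_trace` tibble.
#' @param path file path.
#' @export
write_gaze_trace <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gaze_trace
#' @export
read_gaze_trace <- function(path) {
  out <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  class(out) <- c("gaze_trace", class(out))
  out
}
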