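# Experiment designs: factor crossings, randomized trial schedules, the
# adaptive saccade-latency predictor and the gaze-contingent onset rules.

#' Specification of one of the five experiment designs
#'
#' Encodes the factor levels, repetitions and timing constants of each
#' design:
#' \itemize{
#'   \item Experiment 1: full test display, contrast differences -0.28 to
#'     0.28 in steps of 0.04, overlap paradigm, 480 trials.
#'   \item Experiment 2: single contrast difference -0.07, intended
#'     adaptation durations 100-1200 ms in 100 ms steps, no-overlap, target
#'     onset fixed at 1200 ms, 384 trials.
#'   \item Experiment 3: contrast differences -0.3 to 0.2 in steps of 0.05,
#'     postsaccadic blank durations 0/100/200/400/800/1600 ms, constant
#'     intended adaptation duration 1.5 s, 528 trials.
#'   \item Experiment 4: as Experiment 1 but the test is a vertical slice
#'     (centre or periphery), blocked, 120 trials per block.
#'   \item Experiment 5: adaptation contrast jittered in [0.3, 0.7], test
#'     mean contrast equal to it, no mask, contrast differences
#'     -0.4 ... 0.4 (13 levels).
#' }
#'
#' @param experiment integer 1-5.
#' @return An object of class `experiment_spec`.
#' @export
experiment_spec <- function(experiment) {
  if (!experiment %in% 1:5) stop("unknown experiment id: ", experiment)
  base <- list(
    experiment = as.integer(experiment),
    f_anti_levels = c(1.5, 2.5),
    position_levels = c("upper", "lower"),
    direction_levels = c("left", "right"),
    lambda_range = c(5, 6.25),          # deg, correlated-grating wavelength
    phase_range = c(-0.5 * pi, 0.5 * pi),
    adaptation_contrast = 0.5,
    test_mean_contrast = 0.15,
    test_duration_ms = 400,
    mask_duration_ms = 300,
    overlap = TRUE,                      # fixation persists 200 ms past target
    fixation_to_target_range_s = c(1.4, 1.6),
    blank_levels_ms = 0,
    intended_adaptation_ms = NA_real_,
    slice_conditions = NULL,
    latency_limit_ms = 600,
    adaptation_deviation_limit_ms = NA_real_,
    has_mask = TRUE)
  spec <- switch(as.character(experiment),
    "1" = within(base, {
      delta_c_levels <- seq(-0.28, 0.28, by = 0.04)
      reps <- 4L                         # per cell incl. saccade direction
    }),
    "2" = within(base, {
      delta_c_levels <- -0.07
      duration_levels_ms <- seq(100, 1200, by = 100)
      reps <- 4L
      overlap <- FALSE
      fixation_to_target_range_s <- c(1.2, 1.2)
      latency_limit_ms <- NA_real_
    }),
    "3" = within(base, {
      delta_c_levels <- seq(-0.3, 0.2, by = 0.05)
      blank_levels_ms <- c(0, 100, 200, 400, 800, 1600)
      reps <- 1L
      overlap <- FALSE
      fixation_to_target_range_s <- c(1.5, 1.5)
      intended_adaptation_ms <- 1500
      latency_limit_ms <- NA_real_
      adaptation_deviation_limit_ms <- 100
    }),
    "4" = within(base, {
      delta_c_levels <- seq(-0.28, 0.28, by = 0.04)
      slice_conditions <- c("center", "periphery")
      reps <- 1L                         # per block
    }),
    "5" = within(base, {
      delta_c_levels <- c(-0.4, -0.3, -0.2, -0.15, -0.1, -0.05, 0,
                          0.05, 0.1, 0.15, 0.2, 0.3, 0.4)
      reps <- 4L
      adaptation_contrast <- NA_real_    # jittered per trial in [0.3, 0.7]
      adaptation_contrast_range <- c(0.3, 0.7)
      test_mean_contrast <- NA_real_     # equals adaptation contrast
      has_mask <- FALSE
    }))
  spec$delta_c_levels <- round(spec$delta_c_levels, 10)
  structure(spec, class = "experiment_spec")
}

#' @export
print.experiment_spec <- function(x, ...) {
  cat(sprintf("<experiment_spec> Experiment %d: %d contrast-difference level(s), reps %d\n",
              x$experiment, length(x$delta_c_levels), x$reps))
  invisible(x)
}

#' Build a randomized, counterbalanced trial schedule
#'
#' Fully crosses the design factors of the experiment (contrast difference,
#' correlated-grating position, anticorrelation factor, saccade direction,
#' plus the experiment-specific factor: intended adaptation duration in
#' Experiment 2, blank duration in Experiment 3, slice condition in
#' Experiment 4), replicates the crossing `reps` times and shuffles trial
#' order. Per-trial jitters (correlated wavelength, common phase,
#' fixation-to-target interval, Experiment 5 adaptation contrast) are drawn
#' from a dedicated RNG stream of the seed. Experiment 4 is blocked by slice
#' condition: trials are shuffled within block and blocks concatenated.
#'
#' @param spec an [experiment_spec()].
#' @param seed integer seed for order and jitters.
#' @return A tibble with one row per trial (class `trial_schedule`).
#' @export
build_schedule <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "experiment_spec"))
  factors <- list(delta_c = spec$delta_c_levels,
                  correlated_position = spec$position_levels,
                  f_anti = spec$f_anti_levels,
                  saccade_direction = spec$direction_levels)
  if (spec$experiment == 2)
    factors$intended_adaptation_ms <- spec$duration_levels_ms
  if (spec$experiment == 3)
    factors$blank_ms <- spec$blank_levels_ms
  cells <- expand.grid(factors, stringsAsFactors = FALSE)
  grid <- cells[rep(seq_len(nrow(cells)), times = spec$reps), , drop = FALSE]

  rng <- local_rng(derive_seed(seed, "schedule"))
  one_block <- function(block_grid) {
    n <- nrow(block_grid)
    block_grid <- block_grid[rng$sample(seq_len(n)), , drop = FALSE]
    block_grid$lambda_corr <- rng$unif(n, spec$lambda_range[1], spec$lambda_range[2])
    block_grid$common_phase <- rng$unif(n, spec$phase_range[1], spec$phase_range[2])
    block_grid$fixation_to_target_s <-
      rng$unif(n, spec$fixation_to_target_range_s[1], spec$fixation_to_target_range_s[2])
    if (spec$experiment == 5) {
      block_grid$adaptation_contrast <-
        rng$unif(n, spec$adaptation_contrast_range[1], spec$adaptation_contrast_range[2])
    } else {
      block_grid$adaptation_contrast <- spec$adaptation_contrast
    }
    block_grid
  }

  if (spec$experiment == 4) {
    blocks <- lapply(spec$slice_conditions, function(cond) {
      b <- one_block(cells[rep(seq_len(nrow(cells)), times = spec$reps), , drop = FALSE])
      b$slice_condition <- cond
      b
    })
    grid <- do.call(rbind, blocks)
  } else {
    grid <- one_block(grid)
    grid$slice_condition <- NA_character_
  }

  if (spec$experiment != 2) grid$intended_adaptation_ms <- spec$intended_adaptation_ms
  if (spec$experiment != 3) grid$blank_ms <- 0
  sign_dir <- ifelse(grid$saccade_direction == "right", 1, -1)
  grid$target_eccentricity <- sign_dir * 2 * grid$lambda_corr
  grid$experiment <- spec$experiment
  grid$trial <- seq_len(nrow(grid))
  out <- tibble::as_tibble(grid[, c(
    "experiment", "trial", "delta_c", "correlated_position", "f_anti",
    "saccade_direction", "lambda_corr", "common_phase",
    "fixation_to_target_s", "target_eccentricity", "adaptation_contrast",
    "intended_adaptation_ms", "blank_ms", "slice_condition")])
  class(out) <- c("trial_schedule", class(out))
  out
}

#' Adaptive saccade-latency predictor
#'
#' Before any latency is observed the estimate is 190 ms; afterwards it is
#' the median of up to the last 20 realized latencies.
#'
#' @param history numeric vector of realized saccade latencies (ms), oldest
#'   first. May be empty.
#' @param window number of most recent trials used (default 20).
#' @param initial_ms initial estimate before any observation (default 190).
#' @return Predicted saccade latency in ms.
#' @export
predict_latency <- function(history, window = 20L, initial_ms = 190) {
  history <- history[!is.na(history)]
  if (length(history) == 0) return(initial_ms)
  tail_hist <- utils::tail(history, window)
  stats::median(tail_hist)
}

#' Stimulus-onset schedule for Experiment 2
#'
#' The saccade target appears at a fixed 1200 ms after trial initiation. The
#' adaptation stimulus is timed so that, if the saccade starts at the
#' predicted latency after target onset, the realized adaptation duration
#' equals the intended one: `adaptation_onset - target_onset =
#' predicted_latency - intended_adaptation`. Equal values give simultaneous
#' onsets.
#'
#' @param intended_adaptation_ms intended adaptation duration (ms, > 0).
#' @param predicted_latency_ms predicted saccade latency (ms, > 0).
#' @param target_fixed_ms target onset after trial initiation (default 1200).
#' @return Named numeric vector `c(adaptation_onset = , target_onset = )` in
#'   ms relative to trial initiation.
#' @export
schedule_onsets_exp2 <- function(intended_adaptation_ms, predicted_latency_ms,
                                 target_fixed_ms = 1200) {
  stopifnot(intended_adaptation_ms > 0, predicted_latency_ms > 0)
  adaptation <- target_fixed_ms + predicted_latency_ms - intended_adaptation_ms
  if (adaptation < 0)
    stop("intended adaptation duration too long for the fixed target onset")
  c(adaptation_onset = adaptation, target_onset = target_fixed_ms)
}

#' Stimulus-onset schedule for Experiment 3
#'
#' Adaptation onset is delayed by the predicted saccade latency and the
#' target appears at 1500 ms, so a saccade at the predicted latency yields an
#' adaptation duration of exactly 1500 ms.
#'
#' @param predicted_latency_ms predicted saccade latency (ms, >= 0).
#' @param target_fixed_ms target onset after trial initiation (default 1500).
#' @return Named numeric vector `c(adaptation_onset = , target_onset = )`.
#' @export
schedule_onsets_exp3 <- function(predicted_latency_ms, target_fixed_ms = 1500) {
  stopifnot(predicted_latency_ms >= 0)
  c(adaptation_onset = predicted_latency_ms, target_onset = target_fixed_ms)
}

#' Write / read a trial schedule as CSV
#'
#' @param schedule a tibble from [build_schedule()].
#' @param path file path.
#' @return `read_schedule` returns the schedule tibble.
#' @export
write_schedule <- function(schedule, path) {
  utils::write.csv(as.data.frame(schedule), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  out <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  if ("slice_condition" %in% names(out))
    out$slice_condition <- as.character(out$slice_condition)
  class(out) <- c("trial_schedule", class(out))
  out
}
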