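# End-to-end orchestration: configuration (JSON round-trip), the
# design -> simulate -> process -> validate -> analyze pipeline and the
# run report with exclusion summaries, group fits and condition analyses.

#' Run configuration
#'
#' Serializable description of a full simulation-and-analysis run.
#'
#' @param experiment experiment id (1-5).
#' @param n_participants number of simulated participants.
#' @param seed master seed.
#' @param observer list of [observer_params()] overrides (field = value).
#' @param n_boot bootstrap replicates for psychometric CIs (0 = none).
#' @param subset_analyses character vector of factor columns for
#'   [subset_fits()] (e.g. `"f_anti"`).
#' @param out_dir optional output directory for CSV artifacts (`NULL` =
#'   keep everything in memory).
#' @return An object of class `run_config`.
#' @export
run_config <- function(experiment = 1, n_participants = 4, seed = 1L,
                       observer = list(), n_boot = 0,
                       subset_analyses = character(0), out_dir = NULL) {
  stopifnot(experiment %in% 1:5, n_participants >= 1)
  structure(
    list(experiment = as.integer(experiment),
         n_participants = as.integer(n_participants),
         seed = as.integer(seed), observer = observer,
         n_boot = as.integer(n_boot),
         subset_analyses = as.character(subset_analyses),
         out_dir = out_dir),
    class = "run_config")
}

#' Save / load a run configuration as JSON
#'
#' The round-trip `load_config(save_config(cfg))` reproduces the
#' configuration exactly.
#'
#' @param config a [run_config()].
#' @param path JSON file path.
#' @return `load_config` returns the `run_config`.
#' @export
save_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  run_config(experiment = raw$experiment,
             n_participants = raw$n_participants,
             seed = raw$seed,
             observer = if (length(raw$observer)) raw$observer else list(),
             n_boot = raw$n_boot,
             subset_analyses = raw$subset_analyses,
             out_dir = raw$out_dir)
}

# FNV-1a hash over the serialized object; a compact provenance fingerprint
.config_hash <- function(x) {
  bytes <- serialize(x, NULL, version = 2)
  h <- 2166136261
  for (b in as.integer(bytes)) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Summarize trial exclusions
#'
#' Per-participant and group exclusion fractions, total and by reason code.
#' A trial violating several rules counts once in the total but once per
#' reason, so reason fractions can sum to more than the total.
#'
#' @param records trial-record tibble from [generate_dataset()].
#' @return A list with `per_participant` (tibble) and `group` (named
#'   numeric: `excluded_total` plus one fraction per reason code).
#' @export
summarize_exclusions <- function(records) {
  codes <- c("blink", "switch_outside_saccade", "fixation_unstable",
             "amplitude_invalid", "latency_too_long",
             "adaptation_duration_deviant")
  per <- lapply(split(records, records$participant), function(d) {
    n <- nrow(d)
    row <- tibble::tibble(participant = d$participant[1], n_trials = n,
                          excluded_total = mean(!d$valid))
    for (code in codes)
      row[[code]] <- mean(grepl(code, d$reasons, fixed = TRUE))
    row
  })
  per <- do.call(rbind, per)
  group <- colMeans(per[, -1, drop = FALSE])
  list(per_participant = per, group = group)
}

# per-participant psychometric fits, optionally within a condition column
.participant_fits <- function(records, condition = NULL, n_boot = 0) {
  cols <- c("participant", condition)
  key <- interaction(records[cols], drop = TRUE)
  rows <- lapply(split(records, key), function(d) {
    fit <- tryCatch(fit_psychometric(d$delta_c, d$response, n_boot = n_boot),
                    error = function(e) e)
    failed <- inherits(fit, "error")
    out <- tibble::tibble(participant = d$participant[1],
                          pse = if (failed) NA_real_ else fit$pse,
                          jnd = if (failed) NA_real_ else fit$jnd,
                          lapse = if (failed) NA_real_ else fit$lapse,
                          n = nrow(d),
                          error = if (failed) conditionMessage(fit) else NA_character_)
    if (!is.null(condition)) out[[condition]] <- d[[condition]][1]
    out
  })
  do.call(rbind, rows)
}

#' Run a full simulated experiment and analyse it
#'
#' Executes the pipeline end to end: schedule construction, gaze and
#' response simulation, offline gaze processing and exclusion, then the
#' experiment's analysis — per-participant psychometric fits and a group
#' one-sided t test against zero (Experiments 1, 4, 5; per condition where
#' applicable), the running-average build-up curve (Experiment 2), fits
#' per blank duration plus the logarithmic decay fit of the group mean
#' PSEs (Experiment 3). Fully deterministic given the configuration.
#'
#' @param config a [run_config()].
#' @return An object of class `run_report`: `records`, `exclusions`,
#'   `fits`, experiment-specific analyses, group summaries (Mean ± SD) and
#'   provenance (`config`, `config_hash`, `seed`).
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "run_config"))
  spec <- experiment_spec(config$experiment)
  obs <- do.call(observer_params, config$observer)
  records <- generate_dataset(spec, config$n_participants, obs,
                              master_seed = config$seed)
  valid <- records[records$valid, , drop = FALSE]
  exclusions <- summarize_exclusions(records)

  report <- list(config = config, config_hash = .config_hash(unclass(config)),
                 seed = config$seed, records = records,
                 exclusions = exclusions)

  if (spec$experiment %in% c(1, 5)) {
    fits <- .participant_fits(valid, n_boot = config$n_boot)
    ok <- !is.na(fits$pse)
    report$fits <- fits
    report$group <- list(
      mean_pse = mean(fits$pse[ok]), sd_pse = stats::sd(fits$pse[ok]),
      mean_jnd = mean(fits$jnd[ok]), sd_jnd = stats::sd(fits$jnd[ok]))
    if (sum(ok) >= 2)
      report$t_pse_vs_zero <- t_test(fits$pse[ok], mode = "one-sample",
                                     tail = "less")
  } else if (spec$experiment == 2) {
    curves <- lapply(split(valid, valid$participant), function(d)
      running_average(d$adaptation_ms, d$response))
    report$running_average <- curves
    # pointwise group mean over emitted bins
    all_centers <- sort(unique(unlist(lapply(curves, `[[`, "bin_center"))))
    mat <- vapply(curves, function(cu) {
      v <- rep(NA_real_, length(all_centers))
      v[match(cu$bin_center, all_centers)] <- cu$proportion
      v
    }, numeric(length(all_centers)))
    report$group_curve <- tibble::tibble(
      bin_center = all_centers,
      proportion = rowMeans(as.matrix(mat), na.rm = TRUE))
  } else if (spec$experiment == 3) {
    fits <- .participant_fits(valid, condition = "blank_ms",
                              n_boot = config$n_boot)
    report$fits <- fits
    ok <- !is.na(fits$pse)
    mean_pse <- vapply(split(fits[ok, ], fits$blank_ms[ok]),
                       function(d) mean(d$pse), numeric(1))
    blanks <- as.numeric(names(mean_pse))
    report$mean_pse_by_blank <- tibble::tibble(blank_ms = blanks,
                                               pse = unname(mean_pse))
    report$decay_fit <- tryCatch(fit_log_decay(blanks, unname(mean_pse)),
                                 error = function(e) NULL)
  } else if (spec$experiment == 4) {
    fits <- .participant_fits(valid, condition = "slice_condition",
                              n_boot = config$n_boot)
    report$fits <- fits
    ok <- !is.na(fits$pse)
    report$group_by_condition <- lapply(
      split(fits[ok, ], fits$slice_condition[ok]),
      function(d) list(mean_pse = mean(d$pse), sd_pse = stats::sd(d$pse),
                       mean_jnd = mean(d$jnd), sd_jnd = stats::sd(d$jnd)))
  }

  for (col in config$subset_analyses)
    report$subsets[[col]] <- subset_fits(valid, col)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_trial_records(records, file.path(config$out_dir, "trial_records.csv"))
    if (!is.null(report$fits))
      utils::write.csv(as.data.frame(report$fits),
                       file.path(config$out_dir, "fits.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(exclusions$per_participant),
                     file.path(config$out_dir, "exclusions.csv"),
                     row.names = FALSE)
  }
  class(report) <- "run_report"
  report
}

#' @export
print.run_report <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<run_report> Experiment %d, %d participant(s), seed %d [%s]\n",
              cfg$experiment, cfg$n_participants, cfg$seed, x$config_hash))
  cat(sprintf("  trials: %d (%.1f%% excluded)\n", nrow(x$records),
              100 * x$exclusions$group[["excluded_total"]]))
  if (!is.null(x$group))
    cat(sprintf("  group PSE %.3f ± %.3f, JND %.3f ± %.3f (Mean ± SD)\n",
                x$group$mean_pse, x$group$sd_pse,
                x$group$mean_jnd, x$group$sd_jnd))
  if (!is.null(x$decay_fit))
    cat(sprintf("  decay fit: pse = %.4f log(blank_ms) + %.4f\n",
                x$decay_fit$A, x$decay_fit$B))
  invisible(x)
}
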