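#!/usr/bin/env Rscript
# Thin command-line wrapper over transadapt::run_experiment().
#
# Usage:
#   Rscript scripts/run_pipeline.R --experiment 1 --participants 4 \
#       --seed 11 --out outdir [--config config.json]
#
# A --config JSON (see transadapt::save_config) overrides the other flags.

suppressMessages(library(transadapt))

args <- commandArgs(trailingOnly = TRUE)
get_arg <- function(flag, default) {
  i <- which(args == flag)
  if (length(i) == 1 && i < length(args)) args[i + 1] else default
}

cfg_path <- get_arg("--config", NA)
if (!is.na(cfg_path)) {
  config <- load_config(cfg_path)
  out <- get_arg("--out", config$out_dir)
  if (!is.null(out)) config$out_dir <- out
} else {
  config <- run_config(
    experiment = as.integer(get_arg("--experiment", "1")),
    n_participants = as.integer(get_arg("--participants", "1")),
    seed = as.integer(get_arg("--seed", "1")),
    out_dir = get_arg("--out", "transadapt_run"))
}

report <- run_experiment(config)
print(report)
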