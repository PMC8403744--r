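# Shared fixtures: noise-free and default observers, and a brute-force
# running-average oracle that literally enumerates the quoted bin scheme.

quiet_observer <- function(...) {
  # oculomotor noise switched off: perfect landing, no jitter, no blinks,
  # no lapses; individual fields can still be overridden
  args <- modifyList(list(landing_error_sd = 0, fixation_jitter_sd = 0,
                          blink_prob = 0, lapse_rate = 0), list(...))
  do.call(observer_params, args)
}

# independent enumeration oracle for the running-average bin scheme:
# growing bins anchored at 0 (0-150 ... 0-300), a 300 ms bin sliding in
# 1 ms steps, shrinking bins anchored at 1400 (1101-1400 ... 1250-1400)
running_average_oracle <- function(duration_ms, response) {
  response <- as.numeric(response)
  bins <- rbind(
    cbind(start = 0, end = 150:300),
    cbind(start = 1:1100, end = 301:1400),
    cbind(start = 1101:1250, end = 1400))
  rows <- lapply(seq_len(nrow(bins)), function(i) {
    inb <- duration_ms >= bins[i, "start"] & duration_ms <= bins[i, "end"]
    if (!any(inb)) return(NULL)
    c(center = unname((bins[i, "start"] + bins[i, "end"]) / 2),
      n = sum(inb), prop = mean(response[inb]))
  })
  do.call(rbind, Filter(Negate(is.null), rows))
}

# simulate one clean saccade trace and return (detected onset, truth onset)
onset_pair <- function(seed, params) {
  ecc <- (if (seed %% 2) 1 else -1) * (10 + (seed %% 26) / 10)
  tr <- simulate_gaze(1500, ecc, params = params, seed = seed)
  truth <- attr(tr, "truth")
  s <- detect_saccades(tr)
  s <- s[s$onset_ms > 1500, , drop = FALSE]
  c(detected = if (nrow(s)) s$onset_ms[1] else NA_real_,
    truth = truth$onset_ms)
}
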