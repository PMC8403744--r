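make_trace <- function(x, y = rep(0, length(x)), blink = rep(FALSE, length(x))) {
  out <- tibble::tibble(t_ms = seq_along(x) - 1, x_deg = x, y_deg = y,
                        blink = blink)
  class(out) <- c("gaze_trace", class(out))
  out
}

test_that("motionless and degenerate traces yield no saccades", {
  expect_equal(nrow(detect_saccades(make_trace(rep(0, 500)))), 0)
  expect_equal(nrow(detect_saccades(make_trace(numeric(3)))), 0)
  # slow drift below both thresholds is not a saccade
  drift <- make_trace(seq(0, 0.5, length.out = 500))  # 1 deg/s
  expect_equal(nrow(detect_saccades(drift)), 0)
})

test_that("a velocity ramp is detected where it crosses threshold", {
  # piecewise: still, then constant 100 deg/s for 40 ms, then still
  x <- c(rep(0, 300), cumsum(rep(0.1, 40)), rep(4, 300))
  s <- detect_saccades(make_trace(x))
  expect_equal(nrow(s), 1)
  expect_equal(s$onset_ms[1], 299, tolerance = 3)
  expect_equal(s$amplitude_deg[1], 4, tolerance = 0.1)
})

test_that("two saccades separated by a fixation stay distinct", {
  step <- cumsum(rep(0.2, 30))  # 200 deg/s for 30 ms
  x <- c(rep(0, 200), step, rep(6, 100), 6 + step, rep(12, 200))
  s <- detect_saccades(make_trace(x))
  expect_equal(nrow(s), 2)
  # but they merge when the gap is shorter than the merge window
  x2 <- c(rep(0, 200), step, rep(6, 10), 6 + step, rep(12, 200))
  expect_equal(nrow(detect_saccades(make_trace(x2))), 1)
})

test_that("online trigger fires at the first sample beyond 2 degrees", {
  jit <- make_trace(rep(c(-0.3, 0.3), 250))
  expect_true(is.na(online_trigger_time(jit)))
  x <- c(rep(0, 1400), rep(11, 100))
  expect_equal(online_trigger_time(make_trace(x)), 1400)
  # property: on clean simulated saccades the trigger falls inside the saccade
  p <- quiet_observer()
  for (seed in 1:25) {
    tr <- simulate_gaze(1500, c(1, -1)[seed %% 2 + 1] * 11, params = p,
                        seed = seed)
    truth <- attr(tr, "truth")
    trig <- online_trigger_time(tr)
    expect_gte(trig, truth$onset_ms)
    expect_lte(trig, truth$offset_ms)
  }
})

test_that("amplitude validity uses the integer distance of the wavelength ratio", {
  v <- amplitude_validity(11.0, 5.5)
  expect_equal(v$f_corr, 2)
  expect_equal(v$integer_distance, 0)
  expect_true(v$valid)
  # a half-integer ratio is the worst case and is excluded
  v <- amplitude_validity(2.5 * 5.5, 5.5)
  expect_equal(v$integer_distance, 0.5)
  expect_false(v$valid)
  # arithmetic at the boundary
  v <- amplitude_validity(12.4, 5.5)
  expect_equal(v$f_corr, 12.4 / 5.5)
  expect_gte(v$integer_distance, 0.25)
  expect_false(v$valid)
  # just inside the boundary is kept; sign is ignored
  expect_true(amplitude_validity(-5.5 * 2.249, 5.5)$valid)
  expect_false(amplitude_validity(5.5 * 2.25, 5.5)$valid)
  expect_error(amplitude_validity(11, 0), "positive")
})

test_that("integer distance is symmetric around integers and bounded", {
  f <- runif(500, 0, 4)
  d <- amplitude_validity(f * 3, 3)$integer_distance
  expect_true(all(d >= 0 & d <= 0.5 + 1e-12))
  d_up <- amplitude_validity((2 + 0.13) * 3, 3)$integer_distance
  d_dn <- amplitude_validity((2 - 0.13) * 3, 3)$integer_distance
  expect_equal(d_up, d_dn)
})

test_that("trial measures follow the window definitions", {
  p <- quiet_observer()
  tr <- simulate_gaze(1500, 11, params = p, seed = 21)
  truth <- attr(tr, "truth")
  m <- compute_trial_measures(tr, adaptation_onset_ms = 0,
                              target_onset_ms = 1500)
  expect_equal(m$latency_ms, truth$latency_ms, tolerance = 2.5)
  expect_equal(m$adaptation_ms, m$latency_ms + 1500)
  expect_equal(m$pre_fix_deg, 0, tolerance = 1e-6)
  expect_equal(m$post_fix_deg, 11, tolerance = 1e-6)
  expect_equal(m$amplitude_deg, 11, tolerance = 1e-6)
  expect_true(m$switch_within_saccade)
  expect_false(m$blink_in_window)
  expect_equal(m$fixation_sd, 0, tolerance = 1e-9)
  expect_equal(m$mask_onset_ms, m$trigger_ms + 400)
})

test_that("every violated exclusion rule is reported, per design", {
  spec1 <- experiment_spec(1)
  spec3 <- experiment_spec(3)
  base <- list(latency_ms = 200, amplitude_deg = 11, adaptation_ms = 1700,
               fixation_sd = 0.1, switch_within_saccade = TRUE,
               blink_in_window = FALSE)
  ok <- validate_trial(base, lambda_corr = 5.5, spec = spec1)
  expect_true(ok$valid)
  expect_length(ok$reasons, 0)

  unstable <- modifyList(base, list(fixation_sd = 0.6))
  expect_equal(validate_trial(unstable, 5.5, spec1)$reasons, "fixation_unstable")
  # boundary: exactly 0.5 is kept ("above 0.5" excludes)
  expect_true(validate_trial(modifyList(base, list(fixation_sd = 0.5)),
                             5.5, spec1)$valid)

  slow <- modifyList(base, list(latency_ms = 650))
  expect_equal(validate_trial(slow, 5.5, spec1)$reasons, "latency_too_long")
  # the latency rule does not apply to the constant-adaptation design
  slow3 <- modifyList(slow, list(adaptation_ms = 1500))
  expect_true(validate_trial(slow3, 5.5, spec3)$valid)

  dev3 <- modifyList(base, list(adaptation_ms = 1650))
  expect_equal(validate_trial(dev3, 5.5, spec3)$reasons,
               "adaptation_duration_deviant")
  expect_true(validate_trial(modifyList(base, list(adaptation_ms = 1600)),
                             5.5, spec3)$valid)

  # several rules violated at once: all reported, not short-circuited
  bad <- modifyList(base, list(fixation_sd = 0.8, amplitude_deg = 13.75,
                               blink_in_window = TRUE,
                               switch_within_saccade = FALSE))
  st <- validate_trial(bad, 5.5, spec1)
  expect_false(st$valid)
  expect_setequal(st$reasons, c("blink", "switch_outside_saccade",
                                "fixation_unstable", "amplitude_invalid"))
})

test_that("blinks invalidate trials and exclusions grow with landing error", {
  spec <- experiment_spec(1)
  always_blink <- quiet_observer(blink_prob = 1)
  # force blinks early in the trial so they fall before mask onset
  tr <- simulate_gaze(1500, 11, params = always_blink, seed = 2)
  expect_true(any(tr$blink))
  excl <- vapply(c(0.25, 1.0), function(sd) {
    p <- quiet_observer(landing_error_sd = sd)
    r <- generate_dataset(spec, 1, p, master_seed = 31)
    mean(grepl("amplitude_invalid", r$reasons, fixed = TRUE))
  }, numeric(1))
  expect_lt(excl[1], excl[2])
})

test_that("offline latency matches ground truth on simulated trials", {
  p <- quiet_observer()
  errs <- vapply(1:50, function(seed) {
    pair <- onset_pair(seed, p)
    pair["detected"] - pair["truth"]
  }, numeric(1))
  expect_true(all(abs(errs) <= 2))
})
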