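test_that("expected proportion reproduces the closed-form baseline values", {
  expect_equal(expected_proportion(-0.14, -0.14, 0.077, 0), 0.5)
  expect_equal(expected_proportion(-0.07, 0, 0.077, 0), pnorm(-0.07 / 0.077))
  expect_equal(expected_proportion(-0.07, 0, 0.077, 0), 0.18, tolerance = 0.01)
  x <- seq(-0.3, 0.3, by = 0.01)
  expect_true(all(diff(expected_proportion(x, -0.1, 0.08, 0.05)) > 0))
})

test_that("psychometric MLE recovers generating parameters", {
  # generate binomial responses on the 15-level design at printed group values
  levels <- seq(-0.28, 0.28, by = 0.04)
  x <- rep(levels, each = 32)  # 480 trials
  set.seed(101)
  r <- runif(length(x)) < expected_proportion(x, -0.14, 0.077, 0.02)
  fit <- fit_psychometric(x, r)
  expect_s3_class(fit, "psychometric_fit")
  expect_equal(fit$pse, -0.14, tolerance = 0.02)
  expect_equal(fit$jnd, 0.077, tolerance = 0.25 * 0.077)
  expect_true(fit$converged)
  expect_equal(fit$n_trials, 480)
  # likelihood at the optimum is no worse than at the generating parameters
  gen_ll <- sum(log(ifelse(r, expected_proportion(x, -0.14, 0.077, 0.02),
                           1 - expected_proportion(x, -0.14, 0.077, 0.02))))
  expect_gte(fit$loglik, gen_ll - 1e-6)
})

test_that("fits are deterministic and symmetric data give PSE near zero", {
  levels <- seq(-0.2, 0.2, by = 0.05)
  x <- rep(levels, each = 20)
  # perfectly symmetric response pattern around 0
  r <- unlist(lapply(levels, function(l) {
    k <- round(20 * pnorm(l / 0.08))
    c(rep(TRUE, k), rep(FALSE, 20 - k))
  }))
  f1 <- fit_psychometric(x, r)
  f2 <- fit_psychometric(x, r)
  expect_identical(f1[c("pse", "jnd", "lapse")], f2[c("pse", "jnd", "lapse")])
  expect_equal(f1$pse, 0, tolerance = 0.01)
})

test_that("degenerate response sets are rejected with a diagnostic", {
  expect_error(fit_psychometric(rep(c(-0.1, 0.1), 10), rep(TRUE, 20)),
               "degenerate")
  expect_error(fit_psychometric(rep(0.1, 20), runif(20) > 0.5),
               "distinct")
})

test_that("bootstrap CIs cover the point estimate", {
  levels <- seq(-0.28, 0.28, by = 0.04)
  x <- rep(levels, each = 16)
  set.seed(7)
  r <- runif(length(x)) < expected_proportion(x, -0.1, 0.08, 0)
  fit <- fit_psychometric(x, r, n_boot = 60, boot_seed = 3)
  expect_true(fit$ci["2.5%", "pse"] <= fit$pse &&
                fit$pse <= fit$ci["97.5%", "pse"])
  expect_true(all(fit$ci[, "jnd"] > 0))
})

test_that("running average equals the brute-force bin enumeration", {
  set.seed(55)
  for (rep_i in 1:8) {
    n <- sample(30:250, 1)
    d <- round(runif(n, 0, 1400))
    r <- runif(n) < 0.4 + d / 4000
    got <- running_average(d, r)
    want <- running_average_oracle(d, r)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$bin_center, unname(want[, "center"]))
    expect_equal(got$n, unname(want[, "n"]))
    expect_equal(got$proportion, unname(want[, "prop"]))
  }
})

test_that("running-average edge cases follow the quoted scheme", {
  # uniform positive responses give a curve identically 1
  d <- seq(10, 1390, by = 20)
  ra <- running_average(d, rep(TRUE, length(d)))
  expect_true(all(ra$proportion == 1))
  # a single trial at 50 ms appears in every growing bin (all anchored at
  # 0, ends 150..300) plus the sliding bins that still cover 50 ms, all
  # with proportion 1
  one <- running_average(50, TRUE)
  expect_true(all(one$proportion == 1))
  grow <- one[one$bin_start == 0, ]
  expect_equal(grow$bin_end, 150:300)
  expect_true(all(one$bin_start <= 50 & one$bin_end >= 50))
  # full scheme emits 1401 bins when every bin is populated
  dense <- running_average(0:1400, rep(TRUE, 1401))
  expect_equal(nrow(dense), 1401)
  expect_true(all(diff(dense$bin_center) > 0))
})

test_that("log decay fit is exact on noiseless points and matches algebra", {
  blanks <- c(100, 200, 400, 800, 1600)
  y <- 0.02 * log(blanks) - 0.20
  fit <- fit_log_decay(blanks, y)
  expect_equal(fit$A, 0.02, tolerance = 1e-12)
  expect_equal(fit$B, -0.20, tolerance = 1e-12)
  expect_equal(max(abs(fit$residuals)), 0, tolerance = 1e-12)
  # two points determine (A, B): compare to the closed-form solution
  b2 <- c(100, 1600); y2 <- c(-0.11, -0.06)
  f2 <- fit_log_decay(b2, y2)
  A_cf <- diff(y2) / diff(log(b2))
  expect_equal(f2$A, A_cf, tolerance = 1e-12)
  expect_equal(f2$B, y2[1] - A_cf * log(b2[1]), tolerance = 1e-12)
  expect_equal(predict(f2, 400), A_cf * log(400) + f2$B)
  # blank 0 is excluded from the domain and reported as the anchor
  f3 <- fit_log_decay(c(0, blanks), c(-0.12, y))
  expect_equal(nrow(f3$domain), 5)
  expect_equal(f3$anchor_pse, -0.12)
  expect_error(fit_log_decay(c(400, 400), c(-0.1, -0.2)), "distinct")
  # fitted magnitude decreases with blank when A > 0 and pse < 0
  expect_lt(abs(predict(fit, 1600)), abs(predict(fit, 100)))
})

test_that("t tests match closed forms and the pooled df convention", {
  v <- c(-0.12, -0.15, -0.10, -0.18, -0.13)
  res <- t_test(v, mode = "one-sample", tail = "less")
  t_hand <- mean(v) / (sd(v) / sqrt(5))
  expect_equal(res$t, t_hand, tolerance = 1e-10)
  expect_equal(res$df, 4)
  expect_equal(res$p, pt(t_hand, 4), tolerance = 1e-10)
  # pooled two-sample df = n1 + n2 - 2 (16 and 7 give 21)
  set.seed(4)
  a <- rnorm(16); b <- rnorm(7)
  res2 <- t_test(a, b, mode = "two-sample")
  expect_equal(res2$df, 21)
  sp2 <- (15 * var(a) + 6 * var(b)) / 21
  t2_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 16 + 1 / 7))
  expect_equal(res2$t, t2_hand, tolerance = 1e-10)
  # paired equals one-sample on differences
  x <- rnorm(10); y <- rnorm(10)
  expect_equal(t_test(x, y, mode = "paired")$t,
               t_test(x - y, mode = "one-sample")$t, tolerance = 1e-12)
  expect_error(t_test(rep(-1, 4), mode = "one-sample"), "degenerate")
})

test_that("subset fits partition trials and recover per-level differences", {
  spec <- experiment_spec(1)
  p <- quiet_observer(position_bias = -0.06)
  rec <- generate_dataset(spec, 1, p, master_seed = 17)
  valid <- rec[rec$valid, ]
  fits <- subset_fits(rec, "correlated_position")
  expect_equal(sum(fits$n), nrow(valid))
  expect_true(all(is.na(fits$error)))
  d_pse <- fits$pse[fits$level == "lower"] - fits$pse[fits$level == "upper"]
  expect_lt(abs(d_pse - (-0.06)), 0.03)
  # a homogeneous split shows no effect beyond noise
  p0 <- quiet_observer()
  rec0 <- generate_dataset(spec, 1, p0, master_seed = 18)
  fits0 <- subset_fits(rec0, "f_anti")
  expect_lt(abs(diff(fits0$pse)), 0.03)
})
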