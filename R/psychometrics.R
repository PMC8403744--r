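# Response-data analysis: maximum-likelihood cumulative-Gaussian
# psychometric fits (PSE/JND with a symmetric lapse), the growing/sliding
# running-average build-up curve, the logarithmic decay fit, subset fits
# and t-test wrappers.

#' Expected proportion of anticorrelated-higher responses
#'
#' Lapse-bounded cumulative Gaussian evaluated at a contrast difference:
#' `lapse/2 + (1 - lapse) * pnorm((delta_c - pse) / jnd)`.
#'
#' @param delta_c contrast difference(s).
#' @param pse point of subjective equality.
#' @param jnd spread (SD) of the cumulative Gaussian, > 0.
#' @param lapse symmetric lapse rate.
#' @return Expected proportion(s).
#' @export
expected_proportion <- function(delta_c, pse, jnd, lapse = 0) {
  response_probability(delta_c, pse, jnd, lapse)
}

# negative log-likelihood of (mu, log sigma, lapse)
.pf_nll <- function(par, x, k, n) {
  mu <- par[1]; sigma <- exp(par[2]); lapse <- par[3]
  p <- lapse / 2 + (1 - lapse) * stats::pnorm((x - mu) / sigma)
  p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
  -sum(k * log(p) + (n - k) * log(1 - p))
}

.fit_pf_once <- function(x, k, n, lapse_max) {
  # deterministic multi-start: quantile-based location guesses crossed with
  # scale guesses, so the fit depends only on the data
  prop <- k / n
  wmean <- sum(x * n) / sum(n)
  span <- max(diff(range(x)), 1e-3)
  mu0 <- c(wmean, x[which.min(abs(prop - 0.5))])
  sig0 <- span * c(0.1, 0.25, 0.5)
  starts <- expand.grid(mu = unique(mu0), lsig = log(sig0),
                        lapse = c(0.01, 0.05))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(unlist(starts[i, ]), .pf_nll, x = x, k = k, n = n,
                   method = "L-BFGS-B",
                   lower = c(min(x) - 2 * span, log(span * 1e-3), 0),
                   upper = c(max(x) + 2 * span, log(span * 5), lapse_max)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  best
}

#' Fit a cumulative-Gaussian psychometric function
#'
#' Maximum-likelihood fit of `P(anticorrelated higher) = lapse/2 +
#' (1 - lapse) * pnorm((delta_c - pse) / jnd)` to binary 2AFC responses,
#' with the symmetric lapse bounded in `[0, lapse_max]`. The PSE is the
#' location (50% point with no lapse) and the JND the SD of the Gaussian.
#' Optimisation uses bounded quasi-Newton from a deterministic set of
#' starting points, so the fit is reproducible given the data. Optional
#' nonparametric bootstrap (resampling trials) yields percentile CIs.
#'
#' @param delta_c numeric vector of tested contrast differences.
#' @param response logical/0-1 vector, `TRUE` = anticorrelated judged
#'   higher.
#' @param lapse_max upper bound of the lapse rate (default 0.1).
#' @param n_boot bootstrap replicates for CIs (default 0 = no CIs).
#' @param conf confidence level of bootstrap CIs.
#' @param boot_seed seed of the bootstrap resampling stream.
#' @return An object of class `psychometric_fit`: `pse`, `jnd`, `lapse`,
#'   `guess` (= lapse/2), `loglik`, `n_trials`, `levels`, `ci` (matrix or
#'   `NULL`), `converged`.
#' @export
fit_psychometric <- function(delta_c, response, lapse_max = 0.1,
                             n_boot = 0, conf = 0.95, boot_seed = 1L) {
  stopifnot(length(delta_c) == length(response))
  response <- as.logical(response)
  keep <- !is.na(delta_c) & !is.na(response)
  delta_c <- delta_c[keep]; response <- response[keep]
  x <- sort(unique(delta_c))
  if (length(x) < 2)
    stop("need at least 2 distinct contrast-difference levels")
  if (all(response) || !any(response))
    stop("degenerate fit: all responses identical (proportion ",
         mean(response), "); the psychometric function is unconstrained")
  k <- vapply(x, function(v) sum(response[delta_c == v]), numeric(1))
  n <- vapply(x, function(v) sum(delta_c == v), numeric(1))

  best <- .fit_pf_once(x, k, n, lapse_max)
  if (is.null(best)) stop("psychometric fit failed to converge")

  ci <- NULL
  if (n_boot > 0) {
    rng <- local_rng(derive_seed(boot_seed, "pfboot"))
    nt <- length(delta_c)
    boots <- matrix(NA_real_, n_boot, 2,
                    dimnames = list(NULL, c("pse", "jnd")))
    for (b in seq_len(n_boot)) {
      idx <- rng$integer(nt, nt)
      xb <- delta_c[idx]; rb <- response[idx]
      ub <- sort(unique(xb))
      if (length(ub) < 2 || all(rb) || !any(rb)) next
      kb <- vapply(ub, function(v) sum(rb[xb == v]), numeric(1))
      nb <- vapply(ub, function(v) sum(xb == v), numeric(1))
      fb <- .fit_pf_once(ub, kb, nb, lapse_max)
      if (!is.null(fb)) boots[b, ] <- c(fb$par[1], exp(fb$par[2]))
    }
    a <- (1 - conf) / 2
    ci <- apply(boots, 2, stats::quantile, probs = c(a, 1 - a), na.rm = TRUE)
  }

  structure(
    list(pse = unname(best$par[1]), jnd = unname(exp(best$par[2])),
         lapse = unname(best$par[3]), guess = unname(best$par[3] / 2),
         loglik = -best$value, n_trials = length(delta_c),
         levels = tibble::tibble(delta_c = x, n = n, k = k, prop = k / n),
         ci = ci, converged = best$convergence == 0),
    class = "psychometric_fit")
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf("<psychometric_fit> PSE %.4f, JND %.4f, lapse %.3f (n = %d)\n",
              x$pse, x$jnd, x$lapse, x$n_trials))
  invisible(x)
}

#' Running average of responses over adaptation duration
#'
#' Computes the proportion of anticorrelated-higher responses in a sequence
#' of overlapping bins spanning `[0, 1400]` ms: the first bin is `[0, 150]`
#' and grows by 1 ms (anchored at 0) until the full 300 ms width is reached
#' (`[0, 300]`); then a 300 ms bin slides in 1 ms steps; at the end of the
#' range the procedure is mirrored, bins shrinking while anchored at
#' 1400 ms, down to `[1250, 1400]`. Each emitted point carries the bin mean
#' (midpoint) as its abscissa. Empty bins are omitted.
#'
#' @param duration_ms adaptation durations (ms).
#' @param response logical/0-1 responses.
#' @param bin_ms full bin width (default 300).
#' @param step_ms bin step (default 1).
#' @param range_ms analysis range (default `c(0, 1400)`).
#' @return A tibble with `bin_start`, `bin_end`, `bin_center`, `n`,
#'   `proportion`.
#' @export
running_average <- function(duration_ms, response, bin_ms = 300, step_ms = 1,
                            range_ms = c(0, 1400)) {
  stopifnot(length(duration_ms) == length(response))
  response <- as.numeric(response)
  lo <- range_ms[1]; hi <- range_ms[2]
  half <- bin_ms / 2
  grow_ends <- seq(lo + half, lo + bin_ms, by = step_ms)
  starts <- c(rep(lo, length(grow_ends)),
              seq(lo + step_ms, hi - bin_ms, by = step_ms),
              seq(hi - bin_ms + step_ms, hi - half, by = step_ms))
  ends <- c(grow_ends,
            seq(lo + bin_ms + step_ms, hi, by = step_ms),
            rep(hi, length(seq(hi - bin_ms + step_ms, hi - half, by = step_ms))))

  ord <- order(duration_ms)
  d <- duration_ms[ord]; r <- response[ord]
  csum <- c(0, cumsum(r))
  # counts in [start, end] via binary search on the sorted durations
  i_lo <- findInterval(starts - 1e-9, d)      # index of last d < start
  i_hi <- findInterval(ends + 1e-9, d)        # index of last d <= end
  n_in <- i_hi - i_lo
  k_in <- csum[i_hi + 1] - csum[i_lo + 1]
  keep <- n_in > 0
  tibble::tibble(
    bin_start = starts[keep], bin_end = ends[keep],
    bin_center = (starts[keep] + ends[keep]) / 2,
    n = n_in[keep], proportion = k_in[keep] / n_in[keep])
}

#' Fit the logarithmic decay of the PSE over blank duration
#'
#' Least-squares fit of `pse = A * log(blank_ms) + B` (natural log) over
#' blanks of at least `min_blank_ms` (the model is undefined at 0; the
#' no-blank PSE is reported separately as the anchor, not fitted).
#'
#' @param blank_ms blank durations (ms).
#' @param pse PSE values.
#' @param min_blank_ms smallest blank included in the fit domain
#'   (default 100).
#' @return An object of class `decay_fit`: `A`, `B`, `fitted`, `residuals`,
#'   `domain` (tibble of the points used), `anchor_pse` (mean PSE at blanks
#'   below the domain, `NA` if none).
#' @export
fit_log_decay <- function(blank_ms, pse, min_blank_ms = 100) {
  stopifnot(length(blank_ms) == length(pse))
  in_dom <- blank_ms >= min_blank_ms & !is.na(pse)
  if (sum(in_dom) < 2 || length(unique(blank_ms[in_dom])) < 2)
    stop("need at least 2 distinct positive blank durations in the fit domain")
  lx <- log(blank_ms[in_dom])
  fit <- stats::lm(pse[in_dom] ~ lx)
  anchor <- if (any(!in_dom & !is.na(pse)))
    mean(pse[!in_dom & !is.na(pse)]) else NA_real_
  structure(
    list(A = unname(stats::coef(fit)[2]), B = unname(stats::coef(fit)[1]),
         fitted = unname(stats::fitted(fit)),
         residuals = unname(stats::residuals(fit)),
         domain = tibble::tibble(blank_ms = blank_ms[in_dom],
                                 pse = pse[in_dom]),
         anchor_pse = anchor),
    class = "decay_fit")
}

#' Predict from a logarithmic decay fit
#'
#' @param object a `decay_fit`.
#' @param blank_ms blank durations (ms, > 0).
#' @param ... unused.
#' @return Predicted PSE values `A * log(blank_ms) + B`.
#' @export
predict.decay_fit <- function(object, blank_ms, ...) {
  stopifnot(all(blank_ms > 0))
  object$A * log(blank_ms) + object$B
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("<decay_fit> pse = %.4f * log(blank_ms) + %.4f (%d points)\n",
              x$A, x$B, nrow(x$domain)))
  invisible(x)
}

#' t tests in the conventions of the analysis
#'
#' Thin wrapper over [stats::t.test()] returning the statistic, degrees of
#' freedom and p value: one-sample (against `mu`), paired, or two-sample
#' with pooled variance (so unequal group sizes n1, n2 give
#' `df = n1 + n2 - 2`).
#'
#' @param x numeric sample.
#' @param y second sample (paired / two-sample modes).
#' @param mode one of `"one-sample"`, `"paired"`, `"two-sample"`.
#' @param tail `"two.sided"`, `"less"` or `"greater"`.
#' @param mu null value for the one-sample test.
#' @return A list with `t`, `df`, `p`, `mean` (of `x`, or of differences
#'   for paired), `mode`.
#' @export
t_test <- function(x, y = NULL,
                   mode = c("one-sample", "paired", "two-sample"),
                   tail = c("two.sided", "less", "greater"), mu = 0) {
  mode <- match.arg(mode)
  tail <- match.arg(tail)
  degenerate <- function(v) length(v) >= 2 && stats::sd(v) == 0
  res <- switch(mode,
    "one-sample" = {
      if (degenerate(x)) stop("degenerate t test: zero variance in sample")
      stats::t.test(x, mu = mu, alternative = tail)
    },
    "paired" = {
      stopifnot(!is.null(y), length(x) == length(y))
      if (degenerate(x - y)) stop("degenerate t test: zero variance of differences")
      stats::t.test(x, y, paired = TRUE, alternative = tail)
    },
    "two-sample" = {
      stopifnot(!is.null(y))
      stats::t.test(x, y, var.equal = TRUE, alternative = tail)
    })
  m <- if (mode == "paired") mean(x - y) else mean(x)
  list(t = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value, mean = m, mode = mode)
}

#' Psychometric fits on subsets of the trial records
#'
#' Splits the valid trials by a design factor (e.g. `f_anti`,
#' `correlated_position`, `slice_condition`, `blank_ms`) and fits one
#' psychometric function per level and participant. Fit errors in one
#' level (e.g. too few levels after splitting) are reported per level
#' without aborting the others.
#'
#' @param records trial-record tibble from [generate_dataset()].
#' @param split_by name of the factor column.
#' @param by_participant if `TRUE` (default) fit per participant x level,
#'   else pool participants.
#' @param valid_only drop invalid trials first (default `TRUE`).
#' @return A tibble with `participant` (if applicable), `level`, `pse`,
#'   `jnd`, `lapse`, `n`, `error` (NA when the fit succeeded).
#' @export
subset_fits <- function(records, split_by, by_participant = TRUE,
                        valid_only = TRUE) {
  stopifnot(split_by %in% names(records))
  if (valid_only) records <- records[records$valid, , drop = FALSE]
  group_cols <- if (by_participant) c("participant", split_by) else split_by
  key <- interaction(records[group_cols], drop = TRUE)
  parts <- split(records, key)
  rows <- lapply(parts, function(d) {
    fit <- tryCatch(fit_psychometric(d$delta_c, d$response),
                    error = function(e) e)
    failed <- inherits(fit, "error")
    tibble::tibble(
      participant = if (by_participant) d$participant[1] else NA_integer_,
      level = as.character(d[[split_by]][1]),
      pse = if (failed) NA_real_ else fit$pse,
      jnd = if (failed) NA_real_ else fit$jnd,
      lapse = if (failed) NA_real_ else fit$lapse,
      n = nrow(d),
      error = if (failed) conditionMessage(fit) else NA_character_)
  })
  out <- do.call(rbind, rows)
  out[order(out$participant, out$level), ]
}
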