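## Point prevalence, binomial confidence intervals, and the precision-based
## sample-size formula for prevalence surveys.

#' Point prevalence
#'
#' @param k case count.
#' @param n screened count (> 0).
#' @return `k / n`.
#' @examples
#' point_prevalence(200, 9407)  # 0.02126...
#' @export
point_prevalence <- function(k, n) {
  if (any(n <= 0)) abort_domain("n must be positive")
  if (any(k < 0) || any(k > n)) abort_domain("k must satisfy 0 <= k <= n")
  k / n
}

new_interval_estimate <- function(point, lower, upper, method, confidence) {
  structure(list(point = point, lower = lower, upper = upper,
                 method = method, confidence = confidence),
            class = "interval_estimate")
}

#' @export
print.interval_estimate <- function(x, ...) {
  cat(sprintf("%s %.0f%% CI: %.4f (%.4f, %.4f)\n",
              x$method, 100 * x$confidence, x$point, x$lower, x$upper))
  invisible(x)
}

#' @export
format.interval_estimate <- function(x, decimals = 1, ...) {
  paste0(format_percent(x$lower, decimals, symbol = FALSE), "–",
         format_percent(x$upper, decimals, symbol = FALSE), "%")
}

check_ci_args <- function(k, n, confidence) {
  if (n <= 0) abort_domain("n must be positive")
  if (k < 0 || k > n) abort_domain("k must satisfy 0 <= k <= n")
  if (confidence <= 0 || confidence >= 1)
    abort_domain("confidence must lie in (0, 1)")
}

#' Wald (normal-approximation) binomial confidence interval
#'
#' p +/- z * sqrt(p(1-p)/n), clipped to \[0, 1\]. This is the method that
#' reproduces, at 1-decimal percent rendering with half-up rounding, every
#' printed confidence interval of the packaged case-series tables.
#'
#' @param k count of successes.
#' @param n total count.
#' @param confidence confidence level in (0, 1).
#' @return an `interval_estimate` (point, lower, upper, method, confidence).
#' @examples
#' wald_interval(105, 200)  # 45.6--59.4% at 1 dp
#' @export
wald_interval <- function(k, n, confidence = 0.95) {
  check_ci_args(k, n, confidence)
  p <- k / n
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  me <- z * sqrt(p * (1 - p) / n)
  new_interval_estimate(p, max(p - me, 0), min(p + me, 1),
                        "wald", confidence)
}

#' Wilson score binomial confidence interval
#'
#' Score-test inversion bounds; never degenerate at k = 0 or k = n and with
#' lower bound strictly positive whenever k > 0.
#'
#' @inheritParams wald_interval
#' @return an `interval_estimate`.
#' @export
wilson_interval <- function(k, n, confidence = 0.95) {
  check_ci_args(k, n, confidence)
  p <- k / n
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  z2 <- z^2
  centre <- (p + z2 / (2 * n)) / (1 + z2 / n)
  half <- z * sqrt(p * (1 - p) / n + z2 / (4 * n^2)) / (1 + z2 / n)
  new_interval_estimate(p, max(centre - half, 0), min(centre + half, 1),
                        "wilson", confidence)
}

#' Clopper–Pearson exact binomial confidence interval
#'
#' Exact tail-inversion interval, delegated to [stats::binom.test()].
#'
#' @inheritParams wald_interval
#' @return an `interval_estimate`.
#' @export
clopper_pearson_interval <- function(k, n, confidence = 0.95) {
  check_ci_args(k, n, confidence)
  ci <- stats::binom.test(k, n, conf.level = confidence)$conf.int
  new_interval_estimate(k / n, ci[1], ci[2], "clopper_pearson", confidence)
}

#' Binomial confidence interval with selectable method
#'
#' @inheritParams wald_interval
#' @param method one of `"wald"` (default; matches the printed tables),
#'   `"wilson"`, `"clopper_pearson"`.
#' @return an `interval_estimate`.
#' @export
binom_interval <- function(k, n, confidence = 0.95,
                           method = c("wald", "wilson", "clopper_pearson")) {
  method <- match.arg(method)
  switch(method,
         wald = wald_interval(k, n, confidence),
         wilson = wilson_interval(k, n, confidence),
         clopper_pearson = clopper_pearson_interval(k, n, confidence))
}

#' Sample size for a prevalence survey (Daniel's formula)
#'
#' n = ceil(z^2 p (1 - p) / d^2), where p is the expected prevalence and d
#' the absolute precision, inflated by 1/(1 - loss) for anticipated loss to
#' follow-up. The precision d has no default: it must be stated by the user.
#'
#' @param expected_prevalence anticipated prevalence fraction in (0, 1).
#' @param absolute_precision half-width d of the desired confidence interval,
#'   on the fraction scale, in (0, 1).
#' @param confidence confidence level in (0, 1), default 0.95.
#' @param loss_to_followup anticipated loss fraction in \[0, 1); 0 disables
#'   inflation.
#' @return integer sample size.
#' @examples
#' daniel_sample_size(0.5, 0.05)    # 385
#' daniel_sample_size(0.057, 0.005) # 8260
#' @export
daniel_sample_size <- function(expected_prevalence, absolute_precision,
                               confidence = 0.95, loss_to_followup = 0) {
  p <- expected_prevalence
  d <- absolute_precision
  if (p <= 0 || p >= 1) abort_domain("expected_prevalence must be in (0, 1)")
  if (d <= 0 || d >= 1) abort_domain("absolute_precision must be in (0, 1)")
  if (confidence <= 0 || confidence >= 1)
    abort_domain("confidence must be in (0, 1)")
  if (loss_to_followup < 0 || loss_to_followup >= 1)
    abort_domain("loss_to_followup must be in [0, 1)")
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  n <- z^2 * p * (1 - p) / d^2
  if (loss_to_followup > 0) n <- n / (1 - loss_to_followup)
  as.integer(ceiling(n))
}
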