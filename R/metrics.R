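#' Wilson score confidence interval for a binomial proportion
#'
#' Closed-form Wilson interval: for observed k successes out of n,
#' centre (k + z^2/2)/(n + z^2) with half-width
#' z * sqrt(k(n-k)/n + z^2/4) / (n + z^2). Asymmetric near 0 and 1 and
#' never escapes `[0, 1]`, which is why it is the interval of choice for
#' sensitivities and specificities close to 100%.
#'
#' @param k Number of successes, `0 <= k <= n`.
#' @param n Number of trials, `>= 1`.
#' @param level Confidence level, default 0.95.
#' @return Numeric length-2 vector `(lower, upper)`.
#' @examples
#' wilson_ci(50, 100)
#' @export
wilson_ci <- function(k, n, level = 0.95) {
  if (n < 1 || k < 0 || k > n) {
    stop("wilson_ci requires 0 <= k <= n and n >= 1", call. = FALSE)
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- k / n
  denom <- n + z^2
  centre <- (k + z^2 / 2) / denom
  half <- z * sqrt(k * (n - k) / n + z^2 / 4) / denom
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

#' Diagnostic accuracy of a binary prediction
#'
#' Standard 2x2-table metrics — sensitivity, specificity, negative and
#' positive predictive values — each with a Wilson 95% confidence
#' interval. A metric with a zero denominator (e.g. PPV when nothing is
#' predicted positive) is reported as `NA` and listed in `undefined`,
#' never silently set to 0.
#'
#' @param predicted_positive Logical vector of predictions.
#' @param outcome Logical vector of true outcomes, same length.
#' @param level Confidence level for the Wilson intervals.
#' @return A `"diagnostic_metrics"` list: counts `tp`, `fp`, `tn`, `fn`
#'   and per-metric lists `estimate`, `ci`.
#' @export
diagnostic_metrics <- function(predicted_positive, outcome,
                               level = 0.95) {
  if (length(predicted_positive) != length(outcome) ||
      length(outcome) == 0) {
    stop("predicted_positive and outcome must be equal-length, non-empty",
         call. = FALSE)
  }
  stopifnot(is.logical(predicted_positive), is.logical(outcome),
            !anyNA(predicted_positive), !anyNA(outcome))
  tp <- sum(predicted_positive & outcome)
  fp <- sum(predicted_positive & !outcome)
  tn <- sum(!predicted_positive & !outcome)
  fn <- sum(!predicted_positive & outcome)
  one <- function(k, n) {
    if (n == 0) {
      list(estimate = NA_real_, ci = c(lower = NA_real_,
                                       upper = NA_real_))
    } else {
      list(estimate = k / n, ci = wilson_ci(k, n, level))
    }
  }
  metrics <- list(sensitivity = one(tp, tp + fn),
                  specificity = one(tn, tn + fp),
                  npv = one(tn, tn + fn),
                  ppv = one(tp, tp + fp))
  structure(
    c(list(tp = tp, fp = fp, tn = tn, fn = fn,
           n = length(outcome),
           undefined = names(metrics)[vapply(metrics, function(m)
             is.na(m$estimate), logical(1))]),
      metrics),
    class = "diagnostic_metrics")
}

#' @export
print.diagnostic_metrics <- function(x, ...) {
  cat(sprintf("2x2: TP %d  FP %d  TN %d  FN %d (n = %d)\n",
              x$tp, x$fp, x$tn, x$fn, x$n))
  for (m in c("sensitivity", "specificity", "npv", "ppv")) {
    v <- x[[m]]
    if (is.na(v$estimate)) {
      cat(sprintf("  %-12s undefined (zero denominator)\n", m))
    } else {
      cat(sprintf("  %-12s %5.1f%% (%.1f-%.1f)\n", m, 100 * v$estimate,
                  100 * v$ci[1], 100 * v$ci[2]))
    }
  }
  invisible(x)
}

#' Format a count as the percentage it represents
#'
#' The cohort-summary convention used throughout reports: `k/n`
#' displayed as a percentage rounded to one decimal place.
#'
#' @param k,n Counts.
#' @param digits Decimal places (default 1).
#' @return Numeric percentage, rounded.
#' @examples
#' count_percent(39, 179)  # 21.8
#' @export
count_percent <- function(k, n, digits = 1) {
  stopifnot(n > 0)
  round(100 * k / n, digits)
}
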