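#' Empirical ROC analysis of predicted probabilities
#'
#' Builds the empirical ROC curve of a continuous (here: discrete-valued)
#' predictor against a binary outcome. Thresholds are the distinct
#' predicted values, ascending; at each threshold t the prediction is
#' positive when value >= t. The AUC is computed in its Mann-Whitney
#' form, U / (n1 * n0) with ties counted 1/2 — the probability that a
#' random case outranks a random control — and its 95% CI by the DeLong
#' method.
#'
#' @param scores Numeric vector of predicted probabilities (or any
#'   monotone risk score).
#' @param outcome Logical vector: postnatally confirmed CoAo?
#' @param level Confidence level for the AUC CI.
#' @return A `"roc_analysis"` list: `thresholds`, `sensitivity`,
#'   `specificity` (parallel vectors), `auc`, `auc_ci`, `n_pos`,
#'   `n_neg`, and the input `scores`/`outcome` (used by
#'   [select_cutoff()]).
#' @export
empirical_roc <- function(scores, outcome, level = 0.95) {
  stopifnot(is.numeric(scores), is.logical(outcome),
            length(scores) == length(outcome), !anyNA(scores),
            !anyNA(outcome))
  n_pos <- sum(outcome)
  n_neg <- sum(!outcome)
  if (n_pos == 0 || n_neg == 0) {
    stop("ROC analysis requires both outcome classes present",
         call. = FALSE)
  }
  thresholds <- sort(unique(scores))
  sens <- vapply(thresholds, function(t) mean(scores[outcome] >= t),
                 numeric(1))
  spec <- vapply(thresholds, function(t) mean(scores[!outcome] < t),
                 numeric(1))
  structure(
    list(thresholds = thresholds, sensitivity = sens,
         specificity = spec,
         auc = auc_mann_whitney(scores, outcome),
         auc_ci = delong_auc_ci(scores, outcome, level),
         n_pos = n_pos, n_neg = n_neg,
         scores = scores, outcome = outcome),
    class = "roc_analysis")
}

#' Mann-Whitney AUC
#'
#' AUC as the scaled rank-sum statistic: with midranks, ties between a
#' case and a control count 1/2.
#'
#' @inheritParams empirical_roc
#' @return AUC in `[0, 1]`.
#' @export
auc_mann_whitney <- function(scores, outcome) {
  n1 <- sum(outcome)
  n0 <- sum(!outcome)
  r <- rank(scores)  # midranks
  (sum(r[outcome]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Trapezoidal AUC from ROC operating points
#'
#' Integrates the empirical ROC polygon (including the (0,0) and (1,1)
#' endpoints). Equals [auc_mann_whitney()] exactly; kept as the
#' geometric route for cross-validation of the ROC machinery.
#'
#' @param roc A `"roc_analysis"`.
#' @return AUC in `[0, 1]`.
#' @export
auc_trapezoid <- function(roc) {
  stopifnot(inherits(roc, "roc_analysis"))
  fpr <- c(1 - roc$specificity, 0)
  tpr <- c(roc$sensitivity, 0)
  ord <- order(fpr, tpr)
  fpr <- fpr[ord]
  tpr <- tpr[ord]
  sum(diff(fpr) * (head_(tpr) + tail_(tpr)) / 2)
}

head_ <- function(x) x[-length(x)]
tail_ <- function(x) x[-1]

# DeLong (1988) variance of the Mann-Whitney AUC via placement values.
delong_auc_ci <- function(scores, outcome, level = 0.95) {
  x <- scores[outcome]
  y <- scores[!outcome]
  m <- length(x)
  n <- length(y)
  psi <- function(a, b) (a > b) + 0.5 * (a == b)
  v10 <- vapply(x, function(xi) mean(psi(xi, y)), numeric(1))
  v01 <- vapply(y, function(yj) mean(psi(x, yj)), numeric(1))
  auc <- mean(v10)
  v <- 0
  if (m > 1) v <- v + stats::var(v10) / m
  if (n > 1) v <- v + stats::var(v01) / n
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(lower = max(0, auc - z * sqrt(v)),
    upper = min(1, auc + z * sqrt(v)))
}

#' Select an operating cut-off from a ROC analysis
#'
#' Three selection rules mirroring the clinical report:
#' * `best_balance` — maximize the Youden index J = Sn + Sp - 1, breaking
#'   ties toward higher specificity (fewer false referrals);
#' * `max_sensitivity` — among thresholds attaining the maximal
#'   sensitivity, the one with highest specificity;
#' * `max_specificity` — among thresholds attaining the maximal
#'   specificity with sensitivity > 0, the one with highest sensitivity.
#'
#' The returned threshold is an attained score value; prediction is
#' positive when score >= threshold.
#'
#' @param roc A `"roc_analysis"` from [empirical_roc()].
#' @param criterion One of `"best_balance"`, `"max_sensitivity"`,
#'   `"max_specificity"`.
#' @return A `"cutoff_report"`: `criterion`, `threshold`,
#'   `threshold_percent` (display value, rounded half-to-even),
#'   `sensitivity`, `specificity`, and full [diagnostic_metrics()] at
#'   the threshold.
#' @export
select_cutoff <- function(roc, criterion = c("best_balance",
                                             "max_sensitivity",
                                             "max_specificity")) {
  stopifnot(inherits(roc, "roc_analysis"))
  criterion <- match.arg(criterion)
  sn <- roc$sensitivity
  sp <- roc$specificity
  idx <- switch(
    criterion,
    best_balance = {
      j <- sn + sp - 1
      cand <- which(j == max(j))
      cand[which.max(sp[cand])]
    },
    max_sensitivity = {
      cand <- which(sn == max(sn))
      cand[which.max(sp[cand])]
    },
    max_specificity = {
      ok <- sn > 0
      cand <- which(ok & sp == max(sp[ok]))
      cand[which.max(sn[cand])]
    })
  thr <- roc$thresholds[idx]
  metrics <- diagnostic_metrics(roc$scores >= thr, roc$outcome)
  structure(
    list(criterion = criterion, threshold = thr,
         threshold_percent = round(100 * thr),
         sensitivity = sn[idx], specificity = sp[idx],
         metrics = metrics),
    class = "cutoff_report")
}

#' @export
print.roc_analysis <- function(x, ...) {
  cat(sprintf(
    "Empirical ROC: %d cases / %d controls, %d thresholds\n",
    x$n_pos, x$n_neg, length(x$thresholds)))
  cat(sprintf("  AUC %.3f (%.2f-%.2f)\n", x$auc, x$auc_ci[1],
              x$auc_ci[2]))
  invisible(x)
}

#' @export
print.cutoff_report <- function(x, ...) {
  cat(sprintf("Cut-off (%s): >= %.4f (%d%%)  Sn %.1f%%  Sp %.1f%%\n",
              x$criterion, x$threshold, x$threshold_percent,
              100 * x$sensitivity, 100 * x$specificity))
  invisible(x)
}
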