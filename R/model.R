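#' Likelihood-ratio entry for one score parameter
#'
#' One row of the scoring model: a dichotomizing cut-off on an
#' echocardiographic (or gestational-age) parameter together with the
#' positive and negative likelihood ratios applied when the criterion is
#' met or not met.
#'
#' @param parameter_id One of `"ga_weeks"`, `"aao_zscore"`,
#'   `"isthmus_3vt_zscore"`, `"pv_av_ratio"`.
#' @param cutoff Cut-off value (weeks, z-units or unitless ratio).
#' @param direction `"le"` (criterion positive when value <= cutoff) or
#'   `"ge"` (positive when value >= cutoff). Boundaries are inclusive.
#' @param lr_positive,lr_negative Positive reals; `lr_positive` must exceed
#'   `lr_negative` (a criterion can only raise the odds when met).
#' @param lr_positive_ci,lr_negative_ci Optional length-2 numeric 95% CIs.
#'
#' @return An object of class `"lr_entry"`.
#' @export
lr_entry <- function(parameter_id, cutoff, direction, lr_positive,
                     lr_negative, lr_positive_ci = NULL,
                     lr_negative_ci = NULL) {
  parameter_id <- match.arg(parameter_id, score_parameter_ids())
  direction <- match.arg(direction, c("le", "ge"))
  stopifnot(is.numeric(cutoff), length(cutoff) == 1L, is.finite(cutoff))
  if (!is.numeric(lr_positive) || lr_positive <= 0 ||
      !is.numeric(lr_negative) || lr_negative <= 0) {
    stop("likelihood ratios must be strictly positive", call. = FALSE)
  }
  if (lr_positive <= lr_negative) {
    stop("lr_positive must exceed lr_negative for '", parameter_id, "'",
         call. = FALSE)
  }
  check_ci <- function(ci, point, what) {
    if (is.null(ci)) return(NULL)
    stopifnot(is.numeric(ci), length(ci) == 2L)
    if (ci[1] > point || ci[2] < point) {
      stop(what, " CI does not contain the point estimate", call. = FALSE)
    }
    as.numeric(ci)
  }
  structure(
    list(parameter_id = parameter_id,
         cutoff = as.numeric(cutoff),
         direction = direction,
         lr_positive = as.numeric(lr_positive),
         lr_negative = as.numeric(lr_negative),
         lr_positive_ci = check_ci(lr_positive_ci, lr_positive, "LR+"),
         lr_negative_ci = check_ci(lr_negative_ci, lr_negative, "LR-")),
    class = "lr_entry")
}

score_parameter_ids <- function() {
  c("ga_weeks", "aao_zscore", "isthmus_3vt_zscore", "pv_av_ratio")
}

#' Construct a likelihood-ratio scoring model
#'
#' Bundles the four likelihood-ratio entries with the pre-test class counts
#' from which the pre-test odds of coarctation are derived. The odds are
#' carried as the exact count ratio; rounding only happens at display time.
#'
#' @param entries List of four [lr_entry()] objects, one per parameter.
#' @param pretest_coao_count,pretest_no_coao_count Positive integer counts
#'   of CoAo and non-CoAo cases in the derivation cohort.
#'
#' @return An object of class `"scoring_model"`.
#' @seealso [default_model()] for the published model.
#' @export
scoring_model <- function(entries, pretest_coao_count,
                          pretest_no_coao_count) {
  stopifnot(is.list(entries))
  ids <- vapply(entries, function(e) {
    if (!inherits(e, "lr_entry")) stop("entries must be lr_entry objects",
                                       call. = FALSE)
    e$parameter_id
  }, character(1))
  if (!setequal(ids, score_parameter_ids()) ||
      anyDuplicated(ids)) {
    stop("model requires exactly one entry per parameter: ",
         paste(score_parameter_ids(), collapse = ", "), call. = FALSE)
  }
  if (pretest_coao_count <= 0 || pretest_no_coao_count <= 0 ||
      pretest_coao_count != round(pretest_coao_count) ||
      pretest_no_coao_count != round(pretest_no_coao_count)) {
    stop("pre-test counts must be strictly positive integers", call. = FALSE)
  }
  names(entries) <- ids
  entries <- entries[score_parameter_ids()]
  structure(
    list(entries = entries,
         pretest_coao_count = as.integer(pretest_coao_count),
         pretest_no_coao_count = as.integer(pretest_no_coao_count)),
    class = "scoring_model")
}

#' Pre-test odds of a scoring model
#'
#' @param model A [scoring_model()].
#' @return The exact count ratio CoAo / no-CoAo.
#' @export
pretest_odds <- function(model) {
  stopifnot(inherits(model, "scoring_model"))
  model$pretest_coao_count / model$pretest_no_coao_count
}

#' The published coarctation scoring model
#'
#' The four-parameter model: gestational age at diagnosis <= 28 weeks
#' (LR+ 4.3, LR- 0.3), ascending-aorta z-score <= -1.5 (2.8, 0.4), aortic
#' isthmus z-score in the 3VT view <= -2 (1.8, 0.6) and pulmonary/aortic
#' valve ratio >= 1.6 (1.8, 0.4), with pre-test odds of 41 CoAo to 44
#' non-CoAo cases (0.93 when displayed to two decimals).
#'
#' @return A `"scoring_model"`.
#' @examples
#' m <- default_model()
#' pretest_odds(m)           # 41/44
#' m$entries$ga_weeks$cutoff # 28
#' @export
default_model <- function() {
  scoring_model(
    entries = list(
      lr_entry("ga_weeks", 28, "le", 4.3, 0.3,
               lr_positive_ci = c(2.0, 8.8), lr_negative_ci = c(0.1, 0.5)),
      lr_entry("aao_zscore", -1.5, "le", 2.8, 0.4,
               lr_positive_ci = c(1.4, 5.6), lr_negative_ci = c(0.2, 0.7)),
      lr_entry("isthmus_3vt_zscore", -2, "le", 1.8, 0.6,
               lr_positive_ci = c(0.8, 3.8), lr_negative_ci = c(0.3, 1.2)),
      lr_entry("pv_av_ratio", 1.6, "ge", 1.8, 0.4,
               lr_positive_ci = c(1.1, 3.1), lr_negative_ci = c(0.2, 0.9))),
    pretest_coao_count = 41L,
    pretest_no_coao_count = 44L)
}

#' @export
print.scoring_model <- function(x, ...) {
  cat("Likelihood-ratio CoAo scoring model\n")
  cat(sprintf("  Pre-test odds: %d/%d = %.2f\n", x$pretest_coao_count,
              x$pretest_no_coao_count, pretest_odds(x)))
  for (e in x$entries) {
    cat(sprintf("  %-20s %s %g  LR+ %.2g  LR- %.2g\n", e$parameter_id,
                if (e$direction == "le") "<=" else ">=", e$cutoff,
                e$lr_positive, e$lr_negative))
  }
  invisible(x)
}

#' Write / read a scoring model as JSON
#'
#' The on-disk document has `parameters` (array of
#' `{id, cutoff, direction, lr_pos, lr_neg, lr_pos_ci, lr_neg_ci}`) and
#' `pretest` (`{coao, no_coao}` counts). The file shipped at
#' `system.file("extdata", "model_default.json", package = "coarctscore")`
#' round-trips to [default_model()] exactly.
#'
#' @param model A [scoring_model()].
#' @param path File path.
#' @return `write_model()` returns `path` invisibly; `read_model()` a
#'   `"scoring_model"`.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "scoring_model"))
  doc <- list(
    parameters = lapply(unname(model$entries), function(e) {
      p <- list(id = e$parameter_id, cutoff = e$cutoff,
                direction = e$direction, lr_pos = e$lr_positive,
                lr_neg = e$lr_negative)
      if (!is.null(e$lr_positive_ci)) p$lr_pos_ci <- e$lr_positive_ci
      if (!is.null(e$lr_negative_ci)) p$lr_neg_ci <- e$lr_negative_ci
      p
    }),
    pretest = list(coao = model$pretest_coao_count,
                   no_coao = model$pretest_no_coao_count))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  doc <- jsonlite::read_json(path)
  entries <- lapply(doc$parameters, function(p) {
    lr_entry(p$id, p$cutoff, p$direction, p$lr_pos, p$lr_neg,
             lr_positive_ci = if (!is.null(p$lr_pos_ci))
               unlist(p$lr_pos_ci),
             lr_negative_ci = if (!is.null(p$lr_neg_ci))
               unlist(p$lr_neg_ci))
  })
  scoring_model(entries, doc$pretest$coao, doc$pretest$no_coao)
}
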