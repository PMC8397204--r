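#' Dichotomize an exam against the model cut-offs
#'
#' Applies each entry's cut-off to the corresponding exam value
#' (gestational age, ascending-aorta z, isthmus 3VT z, PV/AV ratio).
#' Boundaries are inclusive: a value exactly at the cut-off meets the
#' criterion for both `le` and `ge` directions.
#'
#' @param exam A [fetal_echo_exam()].
#' @param model A [scoring_model()]; defaults to the published model.
#' @param missing How to treat unresolvable parameters: `"error"`
#'   (default, strict) raises an error naming the parameter; `"neutral"`
#'   leaves the criterion `NA`, which [compute_post_test()] maps to a
#'   unit likelihood ratio and flags the result as partial.
#' @return A named logical vector of length 4 (class `"echo_profile"`),
#'   one element per `parameter_id`.
#' @export
dichotomize <- function(exam, model = default_model(),
                        missing = c("error", "neutral")) {
  stopifnot(inherits(exam, "fetal_echo_exam"),
            inherits(model, "scoring_model"))
  missing <- match.arg(missing)
  values <- c(
    ga_weeks = exam$ga_weeks,
    aao_zscore = exam$aao_z,
    isthmus_3vt_zscore = exam$isthmus_3vt_z,
    pv_av_ratio = if (!is.na(exam$pv_mm) && !is.na(exam$av_mm))
      exam$pv_mm / exam$av_mm else NA_real_)
  prof <- vapply(score_parameter_ids(), function(id) {
    v <- values[[id]]
    if (is.na(v)) {
      if (missing == "error") {
        stop("cannot score exam: parameter '", id,
             "' is missing or unresolvable", call. = FALSE)
      }
      return(NA)
    }
    e <- model$entries[[id]]
    if (e$direction == "le") v <= e$cutoff else v >= e$cutoff
  }, logical(1))
  structure(prof, class = "echo_profile")
}

#' Build an echo profile directly
#'
#' @param ga_weeks,aao_zscore,isthmus_3vt_zscore,pv_av_ratio Logicals:
#'   is the corresponding criterion met?
#' @return An `"echo_profile"` logical vector.
#' @export
echo_profile <- function(ga_weeks, aao_zscore, isthmus_3vt_zscore,
                         pv_av_ratio) {
  structure(c(ga_weeks = as.logical(ga_weeks),
              aao_zscore = as.logical(aao_zscore),
              isthmus_3vt_zscore = as.logical(isthmus_3vt_zscore),
              pv_av_ratio = as.logical(pv_av_ratio)),
            class = "echo_profile")
}

#' Post-test probability from a dichotomized profile
#'
#' Sequential application of the likelihood ratios to the pre-test odds:
#' post-test odds = pre-test odds x LR1 x LR2 x LR3 x LR4, where each LR
#' is the entry's LR+ when its criterion is met and LR- otherwise, and
#' post-test probability = odds / (odds + 1). The pre-test odds are used
#' at full precision (the exact count ratio), not rounded.
#'
#' @param profile An `"echo_profile"` (see [dichotomize()]). `NA`
#'   criteria (neutral missing-data mode) contribute LR = 1 and mark the
#'   result partial.
#' @param model A [scoring_model()].
#' @return A `"score_result"`: list with `post_test_odds`,
#'   `post_test_probability`, `contributions` (named numeric, the LR
#'   applied per parameter), `profile` and `partial`.
#' @examples
#' compute_post_test(echo_profile(TRUE, TRUE, TRUE, TRUE))
#' @export
compute_post_test <- function(profile, model = default_model()) {
  stopifnot(inherits(profile, "echo_profile"),
            inherits(model, "scoring_model"))
  contributions <- vapply(score_parameter_ids(), function(id) {
    met <- profile[[id]]
    e <- model$entries[[id]]
    if (is.na(met)) 1 else if (met) e$lr_positive else e$lr_negative
  }, numeric(1))
  odds <- pretest_odds(model) * prod(contributions)
  structure(
    list(post_test_odds = odds,
         post_test_probability = odds / (odds + 1),
         contributions = contributions,
         profile = profile,
         partial = anyNA(profile)),
    class = "score_result")
}

#' Score a fetal echocardiographic exam
#'
#' Convenience composition of [dichotomize()] and [compute_post_test()]:
#' the post-test probability of postnatal coarctation for one exam.
#'
#' @inheritParams dichotomize
#' @return A `"score_result"` (see [compute_post_test()]).
#' @examples
#' ex <- fetal_echo_exam(24, aao_z = -2.1, isthmus_3vt_z = -2.4,
#'                       pv_mm = 6, av_mm = 3.2)
#' score_exam(ex)$post_test_probability  # ~0.973
#' @export
score_exam <- function(exam, model = default_model(),
                       missing = c("error", "neutral")) {
  compute_post_test(dichotomize(exam, model, missing), model)
}

#' Enumerate all discrete score values of a model
#'
#' The dichotomized score can only emit 2^4 = 16 distinct probabilities.
#' Enumerates every criterion combination with its post-test result,
#' sorted by probability (ascending).
#'
#' @param model A [scoring_model()].
#' @return A data.frame with the four logical criterion columns,
#'   `post_test_odds` and `post_test_probability`, 16 rows.
#' @export
enumerate_profiles <- function(model = default_model()) {
  grid <- expand.grid(ga_weeks = c(FALSE, TRUE),
                      aao_zscore = c(FALSE, TRUE),
                      isthmus_3vt_zscore = c(FALSE, TRUE),
                      pv_av_ratio = c(FALSE, TRUE),
                      KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    compute_post_test(echo_profile(grid$ga_weeks[i], grid$aao_zscore[i],
                                   grid$isthmus_3vt_zscore[i],
                                   grid$pv_av_ratio[i]), model)
  })
  grid$post_test_odds <- vapply(res, `[[`, numeric(1), "post_test_odds")
  grid$post_test_probability <-
    vapply(res, `[[`, numeric(1), "post_test_probability")
  grid[order(grid$post_test_probability), , drop = FALSE]
}

#' Score every row of a cohort data frame
#'
#' Vectorized front-end used by the validation pipeline and the CLI:
#' builds a [fetal_echo_exam()] per row and appends
#' `predicted_probability` (and `onset_group`, early when GA <= 28
#' weeks).
#'
#' @param cohort A cohort data.frame (see [read_cohort()] for the
#'   schema).
#' @param model A [scoring_model()].
#' @param zrefs Optional list of [zscore_reference()]s used to fill
#'   missing z-scores from raw diameters.
#' @param missing Passed to [dichotomize()].
#' @return `cohort` with `predicted_probability` and `onset_group`
#'   columns added.
#' @export
score_cohort <- function(cohort, model = default_model(), zrefs = NULL,
                         missing = c("error", "neutral")) {
  stopifnot(is.data.frame(cohort))
  missing <- match.arg(missing)
  probs <- vapply(seq_len(nrow(cohort)), function(i) {
    exam <- exam_from_row(cohort[i, , drop = FALSE])
    if (!is.null(zrefs)) exam <- attach_zscores(exam, zrefs)
    tryCatch(
      score_exam(exam, model, missing)$post_test_probability,
      error = function(e) {
        stop("row ", i,
             if (!is.null(cohort$record_id)) paste0(
               " (record_id ", cohort$record_id[i], ")"),
             ": ", conditionMessage(e), call. = FALSE)
      })
  }, numeric(1))
  cohort$predicted_probability <- probs
  cohort$onset_group <- ifelse(cohort$ga_weeks <= 28, "early", "late")
  cohort
}

exam_fields <- function() {
  names(formals(fetal_echo_exam))
}

# Build an exam from one cohort data.frame row, ignoring non-exam columns.
exam_from_row <- function(row) {
  args <- list()
  for (f in exam_fields()) {
    if (f %in% names(row) && !is.na(row[[f]])) args[[f]] <- row[[f]]
  }
  do.call(fetal_echo_exam, args)
}

#' @export
print.score_result <- function(x, ...) {
  cat(sprintf("Post-test probability of CoAo: %.1f%%%s\n",
              100 * x$post_test_probability,
              if (isTRUE(x$partial)) " (partial: missing parameters)"
              else ""))
  cat(sprintf("  odds %.4f; LRs applied: %s\n", x$post_test_odds,
              paste(sprintf("%s=%.2g", names(x$contributions),
                            x$contributions), collapse = ", ")))
  invisible(x)
}
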