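#' Registry of published rule-based coarctation predictors
#'
#' Alternative prenatal CoAo predictors published by other groups, each
#' encoded as a deterministic decision rule over the exam fields it
#' needs. Only rules whose decision procedure is fully stated are
#' evaluable; the remainder are registered as descriptive-only and raise
#' an error when evaluated (their aggregation logic would have to be
#' guessed).
#'
#' Evaluable rules:
#' * `gomez2013` — the likelihood-ratio score itself, positive at a
#'   post-test probability >= 0.5 (odds above 1);
#' * `gomez2014_early` — AAo z <= -1.1 AND isthmus(3VT) z <= -1.2;
#' * `gomez2014_late` — TV/MV >= 1.48 AND MPA/AAo >= 1.85;
#' * `marginean2015` — all of RV/LV > 1.5, isthmus/DA < 0.7,
#'   isthmus(3VT) < 4.2 mm;
#' * `toole2016` — at least two of: MV z < -1.63, MV/TV < 0.75,
#'   isthmus/DA < 0.5, isthmus-ductal angle < 117 degrees;
#' * `anuwutnavin2016` — points: AAo z <= -2 (4), MV z <= -2 (2),
#'   transverse arch z <= -2 (1), VSD (1); positive at >= 4 points;
#' * `beattie2017` — MPA/AAo <= 0.65 AND diastolic flow persistence at
#'   the isthmus (implemented exactly as printed, although the ratio
#'   direction is the reverse of what right dominance predicts);
#' * `fricke2021_csa` — carotid-subclavian artery index < 0.78;
#' * `fricke2021_composite` — isthmus/DA x MV/TV < 0.37;
#' * `fricke2021` — either Fricke sub-rule positive.
#'
#' @return Named list of `"comparator_rule"` objects.
#' @export
comparator_rules <- function() {
  rule <- function(rule_id, required_fields, evaluable = TRUE) {
    structure(list(rule_id = rule_id,
                   required_fields = required_fields,
                   evaluable = evaluable),
              class = "comparator_rule")
  }
  list(
    gomez2013 = rule("gomez2013",
                     c("ga_weeks", "aao_z", "isthmus_3vt_z", "pv_mm",
                       "av_mm")),
    gomez2014_early = rule("gomez2014_early",
                           c("aao_z", "isthmus_3vt_z")),
    gomez2014_late = rule("gomez2014_late",
                          c("tv_mm", "mv_mm", "mpa_mm", "aao_mm")),
    marginean2015 = rule("marginean2015",
                         c("rv_lv_ratio", "isthmus_3vt_mm", "da_3vt_mm")),
    toole2016 = rule("toole2016",
                     c("mv_z", "mv_mm", "tv_mm", "isthmus_3vt_mm",
                       "da_3vt_mm", "isthmus_ductal_angle_deg")),
    anuwutnavin2016 = rule("anuwutnavin2016",
                           c("aao_z", "mv_z", "transverse_arch_z",
                             "vsd")),
    beattie2017 = rule("beattie2017",
                       c("mpa_mm", "aao_mm",
                         "diastolic_flow_persistence")),
    fricke2021_csa = rule("fricke2021_csa", "csa_index"),
    fricke2021_composite = rule("fricke2021_composite",
                                c("isthmus_3vt_mm", "da_3vt_mm",
                                  "mv_mm", "tv_mm")),
    fricke2021 = rule("fricke2021",
                      c("csa_index", "isthmus_3vt_mm", "da_3vt_mm",
                        "mv_mm", "tv_mm")),
    jowett2012 = rule("jowett2012", character(), evaluable = FALSE),
    arya2016 = rule("arya2016", character(), evaluable = FALSE),
    patel2018 = rule("patel2018", character(), evaluable = FALSE),
    wang2019 = rule("wang2019", character(), evaluable = FALSE),
    morgan2019 = rule("morgan2019", character(), evaluable = FALSE),
    vigneswaran2020 = rule("vigneswaran2020", character(),
                           evaluable = FALSE),
    freeman2021 = rule("freeman2021", character(), evaluable = FALSE))
}

#' Evaluate a comparator rule on an exam
#'
#' @param exam A [fetal_echo_exam()] supplying the rule's required
#'   fields; a missing field raises an error listing the absent
#'   measurements (never a silent negative).
#' @param rule A `"comparator_rule"` from [comparator_rules()], or its
#'   id.
#' @return A `"comparator_prediction"` list: `rule_id`,
#'   `predicted_coao` (logical) and `detail` (per-sub-criterion
#'   booleans or points).
#' @export
evaluate_rule <- function(exam, rule) {
  stopifnot(inherits(exam, "fetal_echo_exam"))
  if (is.character(rule)) {
    rules <- comparator_rules()
    if (!rule %in% names(rules)) {
      stop("unknown comparator rule '", rule, "'", call. = FALSE)
    }
    rule <- rules[[rule]]
  }
  stopifnot(inherits(rule, "comparator_rule"))
  if (!rule$evaluable) {
    stop("rule '", rule$rule_id, "' is descriptive only: its published ",
         "decision procedure is not fully specified and cannot be ",
         "evaluated", call. = FALSE)
  }
  missing_fields <- rule$required_fields[vapply(
    rule$required_fields, function(f) is.na(exam[[f]]), logical(1))]
  if (length(missing_fields) > 0) {
    stop("rule '", rule$rule_id, "' cannot be evaluated: missing ",
         paste(missing_fields, collapse = ", "), call. = FALSE)
  }
  ratios <- cardiac_ratios(exam)
  detail <- list()
  positive <- switch(
    rule$rule_id,
    gomez2013 = {
      res <- score_exam(exam)
      detail <- as.list(res$profile)
      detail$post_test_probability <- res$post_test_probability
      res$post_test_probability >= 0.5
    },
    gomez2014_early = {
      detail <- list(aao = exam$aao_z <= -1.1,
                     isthmus = exam$isthmus_3vt_z <= -1.2)
      detail$aao && detail$isthmus
    },
    gomez2014_late = {
      detail <- list(tv_mv = ratios$tv_mv >= 1.48,
                     mpa_aao = ratios$mpa_aao >= 1.85)
      detail$tv_mv && detail$mpa_aao
    },
    marginean2015 = {
      detail <- list(rv_lv = exam$rv_lv_ratio > 1.5,
                     isthmus_da = ratios$isthmus_da < 0.7,
                     isthmus_mm = exam$isthmus_3vt_mm < 4.2)
      all(unlist(detail))
    },
    toole2016 = {
      detail <- list(mv_z = exam$mv_z < -1.63,
                     mv_tv = exam$mv_mm / exam$tv_mm < 0.75,
                     isthmus_da = ratios$isthmus_da < 0.5,
                     angle = exam$isthmus_ductal_angle_deg < 117)
      sum(unlist(detail)) >= 2
    },
    anuwutnavin2016 = {
      detail <- list(aao = 4 * (exam$aao_z <= -2),
                     mv = 2 * (exam$mv_z <= -2),
                     transverse_arch = 1 * (exam$transverse_arch_z <= -2),
                     vsd = 1 * isTRUE(exam$vsd))
      detail$points <- detail$aao + detail$mv + detail$transverse_arch +
        detail$vsd
      detail$points >= 4
    },
    beattie2017 = {
      detail <- list(mpa_aao = ratios$mpa_aao <= 0.65,
                     diastolic_flow =
                       isTRUE(exam$diastolic_flow_persistence))
      detail$mpa_aao && detail$diastolic_flow
    },
    fricke2021_csa = {
      detail <- list(csa = exam$csa_index < 0.78)
      detail$csa
    },
    fricke2021_composite = {
      comp <- ratios$isthmus_da * (exam$mv_mm / exam$tv_mm)
      detail <- list(composite_value = comp, composite = comp < 0.37)
      detail$composite
    },
    fricke2021 = {
      csa <- exam$csa_index < 0.78
      comp <- ratios$isthmus_da * (exam$mv_mm / exam$tv_mm) < 0.37
      detail <- list(csa = csa, composite = comp)
      csa || comp
    },
    stop("no evaluator registered for rule '", rule$rule_id, "'",
         call. = FALSE))
  structure(list(rule_id = rule$rule_id,
                 predicted_coao = as.logical(positive),
                 detail = detail),
            class = "comparator_prediction")
}

#' Benchmark comparator rules on a cohort
#'
#' Evaluates each rule on every cohort record and summarises its
#' diagnostic accuracy against the postnatal outcome. Rules that cannot
#' be evaluated on the cohort (descriptive-only, or required fields
#' missing in some records) are skipped with a recorded reason rather
#' than failing the benchmark.
#'
#' @param cohort Cohort data.frame with `outcome_coao` and exam columns.
#' @param rules List of `"comparator_rule"`s (default: every registered
#'   rule).
#' @return List with `results` (per evaluated rule:
#'   [diagnostic_metrics()]) and `skipped` (named character vector of
#'   reasons).
#' @export
benchmark_rules <- function(cohort, rules = comparator_rules()) {
  stopifnot(is.data.frame(cohort), !is.null(cohort$outcome_coao))
  outcome <- as.logical(cohort$outcome_coao)
  exams <- lapply(seq_len(nrow(cohort)), function(i) {
    exam_from_row(cohort[i, , drop = FALSE])
  })
  results <- list()
  skipped <- character()
  for (rule in rules) {
    preds <- tryCatch(
      vapply(exams, function(ex) evaluate_rule(ex, rule)$predicted_coao,
             logical(1)),
      error = function(e) conditionMessage(e))
    if (is.character(preds)) {
      skipped[[rule$rule_id]] <- preds
    } else {
      results[[rule$rule_id]] <- diagnostic_metrics(preds, outcome)
    }
  }
  list(results = results, skipped = skipped)
}
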