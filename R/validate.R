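#' Split a scored cohort by onset of cardiac asymmetry
#'
#' Early onset is diagnosis at <= 28 gestational weeks (inclusive), late
#' onset strictly after 28 weeks — the subgrouping used throughout the
#' subgroup analysis.
#'
#' @param cohort A cohort data.frame with a `ga_weeks` column.
#' @return List with `early` and `late` data.frames partitioning the
#'   input.
#' @export
split_by_onset <- function(cohort) {
  stopifnot(is.data.frame(cohort))
  if (nrow(cohort) == 0) {
    return(list(early = cohort, late = cohort))
  }
  stopifnot(!anyNA(cohort$ga_weeks))
  early <- cohort$ga_weeks <= 28
  list(early = cohort[early, , drop = FALSE],
       late = cohort[!early, , drop = FALSE])
}

#' Probability-band breakdown of a scored cohort
#'
#' Partitions the cohort into low / intermediate / high predicted-risk
#' bands — `[0, low)`, `[low, high)`, `[high, 1]` (half-open, so a
#' probability exactly at `low` falls in the middle band) — and reports
#' the size and postnatal CoAo confirmation rate of each band.
#'
#' @param cohort Scored cohort with `predicted_probability` and
#'   `outcome_coao` columns.
#' @param low,high Band edges, `0 < low < high < 1`. Defaults 0.35 and
#'   0.96 mirror the reported low-risk (< 35%) and high-risk (>= 96%)
#'   bands.
#' @return A `"probability_bands"` data.frame: `band`, `n`, `coao`,
#'   `coao_rate_percent`, `fraction_percent`.
#' @export
probability_bands <- function(cohort, low = 0.35, high = 0.96) {
  stopifnot(is.data.frame(cohort),
            !is.null(cohort$predicted_probability),
            !is.null(cohort$outcome_coao))
  if (!(low > 0 && low < high && high < 1)) {
    stop("bands must satisfy 0 < low < high < 1", call. = FALSE)
  }
  p <- cohort$predicted_probability
  y <- as.logical(cohort$outcome_coao)
  band <- cut(p, breaks = c(-Inf, low, high, Inf), right = FALSE,
              labels = c("below_low", "intermediate", "at_or_above_high"))
  out <- data.frame(
    band = levels(band),
    n = as.integer(table(band)),
    coao = as.integer(tapply(y, band, sum, default = 0)))
  out$coao_rate_percent <- ifelse(out$n > 0,
                                  count_percent(out$coao, pmax(out$n, 1)),
                                  NA_real_)
  out$fraction_percent <- count_percent(out$n, nrow(cohort))
  class(out) <- c("probability_bands", "data.frame")
  out
}

#' Compare a variable between outcome groups
#'
#' Two-sided comparison of one exam variable between fetuses with and
#' without postnatal CoAo. Continuous variables use a Welch t-test when
#' both groups pass a Shapiro-Wilk normality screen (alpha = 0.05),
#' otherwise a Mann-Whitney test; categorical variables use chi-square
#' unless any expected cell count is below 5, in which case Fisher's
#' exact test.
#'
#' @param cohort Cohort data.frame with `outcome_coao` and the variable.
#' @param variable Column name to compare.
#' @return A `"group_comparison"` list: `variable`, `type`,
#'   `group_summaries`, `test`, `statistic`, `p_value`, `degenerate`.
#' @export
compare_groups <- function(cohort, variable) {
  stopifnot(is.data.frame(cohort), variable %in% names(cohort),
            !is.null(cohort$outcome_coao))
  y <- as.logical(cohort$outcome_coao)
  v <- cohort[[variable]]
  keep <- !is.na(v)
  v <- v[keep]
  y <- y[keep]
  if (length(v) == 0 || length(unique(y)) < 2) {
    stop("compare_groups needs data in both outcome groups for '",
         variable, "'", call. = FALSE)
  }
  continuous <- is.numeric(v)
  if (continuous) {
    g1 <- v[y]
    g0 <- v[!y]
    if (length(g1) < 2 || length(g0) < 2) {
      stop("continuous comparison needs >= 2 observations per group",
           call. = FALSE)
    }
    summaries <- list(
      coao = list(mean = mean(g1), sd = stats::sd(g1),
                  n = length(g1)),
      no_coao = list(mean = mean(g0), sd = stats::sd(g0),
                     n = length(g0)))
    degenerate <- stats::sd(g1) == 0 && stats::sd(g0) == 0
    if (degenerate) {
      return(structure(list(variable = variable, type = "continuous",
                            group_summaries = summaries,
                            test = "none", statistic = NA_real_,
                            p_value = NA_real_, degenerate = TRUE),
                       class = "group_comparison"))
    }
    normal <- function(x) {
      if (stats::sd(x) == 0 || length(x) < 3 || length(x) > 5000) {
        return(FALSE)
      }
      stats::shapiro.test(x)$p.value > 0.05
    }
    if (normal(g1) && normal(g0)) {
      ht <- stats::t.test(g1, g0)  # Welch by default
      test <- "welch_t"
    } else {
      ht <- stats::wilcox.test(g1, g0, exact = FALSE)
      test <- "mann_whitney"
    }
  } else {
    v <- if (is.logical(v)) factor(v, levels = c(FALSE, TRUE)) else
      factor(v)
    tab <- table(v, y)
    if (nrow(tab) < 2) {
      return(structure(
        list(variable = variable, type = "categorical",
             group_summaries = as.list(table(v)),
             test = "none", statistic = NA_real_, p_value = NA_real_,
             degenerate = TRUE),
        class = "group_comparison"))
    }
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    summaries <- list(
      coao = as.list(tab[, "TRUE"]), no_coao = as.list(tab[, "FALSE"]))
    degenerate <- FALSE
    if (any(expected < 5)) {
      ht <- stats::fisher.test(tab)
      test <- "fisher"
    } else {
      ht <- stats::chisq.test(tab, correct = FALSE)
      test <- "chi_square"
    }
  }
  structure(
    list(variable = variable,
         type = if (continuous) "continuous" else "categorical",
         group_summaries = summaries, test = test,
         statistic = if (!is.null(ht$statistic))
           unname(ht$statistic) else NA_real_,
         p_value = unname(ht$p.value), degenerate = degenerate),
    class = "group_comparison")
}

#' Mean and SD of the predicted probability per outcome group
#'
#' Reported on the percent scale (e.g. 84.2 +/- 18.2 vs 26.0 +/- 28.6),
#' with the Mann-Whitney p-value of the between-group comparison.
#'
#' @param cohort Scored cohort with `predicted_probability` and
#'   `outcome_coao`.
#' @return List with `coao` and `no_coao` (`mean_percent`, `sd_percent`,
#'   `n`; SD is `NA` for single-member groups) and `p_value`.
#' @export
summarize_probabilities <- function(cohort) {
  stopifnot(is.data.frame(cohort),
            !is.null(cohort$predicted_probability),
            !is.null(cohort$outcome_coao))
  y <- as.logical(cohort$outcome_coao)
  p <- 100 * cohort$predicted_probability
  if (!any(y) || !any(!y)) {
    stop("both outcome groups must be non-empty", call. = FALSE)
  }
  one <- function(x) list(
    mean_percent = mean(x),
    sd_percent = if (length(x) > 1) stats::sd(x) else NA_real_,
    n = length(x))
  p_value <- if (sum(y) > 1 && sum(!y) > 1) {
    stats::wilcox.test(p[y], p[!y], exact = FALSE)$p.value
  } else NA_real_
  list(coao = one(p[y]), no_coao = one(p[!y]), p_value = p_value)
}

#' Run the full validation analysis on a scored cohort
#'
#' Reproduces the prospective-validation pipeline on any cohort with
#' known outcomes: whole-cohort ROC with AUC and DeLong CI, the three
#' operating points (best balance / maximum sensitivity / maximum
#' specificity) with diagnostic metrics and Wilson CIs, early/late onset
#' subgroup analyses, probability-band breakdown, group comparisons of
#' the available measurements and the probability summary.
#'
#' @param cohort Cohort data.frame with `outcome_coao`; scored first
#'   with [score_cohort()] if `predicted_probability` is absent.
#' @param model A [scoring_model()] used when scoring is needed.
#' @param band_low,band_high Probability-band edges, see
#'   [probability_bands()].
#' @param compare_variables Character vector of columns to compare
#'   between outcome groups; defaults to the numeric measurement columns
#'   present.
#' @return A `"validation_report"` list, JSON-serializable with
#'   [write_report()] and checkable with [validate_report()].
#' @export
validate_cohort <- function(cohort, model = default_model(),
                            band_low = 0.35, band_high = 0.96,
                            compare_variables = NULL) {
  stopifnot(is.data.frame(cohort))
  if (is.null(cohort$outcome_coao) || anyNA(cohort$outcome_coao)) {
    stop("validation requires a complete outcome_coao column",
         call. = FALSE)
  }
  cohort$outcome_coao <- as.logical(cohort$outcome_coao)
  if (length(unique(cohort$outcome_coao)) < 2) {
    stop("validation requires both outcome classes present",
         call. = FALSE)
  }
  if (is.null(cohort$predicted_probability)) {
    cohort <- score_cohort(cohort, model)
  }
  y <- cohort$outcome_coao
  p <- cohort$predicted_probability

  analyse <- function(scores, outcome) {
    roc <- empirical_roc(scores, outcome)
    cutoffs <- lapply(c("best_balance", "max_sensitivity",
                        "max_specificity"),
                      function(cr) cutoff_to_list(select_cutoff(roc, cr)))
    list(n = length(outcome), n_coao = sum(outcome),
         evaluable = TRUE,
         auc = roc$auc,
         auc_ci_lower = unname(roc$auc_ci[1]),
         auc_ci_upper = unname(roc$auc_ci[2]),
         n_thresholds = length(roc$thresholds),
         cutoffs = cutoffs)
  }
  subgroup <- function(sub) {
    if (nrow(sub) == 0 || length(unique(sub$outcome_coao)) < 2) {
      list(n = nrow(sub), n_coao = sum(sub$outcome_coao),
           evaluable = FALSE)
    } else {
      analyse(sub$predicted_probability, sub$outcome_coao)
    }
  }
  onset <- split_by_onset(cohort)

  if (is.null(compare_variables)) {
    candidates <- c("ga_weeks", "aao_z", "isthmus_3vt_z", "mv_z",
                    "predicted_probability")
    compare_variables <- intersect(candidates, names(cohort))
  }
  comparisons <- lapply(compare_variables, function(v) {
    cmp <- tryCatch(compare_groups(cohort, v), error = function(e) NULL)
    if (is.null(cmp)) return(NULL)
    list(variable = cmp$variable, test = cmp$test,
         statistic = if (is.na(cmp$statistic)) NULL else cmp$statistic,
         p_value = if (is.na(cmp$p_value)) NULL else cmp$p_value,
         degenerate = cmp$degenerate)
  })
  comparisons <- Filter(Negate(is.null), comparisons)

  bands <- probability_bands(cohort, band_low, band_high)
  ps <- summarize_probabilities(cohort)

  structure(
    list(
      n = nrow(cohort),
      n_coao = sum(y),
      prevalence_percent = count_percent(sum(y), nrow(cohort)),
      roc = analyse(p, y),
      subgroups = list(early = subgroup(onset$early),
                       late = subgroup(onset$late)),
      bands = list(
        low = band_low, high = band_high,
        bands = lapply(seq_len(nrow(bands)), function(i) {
          list(band = bands$band[i], n = bands$n[i],
               coao = bands$coao[i],
               coao_rate_percent = bands$coao_rate_percent[i],
               fraction_percent = bands$fraction_percent[i])
        })),
      group_comparisons = comparisons,
      probability_summary = list(
        coao = ps$coao, no_coao = ps$no_coao,
        p_value = if (is.na(ps$p_value)) NULL else ps$p_value)),
    class = "validation_report")
}

cutoff_to_list <- function(co) {
  m <- co$metrics
  metric_list <- function(v) {
    if (is.na(v$estimate)) {
      list(defined = FALSE)
    } else {
      list(defined = TRUE, estimate = v$estimate,
           ci_lower = unname(v$ci[1]), ci_upper = unname(v$ci[2]))
    }
  }
  list(criterion = co$criterion, threshold = co$threshold,
       threshold_percent = co$threshold_percent,
       sensitivity = co$sensitivity, specificity = co$specificity,
       counts = list(tp = m$tp, fp = m$fp, tn = m$tn, fn = m$fn),
       metrics = list(sensitivity = metric_list(m$sensitivity),
                      specificity = metric_list(m$specificity),
                      npv = metric_list(m$npv),
                      ppv = metric_list(m$ppv)))
}

#' Write a validation report to JSON
#'
#' Machine outputs carry probabilities at 6 decimal places; the report
#' also embeds the rounded display percents produced upstream.
#'
#' @param report A `"validation_report"` (or any JSON-serializable
#'   list).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = 6, pretty = TRUE, null = "null")
  invisible(path)
}

#' Check a validation report against the shipped structural schema
#'
#' The package ships a JSON document
#' (`extdata/report_schema.json`) describing the required keys and types
#' of a validation report; this checker walks the report against it and
#' throws with the offending path on mismatch.
#'
#' @param report A `"validation_report"` or a list parsed from a report
#'   JSON file.
#' @return `TRUE`, invisibly, if the report conforms.
#' @export
validate_report <- function(report) {
  schema <- jsonlite::read_json(
    system.file("extdata", "report_schema.json",
                package = "coarctscore"))
  check_node(unclass(report), schema, "$")
  invisible(TRUE)
}

check_node <- function(value, schema, path) {
  type <- schema$type
  fail <- function(msg) {
    stop("report schema violation at ", path, ": ", msg, call. = FALSE)
  }
  switch(
    type,
    number = if (!is.numeric(value) || length(value) != 1L)
      fail("expected a number"),
    integer = if (!is.numeric(value) || length(value) != 1L ||
                  value != round(value))
      fail("expected an integer"),
    string = if (!is.character(value) || length(value) != 1L)
      fail("expected a string"),
    boolean = if (!is.logical(value) || length(value) != 1L)
      fail("expected a boolean"),
    array = {
      if (!is.list(value) && !is.vector(value)) fail("expected an array")
      for (i in seq_along(value)) {
        check_node(value[[i]], schema$items, paste0(path, "[", i, "]"))
      }
    },
    object = {
      if (!is.list(value)) fail("expected an object")
      for (key in names(schema$required)) {
        if (is.null(value[[key]])) fail(paste0("missing key '", key, "'"))
        check_node(value[[key]], schema$required[[key]],
                   paste0(path, ".", key))
      }
      for (key in names(schema$optional)) {
        if (!is.null(value[[key]])) {
          check_node(value[[key]], schema$optional[[key]],
                     paste0(path, ".", key))
        }
      }
    },
    fail(paste0("unknown schema node type '", type, "'")))
  invisible(TRUE)
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("Validation report: n = %d, CoAo %d (%.1f%%)\n", x$n,
              x$n_coao, x$prevalence_percent))
  cat(sprintf("  AUC %.3f (%.2f-%.2f)\n", x$roc$auc,
              x$roc$auc_ci_lower, x$roc$auc_ci_upper))
  for (co in x$roc$cutoffs) {
    cat(sprintf("  %-16s >= %d%%  Sn %.1f%%  Sp %.1f%%\n", co$criterion,
                co$threshold_percent, 100 * co$sensitivity,
                100 * co$specificity))
  }
  invisible(x)
}
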