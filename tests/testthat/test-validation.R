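scored_toy_cohort <- function(n = 120, seed = 11) {
  co <- generate_cohort(default_paper_like_config(n = n, seed = seed))
  score_cohort(co)
}

test_that("onset split is inclusive at 28 weeks and partitions the cohort", {
  df <- data.frame(record_id = c("a", "b", "c"),
                   ga_weeks = c(28.0, 28.1, 20))
  sp <- split_by_onset(df)
  expect_identical(sp$early$record_id, c("a", "c"))
  expect_identical(sp$late$record_id, "b")
  expect_equal(nrow(sp$early) + nrow(sp$late), nrow(df))
  empty <- split_by_onset(df[0, ])
  expect_equal(nrow(empty$early), 0)
  expect_equal(nrow(empty$late), 0)
})

test_that("probability bands are half-open, partition the cohort and track CoAo rates", {
  df <- data.frame(predicted_probability = c(0.1, 0.34, 0.35, 0.5,
                                             0.959, 0.96, 0.99),
                   outcome_coao = c(FALSE, FALSE, FALSE, TRUE, TRUE,
                                    TRUE, TRUE))
  b <- probability_bands(df)
  expect_equal(sum(b$n), nrow(df))
  expect_equal(b$n[b$band == "below_low"], 2L)        # 0.35 is middle
  expect_equal(b$n[b$band == "intermediate"], 3L)     # 0.96 is high
  expect_equal(b$n[b$band == "at_or_above_high"], 2L)
  # every CoAo case scores >= 0.5 here, so the low band rate is 0
  expect_equal(b$coao_rate_percent[b$band == "below_low"], 0)
  expect_equal(b$coao_rate_percent[b$band == "at_or_above_high"], 100)
  expect_error(probability_bands(df, low = 0.9, high = 0.4),
               "0 < low < high < 1")
})

test_that("group comparison picks the declared test family", {
  # balanced 2x2 with identical margins and zero association -> Fisher
  # (expected cells are 4 < 5), p = 1
  df <- data.frame(outcome_coao = rep(c(TRUE, FALSE), each = 8),
                   rfop = rep(c(TRUE, FALSE, TRUE, FALSE), each = 4))
  cmp <- compare_groups(df, "rfop")
  expect_identical(cmp$test, "fisher")
  expect_equal(cmp$p_value, 1.0)

  # perfect association [[10, 0], [0, 10]]: expected cells are exactly
  # 5, so the declared rule stays with chi-square; p is still tiny, and
  # the Fisher p on the same table is < 0.001 by direct enumeration
  df2 <- data.frame(outcome_coao = rep(c(TRUE, FALSE), each = 10),
                    plsvc = rep(c(TRUE, FALSE), each = 10))
  cmp2 <- compare_groups(df2, "plsvc")
  expect_identical(cmp2$test, "chi_square")
  expect_lt(cmp2$p_value, 0.001)
  expect_lt(fisher.test(table(df2$plsvc, df2$outcome_coao))$p.value,
            0.001)
  # the same association in a smaller sample drops expected counts
  # below 5 and switches to Fisher
  df2b <- data.frame(outcome_coao = rep(c(TRUE, FALSE), each = 7),
                     plsvc = rep(c(TRUE, FALSE), each = 7))
  cmp2b <- compare_groups(df2b, "plsvc")
  expect_identical(cmp2b$test, "fisher")
  expect_lt(cmp2b$p_value, 0.001)

  # large balanced table -> chi-square
  df3 <- data.frame(outcome_coao = rep(c(TRUE, FALSE), each = 40),
                    plsvc = rep(c(TRUE, FALSE), 40))
  expect_identical(compare_groups(df3, "plsvc")$test, "chi_square")

  # normal-looking continuous data -> Welch t
  set.seed(5)
  df4 <- data.frame(outcome_coao = rep(c(TRUE, FALSE), each = 40),
                    aao_z = c(rnorm(40, -2), rnorm(40, -0.5)))
  cmp4 <- compare_groups(df4, "aao_z")
  expect_identical(cmp4$test, "welch_t")
  expect_lt(cmp4$p_value, 0.001)

  # heavily skewed data fails the normality screen -> Mann-Whitney
  df5 <- data.frame(outcome_coao = rep(c(TRUE, FALSE), each = 40),
                    isthmus_3vt_z = c(rexp(40)^3, rexp(40)^3 + 2))
  expect_identical(compare_groups(df5, "isthmus_3vt_z")$test,
                   "mann_whitney")

  # constant variable in both groups is degenerate, flagged not tested
  df6 <- data.frame(outcome_coao = rep(c(TRUE, FALSE), each = 5),
                    ga_weeks = rep(30, 10))
  cmp6 <- compare_groups(df6, "ga_weeks")
  expect_true(cmp6$degenerate)
  expect_true(is.na(cmp6$p_value))

  expect_error(compare_groups(
    data.frame(outcome_coao = c(TRUE, FALSE), ga_weeks = c(1, 2)),
    "ga_weeks"), ">= 2 observations")
})

test_that("probability summaries are on the percent scale", {
  df <- data.frame(predicted_probability = c(0.2, 0.4, 0.3, 0.3),
                   outcome_coao = c(TRUE, TRUE, FALSE, FALSE))
  s <- summarize_probabilities(df)
  expect_equal(s$coao$mean_percent, 30)
  expect_equal(s$coao$sd_percent, sd(c(20, 40)))  # ~14.14
  expect_equal(s$no_coao$sd_percent, 0)
  single <- summarize_probabilities(
    data.frame(predicted_probability = c(0.8, 0.1, 0.2),
               outcome_coao = c(TRUE, FALSE, FALSE)))
  expect_equal(single$coao$mean_percent, 80)
  expect_true(is.na(single$coao$sd_percent))
  expect_error(summarize_probabilities(
    data.frame(predicted_probability = 0.5, outcome_coao = TRUE)),
    "non-empty")
})

test_that("validate_cohort produces a schema-valid, internally consistent report", {
  sc <- scored_toy_cohort()
  rep <- validate_cohort(sc)
  expect_true(validate_report(rep))
  expect_equal(rep$n, nrow(sc))
  expect_equal(rep$n_coao, sum(sc$outcome_coao))
  expect_equal(rep$prevalence_percent,
               count_percent(sum(sc$outcome_coao), nrow(sc)))
  expect_lte(rep$roc$n_thresholds, 16L)
  expect_length(rep$roc$cutoffs, 3L)
  expect_true(rep$roc$auc >= rep$roc$auc_ci_lower &&
                rep$roc$auc <= rep$roc$auc_ci_upper)
  expect_equal(rep$subgroups$early$n + rep$subgroups$late$n, rep$n)
  expect_equal(sum(vapply(rep$bands$bands, `[[`, numeric(1), "n")),
               rep$n)
  # operating-point counts reconcile with the cohort
  for (co in rep$roc$cutoffs) {
    expect_equal(co$counts$tp + co$counts$fn, rep$n_coao)
    expect_equal(co$counts$tn + co$counts$fp, rep$n - rep$n_coao)
  }
  # report JSON round-trips through the schema checker
  tmp <- tempfile(fileext = ".json")
  write_report(rep, tmp)
  expect_true(validate_report(jsonlite::read_json(tmp)))
})

test_that("validation refuses missing or single-class outcomes", {
  sc <- scored_toy_cohort(n = 40, seed = 3)
  sc$outcome_coao <- NULL
  expect_error(validate_cohort(sc), "outcome_coao")
  sc2 <- scored_toy_cohort(n = 40, seed = 3)
  sc2$outcome_coao <- FALSE
  expect_error(validate_cohort(sc2), "both outcome classes")
})
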