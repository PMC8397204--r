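# an exam with every optional field at unremarkable mid-range values
normal_exam <- function(...) {
  args <- list(ga_weeks = 32, aao_z = -0.2, isthmus_3vt_z = -0.3,
               pv_mm = 5.2, av_mm = 4.6, tv_mm = 10.0, mv_mm = 9.0,
               mpa_mm = 6.5, aao_mm = 6.0, isthmus_3vt_mm = 4.8,
               da_3vt_mm = 5.8, mv_z = -0.1, tv_z = 0.1,
               transverse_arch_z = -0.2, rv_lv_ratio = 1.1,
               isthmus_ductal_angle_deg = 130, csa_index = 1.1,
               vsd = FALSE, diastolic_flow_persistence = FALSE)
  override <- list(...)
  args[names(override)] <- override
  do.call(fetal_echo_exam, args)
}

evaluable_ids <- c("gomez2013", "gomez2014_early", "gomez2014_late",
                   "marginean2015", "toole2016", "anuwutnavin2016",
                   "beattie2017", "fricke2021_csa",
                   "fricke2021_composite", "fricke2021")

test_that("all evaluable rules are negative on a normal mid-range exam", {
  ex <- normal_exam()
  for (id in evaluable_ids) {
    expect_false(evaluate_rule(ex, id)$predicted_coao, label = id)
  }
})

test_that("the point-based rule totals points and thresholds at 4", {
  pred <- evaluate_rule(normal_exam(aao_z = -2.5, mv_z = -2.2,
                                    transverse_arch_z = -1.0,
                                    vsd = FALSE),
                        "anuwutnavin2016")
  expect_equal(pred$detail$points, 6)  # 4 + 2 + 0 + 0
  expect_true(pred$predicted_coao)

  # exhaustive check over all 16 sub-criterion combinations
  combos <- expand.grid(aao = c(FALSE, TRUE), mv = c(FALSE, TRUE),
                        arch = c(FALSE, TRUE), vsd = c(FALSE, TRUE))
  for (i in seq_len(nrow(combos))) {
    ex <- normal_exam(aao_z = if (combos$aao[i]) -2.5 else 0,
                      mv_z = if (combos$mv[i]) -2.5 else 0,
                      transverse_arch_z = if (combos$arch[i]) -2.5 else 0,
                      vsd = combos$vsd[i])
    pred <- evaluate_rule(ex, "anuwutnavin2016")
    pts <- 4 * combos$aao[i] + 2 * combos$mv[i] + combos$arch[i] +
      combos$vsd[i]
    expect_equal(pred$detail$points, pts)
    expect_true(pred$detail$points >= 0 && pred$detail$points <= 8)
    expect_identical(pred$predicted_coao, pts >= 4)
  }
})

test_that("two-of-four and all-of-three aggregations behave", {
  # exactly one Toole criterion met -> negative
  one <- normal_exam(mv_z = -2)
  expect_false(evaluate_rule(one, "toole2016")$predicted_coao)
  # two met -> positive
  two <- normal_exam(mv_z = -2, isthmus_ductal_angle_deg = 100)
  expect_true(evaluate_rule(two, "toole2016")$predicted_coao)

  # Marginean needs all three: isthmus 4.5 mm fails both the absolute
  # (< 4.2 mm) and ratio (4.5/5.8 = 0.78, not < 0.7) criteria
  partial <- normal_exam(rv_lv_ratio = 1.8, isthmus_3vt_mm = 4.5)
  expect_false(evaluate_rule(partial, "marginean2015")$predicted_coao)
  full <- normal_exam(rv_lv_ratio = 1.8, isthmus_3vt_mm = 3.9,
                      da_3vt_mm = 6.0)  # isthmus/DA = 0.65 < 0.7
  expect_true(evaluate_rule(full, "marginean2015")$predicted_coao)
})

test_that("the paired z-score and ratio rules use their printed cut-offs", {
  expect_true(evaluate_rule(normal_exam(aao_z = -1.1,
                                        isthmus_3vt_z = -1.2),
                            "gomez2014_early")$predicted_coao)
  expect_false(evaluate_rule(normal_exam(aao_z = -1.0,
                                         isthmus_3vt_z = -3),
                             "gomez2014_early")$predicted_coao)
  expect_true(evaluate_rule(
    normal_exam(tv_mm = 15, mv_mm = 10, mpa_mm = 12, aao_mm = 6),
    "gomez2014_late")$predicted_coao)
  expect_false(evaluate_rule(
    normal_exam(tv_mm = 15, mv_mm = 10, mpa_mm = 10, aao_mm = 6),
    "gomez2014_late")$predicted_coao)
  # Beattie as printed: MPA/AAo <= 0.65 AND diastolic flow persistence
  expect_true(evaluate_rule(
    normal_exam(mpa_mm = 3.8, aao_mm = 6,
                diastolic_flow_persistence = TRUE),
    "beattie2017")$predicted_coao)
  expect_false(evaluate_rule(
    normal_exam(mpa_mm = 3.8, aao_mm = 6),
    "beattie2017")$predicted_coao)
})

test_that("Fricke sub-rules evaluate separately and combine by OR", {
  csa_pos <- normal_exam(csa_index = 0.5)
  expect_true(evaluate_rule(csa_pos, "fricke2021_csa")$predicted_coao)
  expect_false(
    evaluate_rule(csa_pos, "fricke2021_composite")$predicted_coao)
  expect_true(evaluate_rule(csa_pos, "fricke2021")$predicted_coao)
  # isthmus/DA x MV/TV = (2.0/5.8) x (9/10) = 0.31 < 0.37
  comp_pos <- normal_exam(isthmus_3vt_mm = 2.0)
  expect_true(
    evaluate_rule(comp_pos, "fricke2021_composite")$predicted_coao)
})

test_that("missing fields and descriptive-only rules raise informative errors", {
  bare <- fetal_echo_exam(30, aao_z = -1, isthmus_3vt_z = -1,
                          pv_mm = 5, av_mm = 4)
  err <- tryCatch(evaluate_rule(bare, "toole2016"),
                  error = conditionMessage)
  expect_match(err, "mv_z")
  expect_match(err, "isthmus_ductal_angle_deg")
  expect_error(evaluate_rule(bare, "morgan2019"), "descriptive only")
  expect_error(evaluate_rule(bare, "nonexistent"), "unknown comparator")
})

test_that("rules are deterministic and benchmark reuses the diagnostic metrics", {
  ex <- normal_exam(aao_z = -2.5, mv_z = -2.2)
  expect_identical(evaluate_rule(ex, "anuwutnavin2016"),
                   evaluate_rule(ex, "anuwutnavin2016"))

  co <- generate_cohort(default_paper_like_config(n = 100, seed = 9))
  sc <- score_cohort(co)
  # outcome defined exactly by the gomez2013 decision rule -> perfect
  self_labelled <- within(sc, outcome_coao <-
                            predicted_probability >= 0.5)
  bench_self <- benchmark_rules(self_labelled,
                                comparator_rules()["gomez2013"])
  m <- bench_self$results$gomez2013
  expect_equal(m$sensitivity$estimate, 1)
  expect_equal(m$specificity$estimate, 1)

  # rules lacking generated fields are skipped with a reason
  bench <- benchmark_rules(sc)
  expect_true(all(c("marginean2015", "toole2016", "beattie2017",
                    "fricke2021", "morgan2019") %in%
                    names(bench$skipped)))
  expect_true(all(c("gomez2013", "gomez2014_early", "gomez2014_late",
                    "fricke2021_composite") %in% names(bench$results)))
  # identical predictions give identical metrics
  r1 <- benchmark_rules(sc, comparator_rules()["gomez2014_early"])
  r2 <- benchmark_rules(sc, comparator_rules()["gomez2014_early"])
  expect_identical(r1$results, r2$results)
})
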