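test_that("the default model carries the published entries and exact pre-test odds", {
  m <- default_model()
  expect_equal(pretest_odds(m), 41 / 44)
  expect_identical(round(pretest_odds(m), 2), 0.93)
  expect_equal(m$entries$ga_weeks$cutoff, 28)
  expect_equal(m$entries$ga_weeks$lr_positive, 4.3)
  expect_equal(m$entries$ga_weeks$lr_negative, 0.3)
  expect_equal(m$entries$aao_zscore$cutoff, -1.5)
  expect_equal(m$entries$aao_zscore$lr_positive, 2.8)
  expect_equal(m$entries$isthmus_3vt_zscore$cutoff, -2)
  expect_equal(m$entries$isthmus_3vt_zscore$lr_negative, 0.6)
  expect_identical(m$entries$pv_av_ratio$direction, "ge")
  expect_equal(m$entries$pv_av_ratio$cutoff, 1.6)
  expect_true(all(vapply(m$entries, function(e)
    e$lr_positive > e$lr_negative, logical(1))))
})

test_that("model constructors enforce their invariants", {
  expect_error(lr_entry("ga_weeks", 28, "le", 0.3, 4.3),
               "lr_positive must exceed")
  expect_error(lr_entry("ga_weeks", 28, "le", 4.3, -0.1),
               "strictly positive")
  expect_error(lr_entry("ga_weeks", 28, "le", 4.3, 0.3,
                        lr_positive_ci = c(5, 9)),
               "CI does not contain")
  e <- default_model()$entries
  expect_error(scoring_model(e[c(1, 1, 2, 3)], 41, 44),
               "exactly one entry per parameter")
  expect_error(scoring_model(e, 0, 44), "strictly positive integers")
})

test_that("dichotomization is boundary-inclusive in both directions and strict on missing data", {
  m <- default_model()
  all_true <- dichotomize(fetal_echo_exam(25, aao_z = -2, isthmus_3vt_z = -2.5,
                                          pv_mm = 7.2, av_mm = 4), m)
  expect_true(all(all_true))
  all_false <- dichotomize(fetal_echo_exam(32, aao_z = -1, isthmus_3vt_z = -1,
                                           pv_mm = 4.8, av_mm = 4), m)
  expect_false(any(all_false))
  # values exactly at the cut-offs meet the criterion (le and ge alike)
  at_boundary <- dichotomize(
    fetal_echo_exam(28, aao_z = -1.5, isthmus_3vt_z = -2,
                    pv_mm = 6.4, av_mm = 4), m)
  expect_true(all(at_boundary))
  expect_error(
    dichotomize(fetal_echo_exam(28, aao_z = -1.5, isthmus_3vt_z = -2,
                                pv_mm = 6.4), m),
    "pv_av_ratio")
  # neutral mode: NA criterion, unit LR, result flagged partial
  prof <- dichotomize(fetal_echo_exam(28, aao_z = -1.5,
                                      isthmus_3vt_z = -2, pv_mm = 6.4),
                      m, missing = "neutral")
  expect_true(is.na(prof[["pv_av_ratio"]]))
  res <- compute_post_test(prof, m)
  expect_true(res$partial)
  expect_equal(unname(res$contributions[["pv_av_ratio"]]), 1)
})

test_that("post-test probabilities match the independent multiplication oracle for all 16 profiles", {
  m <- default_model()
  combos <- expand.grid(ga = c(FALSE, TRUE), aao = c(FALSE, TRUE),
                        ist = c(FALSE, TRUE), pvav = c(FALSE, TRUE))
  for (i in seq_len(nrow(combos))) {
    prof <- echo_profile(combos$ga[i], combos$aao[i], combos$ist[i],
                         combos$pvav[i])
    res <- compute_post_test(prof, m)
    expect_equal(res$post_test_probability,
                 oracle_post_test(combos$ga[i], combos$aao[i],
                                  combos$ist[i], combos$pvav[i]),
                 tolerance = 1e-15)
    # probability <-> odds round trip
    expect_equal(res$post_test_probability /
                   (1 - res$post_test_probability),
                 res$post_test_odds, tolerance = 1e-12)
  }
  # the printed-table extremes at display precision
  expect_equal(
    round(compute_post_test(echo_profile(TRUE, TRUE, TRUE, TRUE),
                            m)$post_test_probability, 4), 0.9732)
  expect_equal(
    round(compute_post_test(echo_profile(FALSE, FALSE, FALSE, FALSE),
                            m)$post_test_probability, 4), 0.0261)
})

test_that("score_exam composes dichotomize and compute_post_test on randomized exams", {
  m <- default_model()
  set.seed(42)
  for (i in 1:1000) {
    ex <- fetal_echo_exam(runif(1, 16, 40),
                          aao_z = runif(1, -4, 1),
                          isthmus_3vt_z = runif(1, -4, 1),
                          pv_mm = runif(1, 3, 9),
                          av_mm = runif(1, 2, 6))
    expect_identical(score_exam(ex, m),
                     compute_post_test(dichotomize(ex, m), m))
  }
})

test_that("score_exam reproduces the worked examples", {
  p_hi <- score_exam(fetal_echo_exam(24, aao_z = -2.1,
                                     isthmus_3vt_z = -2.4,
                                     pv_mm = 6.0, av_mm = 3.2))
  expect_false(p_hi$partial)
  expect_equal(p_hi$post_test_probability,
               oracle_post_test(TRUE, TRUE, TRUE, TRUE),
               tolerance = 1e-12)
  p_lo <- score_exam(fetal_echo_exam(35, aao_z = -0.5,
                                     isthmus_3vt_z = -1.0,
                                     pv_mm = 5.0, av_mm = 4.5))
  expect_equal(p_lo$post_test_probability,
               oracle_post_test(FALSE, FALSE, FALSE, FALSE),
               tolerance = 1e-12)
  expect_error(score_exam(fetal_echo_exam(35, aao_z = -0.5,
                                          isthmus_3vt_z = -1,
                                          pv_mm = 5)),
               "pv_av_ratio")
})

test_that("enumerate_profiles is the complete discrete-score oracle", {
  e <- enumerate_profiles(default_model())
  expect_equal(nrow(e), 16L)
  expect_false(is.unsorted(e$post_test_probability))
  expect_equal(sum(e$post_test_probability >= 0.96), 1L)
  expect_equal(min(e$post_test_probability),
               oracle_post_test(FALSE, FALSE, FALSE, FALSE))
  expect_equal(max(e$post_test_probability),
               oracle_post_test(TRUE, TRUE, TRUE, TRUE))
  # flipping any single criterion false -> true strictly raises the
  # probability: all 32 adjacent pairs
  crit <- c("ga_weeks", "aao_zscore", "isthmus_3vt_zscore",
            "pv_av_ratio")
  n_pairs <- 0
  for (i in seq_len(nrow(e))) {
    for (cr in crit) {
      if (!e[[cr]][i]) {
        flipped <- e[i, crit]
        flipped[[cr]] <- TRUE
        j <- which(apply(e[, crit], 1, function(r)
          all(r == unlist(flipped))))
        expect_gt(e$post_test_probability[j],
                  e$post_test_probability[i])
        n_pairs <- n_pairs + 1
      }
    }
  }
  expect_equal(n_pairs, 32L)
})

test_that("cardiac ratios are emitted only when both operands exist", {
  ex <- fetal_echo_exam(30, pv_mm = 6.4, av_mm = 4.0, tv_mm = 12,
                        mv_mm = 8)
  r <- cardiac_ratios(ex)
  expect_equal(r$pv_av, 1.6)
  expect_equal(r$tv_mv, 1.5)
  expect_null(r$mpa_aao)
  expect_null(r$isthmus_da)
  expect_equal(cardiac_ratios(fetal_echo_exam(30, pv_mm = 4,
                                              av_mm = 4))$pv_av, 1)
  expect_null(cardiac_ratios(fetal_echo_exam(30, pv_mm = 4))$pv_av)
})

test_that("gestational dating follows the 7-day discordance rule", {
  expect_equal(resolve_gestational_dating(12.0, 13.2, TRUE), 13.2)
  expect_equal(resolve_gestational_dating(12.0, 13.0, TRUE), 12.0)
  expect_equal(resolve_gestational_dating(12.0, 12.5, FALSE), 12.5)
})

test_that("gestational age parses decimal and W+D forms", {
  expect_equal(parse_ga("24+3"), 24 + 3 / 7)
  expect_equal(parse_ga(24.5), 24.5)
  expect_equal(parse_ga("31"), 31)
  expect_error(parse_ga("24+8"), "days component")
  expect_error(parse_ga("abc"), "cannot parse")
})

test_that("the shipped model JSON round-trips to the default model exactly", {
  path <- system.file("extdata", "model_default.json",
                      package = "coarctscore")
  expect_identical(read_model(path), default_model())
  tmp <- tempfile(fileext = ".json")
  write_model(default_model(), tmp)
  expect_identical(read_model(tmp), default_model())
})
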