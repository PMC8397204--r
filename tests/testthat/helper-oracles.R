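# Independent oracles used across the suite. These deliberately avoid
# the package's own code paths: brute force over pairs/profiles, direct
# closed forms.

# AUC by exhaustive pairwise comparison (ties count 1/2).
oracle_auc_pairwise <- function(scores, outcome) {
  x <- scores[outcome]
  y <- scores[!outcome]
  total <- 0
  for (xi in x) total <- total + sum(xi > y) + 0.5 * sum(xi == y)
  total / (length(x) * length(y))
}

# Youden-optimal threshold by exhaustive evaluation of every attained
# threshold (>= rule), ties broken toward higher specificity.
oracle_youden <- function(scores, outcome) {
  thr <- sort(unique(scores))
  best <- NULL
  for (t in thr) {
    sn <- mean(scores[outcome] >= t)
    sp <- mean(scores[!outcome] < t)
    j <- sn + sp - 1
    if (is.null(best) || j > best$j ||
        (j == best$j && sp > best$sp)) {
      best <- list(threshold = t, j = j, sn = sn, sp = sp)
    }
  }
  best
}

# Closed-form Wilson interval, written out independently.
oracle_wilson <- function(k, n, z = qnorm(0.975)) {
  p <- k / n
  lo <- (p + z^2 / (2 * n) -
           z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))) / (1 + z^2 / n)
  hi <- (p + z^2 / (2 * n) +
           z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))) / (1 + z^2 / n)
  c(max(0, lo), min(1, hi))
}

# Post-test probability by direct multiplication of the printed model
# constants, independent of the package's model objects.
oracle_post_test <- function(ga_pos, aao_pos, isthmus_pos, pvav_pos) {
  lrs <- c(if (ga_pos) 4.3 else 0.3,
           if (aao_pos) 2.8 else 0.4,
           if (isthmus_pos) 1.8 else 0.6,
           if (pvav_pos) 1.8 else 0.4)
  odds <- (41 / 44) * prod(lrs)
  odds / (odds + 1)
}

# A random cohort of discrete default-model score values (or arbitrary
# continuous scores), with both classes guaranteed present.
random_cohort_scores <- function(n, seed, discrete = TRUE) {
  set.seed(seed)
  repeat {
    if (discrete) {
      vals <- enumerate_profiles(default_model())$post_test_probability
      scores <- sample(vals, n, replace = TRUE)
    } else {
      scores <- runif(n)
    }
    outcome <- runif(n) < plogis(6 * (scores - 0.5))
    if (any(outcome) && any(!outcome)) {
      return(list(scores = scores, outcome = outcome))
    }
  }
}

# A fully populated exam whose four criteria are set as requested.
make_exam <- function(ga_pos, aao_pos, isthmus_pos, pvav_pos) {
  fetal_echo_exam(
    ga_weeks = if (ga_pos) 24 else 34,
    aao_z = if (aao_pos) -2.2 else -0.4,
    isthmus_3vt_z = if (isthmus_pos) -2.6 else -0.9,
    pv_mm = if (pvav_pos) 7.2 else 5.0,
    av_mm = 4.0)
}
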