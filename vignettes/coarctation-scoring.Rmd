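---
title: "Likelihood-ratio scoring for prenatal prediction of aortic coarctation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Likelihood-ratio scoring for prenatal prediction of aortic coarctation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coarctscore)
```

## The clinical problem

Coarctation of the aorta (CoAo) is among the commonest critical congenital
heart defects and also among the most frequently missed before birth. Its
prenatal suspicion rests on an indirect sign — cardiac asymmetry with right
dominance, where the left ventricle and/or ascending aorta look small
relative to their right-sided counterparts. The sign is sensitive but very
unspecific, particularly in the third trimester, so most fetuses referred
for cardiac asymmetry turn out not to have CoAo, yet are delivered in
tertiary centres and undergo postnatal work-up. The practical question is
risk stratification: given asymmetry, how likely is postnatal confirmation
of CoAo?

## The model

`coarctscore` implements a sequential likelihood-ratio (Bayesian) score.
Four parameters are dichotomized at fixed cut-offs:

| parameter                               | criterion | LR+ | LR− |
|-----------------------------------------|-----------|-----|-----|
| gestational age at diagnosis (weeks)    | ≤ 28      | 4.3 | 0.3 |
| ascending aorta z-score                 | ≤ −1.5    | 2.8 | 0.4 |
| aortic isthmus z-score (3VT view)       | ≤ −2      | 1.8 | 0.6 |
| pulmonary/aortic valve ratio            | ≥ 1.6     | 1.8 | 0.4 |

Starting from pre-test odds given by the derivation cohort's class counts
(41 CoAo / 44 no CoAo), each criterion multiplies the odds by its LR+ when
met and its LR− when not:

$$\text{odds}_{post} = \frac{41}{44}\prod_{i=1}^{4} LR_i,\qquad
p = \frac{\text{odds}_{post}}{\text{odds}_{post}+1}.$$

The model assumes conditional independence of the four criteria given the
outcome — the usual (and admittedly optimistic) assumption behind
multiplying likelihood ratios. Because each input is dichotomized, the
score can emit only $2^4 = 16$ distinct probabilities:

```{r}
e <- enumerate_profiles(default_model())
round(e$post_test_probability, 4)
```

Three numerical choices matter and are fixed deliberately:

* **Pre-test odds are the exact fraction 41/44** (≈ 0.9318), not the
  two-decimal display value 0.93. Rounding before the multiplication chain
  perturbs the fourth significant digit of every output; rounding happens
  only at display time.
* **Cut-offs are boundary-inclusive** exactly as written (≤ / ≥): a fetus
  at 28 + 0 weeks, an ascending-aorta z of exactly −1.5, or a PV/AV ratio
  of exactly 1.6 meets the criterion.
* **Missing parameters are an error by default.** The score was designed
  with all four parameters always available; silently imputing would
  misrepresent it. An explicit `missing = "neutral"` mode substitutes a
  unit likelihood ratio and flags the result as `partial` for triage use.

Published LR confidence intervals are stored on the model object but are
not propagated into probability intervals: no propagation method is
defined for the sequential-LR construction, and inventing one would imply
precision the score does not have.

## Z-score references

The score consumes z-scores of the ascending aorta and of the aortic
isthmus in the three-vessels-and-trachea view. Published fetal cardiac
reference equations virtually all take the form
$z = (t(y) - \mu(x))/\sigma(x)$ with $t$ the identity or natural log and
$\mu,\sigma$ polynomials in gestational age (or femur length when dating
is unavailable). `zscore_reference()` captures exactly that family, with
coefficients loaded from JSON, so any published equation set can be
plugged in. The package itself ships only synthetic, clearly-labelled
fixture coefficients (`zrefs_synthetic.json`, log-linear in gestational
age): it deliberately asserts no published equation, keeping the pipeline
runnable end-to-end without vouching for coefficients that would have to
be transcribed from elsewhere. The default predictor is gestational age
throughout; femur-length-based references are supported as an alternative
predictor.

## Validation machinery

`validate_cohort()` reproduces a prospective-validation analysis on any
cohort with known postnatal outcomes:

* **ROC/AUC.** The empirical ROC uses the attained score values as
  thresholds (at most 16 for the default model, prediction positive at
  score ≥ threshold). The AUC is computed in Mann–Whitney form with ties
  counted 1/2; the trapezoidal integral of the ROC polygon is kept as an
  independent route and the two agree to 1e−12 by construction. The AUC
  CI uses DeLong's placement-value variance — the paper trail for such
  analyses rarely names the CI method, and DeLong matches the
  nonparametric default of the common commercial packages.
* **Operating points.** "Best balance between sensitivity and
  specificity" is operationalized as the Youden index maximum, with ties
  broken toward higher specificity (the clinical motivation is avoiding
  false referrals). Maximum sensitivity takes, among thresholds attaining
  maximal sensitivity, the one with highest specificity; maximum
  specificity conversely, restricted to thresholds with non-zero
  sensitivity. Thresholds are reported both as exact attained
  probabilities and as rounded display percents.
* **Proportion CIs.** Sensitivity, specificity, NPV and PPV carry Wilson
  score intervals — asymmetric near 0/1 and bounded in [0, 1], consistent
  with intervals like "100 (91.0–100)" seen in this literature. A metric
  with a zero denominator is reported undefined, never silently zero.
* **Subgroups and bands.** Early onset is diagnosis at ≤ 28 weeks
  (inclusive), late strictly after. Probability bands are half-open:
  [0, low), [low, high), [high, 1], with defaults 0.35 and 0.96. The
  printed integer percents in this literature are best read as labels of
  the discrete score values nearest those edges; the discrete score
  values adjacent to the defaults are ≈ 0.3604, ≈ 0.5357 and ≈ 0.9732,
  which is why a cut-off quoted as "53%" or "96%" is not exactly
  attainable from the printed LRs — the analysis reports the attained
  values alongside the rounded labels.
* **Group comparisons.** Continuous variables use a Welch t-test when
  both outcome groups pass a Shapiro–Wilk screen at α = 0.05, otherwise
  Mann–Whitney; categorical variables use chi-square unless an expected
  cell count falls below 5, then Fisher's exact test. Constant variables
  are flagged degenerate rather than tested.

## Comparator rules

`comparator_rules()` registers the other published rule-based CoAo
predictors for head-to-head benchmarking on the same records. Only rules
whose decision procedure is fully stated are evaluable; rules published
as parameter lists without an aggregation rule are registered as
descriptive-only and raise an error if evaluated — guessing their logic
would benchmark an invention. One oddity is preserved on purpose: the
Beattie rule is implemented with MPA/AAo ≤ 0.65 exactly as printed, even
though right dominance predicts a *large* MPA/AAo in CoAo; treat its
output accordingly. The two Fricke sub-rules are also exposed
individually, since separate accuracies are reported per sub-rule.
`benchmark_rules()` skips rules whose required measurements a cohort
lacks, recording the reason, rather than failing or silently predicting
negative.

## The synthetic cohort generator

Real validation cohorts of this kind are not publicly available, so the
package carries a generator (`generate_cohort()`) that emulates the
statistical structure the analysis needs: two outcome classes, an
early/late-onset mixture with class-dependent early fractions,
truncated-normal gestational ages per onset group, class-conditional
normal z-scores for the two aortic structures, a class-conditional
lognormal PV/AV ratio back-filled into valve diameters through a
GA-linear aortic-valve baseline, and qualitative findings (PLSVC at a
class-independent rate; a redundant foramen ovale flap enriched in
late-onset non-CoAo fetuses, matching its reported role as an asymmetry
mimic). Raw diameters are reconstructed from the z-scores through the
synthetic references, so z and millimetre values are mutually consistent.

`default_paper_like_config()` fixes the study conditions: n = 179,
prevalence 0.218, early fractions 34/39 (CoAo) and 34/140 (no CoAo)
implied by the published subgroup denominators, and class-conditional
distributions whose criterion-positivity rates are back-solved from the
likelihood ratios via Sn = LR⁺(1 − Sp) and (1 − Sn) = LR⁻·Sp (e.g. an
ascending-aorta criterion positive in ~70% of CoAo and ~25% of non-CoAo
fetuses). Class-conditional SDs are not reported anywhere and are chosen
once at plausible values (1 z-unit; 0.11 on the log-ratio scale); the
manifest flags them as assumptions. This is calibration, not validation:
reproducing the published group means or AUC from the generator would be
circular and is deliberately not asserted anywhere in the test suite.

All draws come from one seeded stream in a fixed documented order, each
as a standard deviate transformed afterwards, so cohorts are
bit-reproducible and shifting a class mean under the same seed moves
every affected record monotonically — which is what makes the
AUC-vs-separation monotonicity property exactly checkable.

What the generator does *not* model: longitudinal growth across serial
scans (only the first diagnostic exam is generated), correlation between
the four criteria beyond what the class label induces, measurement error
in the qualitative findings, and the referral-pattern drift that shapes
real cohorts. Passing tests on synthetic cohorts therefore demonstrate
that the machinery is correct under the stated data model, not that the
score generalizes clinically.

## Problem sizes used in the test suite

The suite exercises the dual-route AUC identity and Youden-vs-exhaustive
search on 500 random cohorts of n = 40, parameter recovery on one
n = 5000 cohort (3 standard-error bands), the separation–AUC
monotonicity on five n = 2000 cohorts sharing a seed, and the end-to-end
CLI chain on the n = 179 paper-like configuration. These sizes give
comfortable statistical resolution for the properties checked while
keeping the default test run fast.

## Known limitations

* The score's conditional-independence assumption is inherited, not
  tested; on real data the four criteria are correlated (all reflect
  left-heart size), so post-test probabilities at the extremes are
  likely overconfident.
* The printed LRs are two-significant-digit values; the discrete score
  probabilities they generate differ by up to ~1.5 percentage points
  from operating points quoted from unrounded internal values.
* Pre-test odds travel with the derivation cohort's prevalence (48%);
  in populations with lower CoAo prevalence among asymmetry referrals
  the absolute probabilities overestimate risk even when discrimination
  is preserved — which is exactly why cut-off re-calibration on the
  target population matters.
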