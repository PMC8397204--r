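# coarctscore

Prenatal risk stratification for **coarctation of the aorta (CoAo)** in
fetuses referred for cardiac asymmetry with right dominance. Cardiac
asymmetry is the indirect sign that triggers most prenatal CoAo
suspicions, and it has a notoriously high false-positive rate —
especially late in gestation. `coarctscore` implements a likelihood-ratio
multiparameter score that turns four routine echocardiographic inputs
into a post-test probability of postnatal CoAo confirmation, plus the
full validation toolkit (ROC/AUC, operating-point selection, diagnostic
metrics with confidence intervals, subgroup and probability-band
analyses), a benchmark suite of alternative published rules, and a
synthetic cohort generator so every stage runs without patient data.

It is aimed at fetal-cardiology and perinatal-epidemiology researchers
who want to apply, audit or re-calibrate this class of score.

## The score

Four parameters are dichotomized at fixed cut-offs, each contributing a
positive likelihood ratio (LR+) when the criterion is met and a negative
one (LR−) otherwise:

| parameter                            | criterion | LR+ | LR− |
|--------------------------------------|-----------|-----|-----|
| gestational age at diagnosis (weeks) | ≤ 28      | 4.3 | 0.3 |
| ascending aorta (AAo) z-score        | ≤ −1.5    | 2.8 | 0.4 |
| aortic isthmus z-score (3VT view)    | ≤ −2      | 1.8 | 0.6 |
| pulmonary/aortic valve (PV/AV) ratio | ≥ 1.6     | 1.8 | 0.4 |

With pre-test odds 41/44 (the derivation cohort's class counts):

    post-test odds = (41/44) × LR₁ × LR₂ × LR₃ × LR₄
    post-test probability = odds / (odds + 1)

Because every input is dichotomized the score emits exactly 2⁴ = 16
distinct probabilities, from ≈ 2.6% (no criterion met) to ≈ 97.3% (all
met); `enumerate_profiles()` lists them all.

## Worked example

Score one exam (gestational age accepts `"W+D"` strings):

```r
library(coarctscore)
ex <- fetal_echo_exam("26+2", aao_z = -1.8, isthmus_3vt_z = -2.3,
                      pv_mm = 6.8, av_mm = 4.0)
score_exam(ex)
#> Post-test probability of CoAo: 97.3%
#>   odds 36.3499; LRs applied: ga_weeks=4.3, aao_zscore=2.8,
#>   isthmus_3vt_zscore=1.8, pv_av_ratio=1.8
```

All four criteria are met here (26+2 ≤ 28 weeks, −1.8 ≤ −1.5,
−2.3 ≤ −2, PV/AV = 1.7 ≥ 1.6), so the pre-test odds 0.93 are multiplied
by every LR+, giving odds ≈ 36.3 and a 97.3% probability of postnatal
confirmation — a fetus that should be delivered where neonatal cardiac
surgery is available.

Validate on a synthetic cohort emulating a 179-fetus referral
population:

```r
co <- generate_cohort(default_paper_like_config(seed = 20211))
sc <- score_cohort(co)
validate_cohort(sc)
#> Validation report: n = 179, CoAo 34 (19.0%)
#>   AUC 0.898 (0.84-0.96)
#>   best_balance     >= 84%  Sn 73.5%  Sp 93.8%
#>   max_sensitivity  >= 7%  Sn 100.0%  Sp 25.5%
#>   max_specificity  >= 97%  Sn 26.5%  Sp 98.6%
```

Here 34/179 simulated fetuses (19.0%) have CoAo; the score discriminates
with AUC 0.90, and the Youden-optimal operating point predicts CoAo at a
probability ≥ 84% with 73.5% sensitivity and 93.8% specificity on this
particular draw. The same machinery runs from the shell via the wrapper
in `inst/cli/` (`simulate | predict | validate | compare` subcommands).

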