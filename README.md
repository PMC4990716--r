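# moodscreen

Depression screening from daily mobile mental-health ratings.

Mobile mental-health trackers ask patients three short questions a day —
sleep satisfaction, mood, anxiety — on emoticon scales, and administer the
PHQ-9 depression questionnaire every two weeks. `moodscreen` is an R
implementation of the full analysis pipeline that asks whether those daily
ratings can stand in for the questionnaire: it aggregates daily ratings
into biweekly indicator variables, fits a random-intercept logistic panel
model against the PHQ-9 depression label, evaluates screening accuracy by
ROC/AUC with DeLong-type comparison tests and five-fold cross-validation,
and quantifies how patient adherence to self-reporting affects accuracy.
It is aimed at biostatisticians and digital-health researchers working
with patient-reported outcomes.

## The model

Daily ratings in the 14-day window ending on a PHQ-9 test date are
collapsed per item by one of three approaches: **average** (mean raw
score), **frequency** (count of reported days with score strictly above a
per-item cut-off), or **ratio** (that count over the number of reported
days). Depression status is then modelled as

```
P(Depressed_it = 1 | b_i) = logit^-1(β0 + β1 Sleep_it + β2 Mood_it + β3 Anxiety_it + b_i),
b_i ~ N(0, σ_b²)
```

with patient random intercepts integrated out by Gauss–Hermite quadrature.
Screening scores are population-level predicted probabilities
(`b_i = 0`); dichotomization cut-offs are chosen per item by an
AUC-maximizing search over the integer scale. Adherence is a composite of
activeness, timeliness, duration and persistence, clustered by k-means
into higher/lower groups whose AUCs are compared with an
independent-sample chi-square test.

Because patient-level tracker data of this design are not publicly
deposited, the package ships a seeded synthetic-cohort generator
(`simulate_cohort()`) that emulates the data-collection process — latent
severity shared by ratings and PHQ-9, reporting gaps, back-filled reports,
dropout, staggered entry, adherence classes — so every stage is testable.
See the vignette (`vignettes/depression-screening.Rmd`) for the model,
conventions and known limitations.

## Worked example

```r
library(moodscreen)

co  <- simulate_cohort(sim_config(n_patients = 78, seed = 2))
cs  <- optimize_all(co, approach = "ratio")$cutoffs
ind <- build_indicator_table(co, "ratio", cs)
fit <- fit_relogit(design_from_indicators(ind))
print(fit)
```

```
Random-intercept logistic panel model (583 obs, 78 patients, 15 quadrature nodes)
            estimate     se       z      p
(Intercept)  -2.7948 0.2882 -9.6983 0.0000
sleep         3.4252 0.7140  4.7972 0.0000
mood          1.9880 0.7992  2.4874 0.0129
anxiety       0.7513 0.7750  0.9695 0.3323
sigma_b = 0.5119   loglik = -244.5099   converged = TRUE
```

The coefficients are on the ratio-indicator scale: a 0.1 increase in the
sleep ratio (one extra depressed-flagged day per ten reported) multiplies
the odds of a depressed PHQ-9 result by
`odds_multiplier(fit, "sleep", 0.1)` = 1.408, other indicators held fixed.
`sigma_b` is the SD of the patient-level intercept: residual heterogeneity
in baseline severity not captured by the indicators.

```r
roc <- auc_mw(predict_prob(fit, as.matrix(ind[, c("sleep", "mood", "anxiety")])),
              ind$depressed)
print(roc)
cv <- five_fold_cv(co, "ratio", seed = 2)
round(cv$fold_auc, 4); round(cv$pooled_auc, 4)
```

```
AUC = 0.8903 (SE 0.0130; 293 positives, 290 negatives)
[1] 0.9307 0.8740 0.8443 0.9057 0.8823
[1] 0.8836
```

In-sample screening AUC is 0.89 on this synthetic cohort (an AUC above 0.7
is conventionally considered clinically acceptable), and the pooled
out-of-fold AUC of 0.88 shows little overfit: the per-fold models never see
their held-out rows, and cut-offs are re-searched inside each training
split. The adherence analysis follows the same pattern:

```r
profiles <- adherence_profiles(co)
grouping <- label_groups(kmeans_cluster(profiles, k = 2, seed = 2), profiles)
adh <- group_auc_comparison(co, grouping, "ratio")
adh$comparison
```

`run_full(run_config(...))` orchestrates all stages for every requested
approach and writes `indicators_*.csv`, `cutoffs.json`, `fit.json`,
`roc.json`, `cv.json`, `adherence.csv`, `comparison.json` and a
human-readable `summary.txt`, each stamped with the config hash and seed;
identical configs reproduce byte-identical outputs. A thin command-line
wrapper lives at `inst/scripts/moodscreen-pipeline.R`.

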