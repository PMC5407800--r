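# cutselect

Choosing how to categorize a continuous risk factor — a biomarker, a lymph
node count, body-mass index — into ordinal risk groups means answering two
questions: **how many cutoff points**, and **where**. `cutselect` answers
both, for right-censored survival outcomes and for binary outcomes:

* **Number of cuts** (`find_cut_number()`): fit the grouped model for each
  candidate count K and minimize the Akaike information criterion,
  AIC = 2p − 2ℓ, with p = K regression parameters for the Cox partial
  likelihood and p = K + 1 (intercept included) for logistic regression. By
  default each K is evaluated at outcome-blind equal-quantile cuts, which
  avoids the optimism of scoring each K at its own searched maximum (see the
  vignette for the simulation evidence behind this default).
* **Location of cuts** (`search_cutpoints()`): exhaustive, exact search over
  all feasible cut tuples maximizing a significance criterion — the
  (K+1)-sample log-rank statistic or Cox likelihood-ratio test for survival;
  the logistic likelihood-ratio test, the AUC of the ordinal group score, or
  a Pearson chi-square baseline for binary outcomes. Group-size and
  event-count floors keep the splits stable; ties break to the smallest
  cuts, so results are deterministic.
* **Hold-out validation** (`split_cohort()`, `validate_holdout()`): refit
  the discovered grouping on an untouched test cohort, optionally adjusted
  for covariates, reporting hazard/odds ratios, confidence intervals, and a
  global likelihood-ratio test — the honest replacement for the optimistic
  minimal p-value at searched cuts.
* **Graphics**: a spline-smoothed hazard-ratio curve (`smooth_hr_curve()`)
  to judge whether risk is monotone (one cut) or U-shaped (two), per-group
  Kaplan–Meier curves, AIC profiles, and search surfaces.
* **Synthetic cohorts** (`simulate_survival_cohort()`,
  `simulate_binary_cohort()`, four `simulate_scenario()` presets): seeded
  generators with known true cutpoints, exact proportional hazards within
  groups, configurable censoring, and optional covariates.
* **Command line**: `inst/cli/findcut.R` with `simulate` / `findnum` /
  `locate` / `validate` subcommands.

A value equal to a cut joins the upper group throughout: K cuts
c₁ < … < c_K assign subject i to group #{k : zᵢ ≥ c_k}.

## Worked example

A cohort of 797 subjects whose hazard is U-shaped in a BMI-like risk factor
(true cuts at 19.88 and 29.59), split 497 training / 300 testing:

```r
library(cutselect)
cohort <- simulate_scenario("bmi", n = 797, seed = 1)
parts  <- split_cohort(cohort, n_train = 497, seed = 2)

find_cut_number(parts$train, K_range = 0:2)
#> AIC profile ( survival  outcome); best K = 2
#>  K    loglik n_params      aic               cuts delta_aic
#>  0 -597.0453        0 1194.091                  - 1.0165088
#>  1 -595.8336        1 1193.667           23.96624 0.5930736
#>  2 -594.5371        2 1193.074 22.68914, 25.84500 0.0000000

located <- search_cutpoints(parts$train, K = 2, criterion = "logrank")
located
#> Cutpoint search [ logrank ], K = 2
#>   best cuts: 19.76993, 29.77475  value = 42.58716  (df = 2, p = 5.653e-10)
#>   tuples evaluated: 60725 ; rejected: 18278

validate_holdout(parts$test, cuts = as.numeric(located$best))
#> Hold-out validation ( survival ), cuts at 19.76993, 29.77475
#> n = 300 ; events/cases = 63
#>  term     HR ci_low ci_high        p
#>  grp1 0.2871 0.1496  0.5512 0.000177
#>  grp2 1.4803 0.7069  3.0996 0.298248
#> Global LRT: statistic = 29.618 (df = 2), p = 3.704e-07
```

AIC picks two cuts; the search places them at 19.77 and 29.77, close to the
generating 19.88/29.59; on the held-out 300 subjects the middle group's
hazard is 0.29 times the low group's (the U shape) and the grouping
validates globally at p = 3.7 × 10⁻⁷.

For binary outcomes the same workflow uses `criterion = "logistic_lrt"`,
`"max_auc"`, or `"chi2"`, and `classification_metrics()` summarizes
sensitivity/specificity of the induced classification.

## Documentation

See the vignette `vignettes/cutpoint-selection.Rmd` for the model, the
reasoning behind the defaults (quantile-based AIC evaluation, group floors,
tie-breaking, spline trimming), and known limitations — chiefly that
significance at searched cuts is optimistic and should be read
descriptively, with hold-out validation supplying the inference.
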