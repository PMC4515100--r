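---
title: "Assessing prediction-model performance with multiply imputed covariates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing prediction-model performance with multiply imputed covariates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(miperform)
```

## The problem

Clinical prediction models are routinely derived on datasets where some
covariates are missing for some individuals while outcomes are fully
observed. Multiple imputation (MI) handles the derivation step: the missing
covariates are replaced by $M$ plausible draws, the model
$y_i = h(x_i \beta)$ is fitted to each completed dataset, and the
imputation-specific coefficient vectors $\hat\beta^{(k)}$ are combined by
Rubin's rules into a pooled vector $\bar\beta$.

Assessing the *performance* of such a model is less settled, because a set
of predictions must first be constructed, and there are many ways to do it.
This package implements the full taxonomy and the machinery to compare the
resulting performance estimates by simulation.

## The prediction taxonomy

Crossing three covariate sources with three treatments of the imputation
replicates gives nine constructions:

| covariate source | replicated | pooled response | pooled linear predictor |
|---|---|---|---|
| fully observed rows | P1 | P2 | P3 |
| primary imputations $x^{(k)}$ | P4 | P5 | P6 |
| secondary imputations $x^{(j)}$ | P7 | P8 | P9 |

The *primary* imputations are the ones used to derive the model; their
conditional models include the outcome, as good imputation practice
requires. The *secondary* imputations are drawn by a second chained-equations
run that excludes the outcome, imitating a future clinical setting where the
outcome is unknown at prediction time. Any construction can use either the
imputation-specific coefficients $\hat\beta^{(k)}$ or the pooled $\bar\beta$
(`coef_mode`). For the identity link, P2 = P3, P5 = P6 and P8 = P9 exactly;
under the logit link the two pooling scales differ by a Jensen gap.

Two evaluation strategies then turn predictions into a performance estimate
(MSPE/Brier score, AUROC, or calibration slope):

* **pooled performance** — compute the measure within each replicate and
  combine the $M$ estimates by Rubin's rules
  ($T = W + (1 + 1/M)B$);
* **pooled prediction** — average the predictions first (P2/P3/P5/P6/P8/P9)
  and compute one measure.

The central caveat the package exists to demonstrate: averaging predictions
built from imputations that *saw the outcome* (P5/P6) removes exactly the
between-imputation noise and leaves a deterministic function of the observed
$x$ **and $y$**, so measures computed on them are optimistic. *Ideal*
performance (all predictors observed in future use) is best estimated by
pooled performance on P4; *pragmatic* performance (missingness persists in
future use) by P7–P9 or by partial prediction models.

### Partial prediction models

The second pragmatic strategy fits one model per observed-covariate pattern
— each fitted to *all* individuals of every primary imputed dataset, not to
the pattern subset — and routes each individual to the model whose covariate
set equals their observed covariates. Predictions therefore never read an
imputed value (the test suite enforces this by poisoning masked cells).
Patterns absent from the derivation data raise a routing error rather than
silently falling back; the data offer no principled fallback model.

## The synthetic data generator

The original trial data (a multicentre psychosis case-management trial,
n = 708) are not public, so the generator emulates them:

* **Marginals** follow the published baseline table. Continuous covariates
  are generated on their transformed modelling scale — `log1p(cprs0)`
  ~ N(2.73, 0.82²), `log(onset)` ~ N(4.62, 0.98²), `log(distot)`
  ~ N(−0.07, 0.81²) — and stored on the natural scale. `age` ~
  N(38.29, 11.64²) truncated to the trial's 18–65 eligibility window by
  redrawing only its idiosyncratic latent component. `sex` is coded
  1 = male (57%) and `status` 1 = outpatient (59%); the source table does
  not state the 0/1 coding, so it is fixed here once. `centre` has four
  levels with probabilities taken from the published *counts*
  196/158/201/153 (the printed percentages are internally inconsistent).
* **Joint structure** is not published. A Gaussian copula with a single
  exchangeable latent correlation (default 0.2) couples all covariates —
  one tunable knob that keeps every covariate univariately predictive and
  mutually correlated. This is the main respect in which the synthetic data
  differ from the real trial: cells of the simulation results that are
  sensitive to the covariate joint (the absolute values of the MI rows) are
  reproduced qualitatively, while distribution-free quantities (the
  full-data MSPE, the exact calibration identities, all directional
  orderings) are reproduced quantitatively.
* **Outcomes** are simulated from the published generating models: a linear
  model for the transformed symptom score with intercept 1.64, `cprs0`
  coefficient 0.34 (0.68 in the strong-predictor variant) and Gaussian
  noise N(0, 0.61). The noise term is interpreted as a *variance*: that
  interpretation reproduces the printed full-data MSPE of ≈ 0.598
  (analytically $\sigma^2 (n-p)/n = 0.601$ with $p = 10$), whereas an SD
  interpretation would give ≈ 0.37. Two logistic models (prevalences ~26%
  and ~9%) cover discrimination.
* **`occgp_missing`**, the auxiliary indicator that drives the MAR
  mechanism, is drawn from a fixed logistic model in age, sex and status
  (coefficients 0.03, −0.4, 0.5; intercept −2.67 chosen once to give the
  published ~19% prevalence). Only the indicator matters downstream, so no
  underlying occupation value is generated.

## Missingness mechanisms

Three mechanisms delete covariate values (never outcomes), with exact-$k$
deletion (half-up rounding) rather than Bernoulli thinning:

* **independent MCAR** — 30% of `cprs0`, 10% each of `onset`, `distot`;
* **monotone MCAR** — three disjoint random 10% subgroups with nested
  deletion, so missing `distot` ⇒ missing `onset` ⇒ missing `cprs0`;
* **staged monotone MAR** — at each of three stages a logistic model for
  `occgp_missing` on the stage's drivers is fitted among not-yet-deleted
  individuals and the top fraction of fitted probabilities is deleted
  (fractions 1/10, 1/9, 1/8 for the 30% scenario; 1/5, 1/4, 1/3 for 60%).
  `centre` is excluded from the stage models. Ties in fitted probabilities
  are broken by seeded random jitter.

## Imputation

Chained equations with predictive mean matching, written for exactly the
shipped scenarios (continuous incomplete variables; binaries and
categoricals are never missing here, so no logistic imputation method
exists). Within each of the $M$ chains: initial fill by random draws from
the observed values; variables visited in order of increasing missingness
for `iterations` full cycles; each visit regresses the variable (on its
transformed scale) on all other model covariates — plus the outcome iff the
stack is primary — draws the residual variance from its scaled
inverse-$\chi^2$ posterior and the coefficients from their Normal
posterior, and imputes each recipient with the observed value of one of the
`donors` nearest donor predictions (type-1 matching: donors predicted with
$\hat\beta$, recipients with $\beta^*$).

Defaults: `donors = 5` (a pool of 1, the older software default, is
available but noisier), `iterations = 10`. Each chain derives its own
sub-seed from the master seed via two rounds of multiplicative congruential
mixing mod $2^{31}-1$, so (`M`, config, seed) fully determine the stack.
Donor search uses a constant-width window in the sorted donor predictions
(the `donors` nearest predictions provably lie within `donors` sorted
positions of the insertion point), with random tie-breaking.

## The scenario engine

`run_scenario()` executes, per replicate: fresh covariates (a
`fixed_covariates` flag instead reuses one covariate base, matching a
conditional-on-covariates design), outcome simulation, missingness, primary
and secondary imputation, full and partial model fits, all nine prediction
constructions under both strategies, plus full-data and complete-case
reference analyses — each reference fitting *and evaluating its own model*.
Failed replicates are redrawn with fresh sub-seeds; more than 5% failures
aborts. Raw replicate values are stored paired so one-sided paired t-tests
across methods can be recomputed; summaries report the mean and Monte Carlo
error (SD/√reps), with MSPE scaled ×100.

The canonical study is 1000 replicates at n = 708 with $M = M_2 = 5$. The
shipped tests use desk-scale sizes chosen to keep Monte Carlo error small
relative to the effects being detected: 500 replicates for the full-data
MSPE (MC error ≈ 0.14 on a ×100 scale), 200 replicates for the directional
orderings (paired tests at α = 0.01 have overwhelming power there, since the
method contrasts are strongly positively correlated within replicates), and
200 replicates for coefficient recovery.

## Numerical choices and degenerate inputs

* Rubin pooling uses denominator $M-1$ for $B$ and returns the zero matrix
  at $M = 1$, so all strategies degenerate gracefully to the single-dataset
  analysis.
* Identity-link fits are exact least squares via QR; rank deficiency is an
  error naming the aliased terms (no silent dropping in analysis models; the
  imputation conditional models *do* drop collinear columns with a warning,
  since an imputation chain must keep running).
* Logistic fits use IRLS (max 100 iterations, deviance tolerance 1e-8);
  non-convergence and single-class outcomes are errors naming the
  imputation.
* AUROC uses midranks, so tied scores contribute half-concordances exactly;
  its variance is Hanley–McNeil (a bootstrap would be prohibitive inside
  1000-replicate simulations).
* `pool_on_linear_scale()` never inverts probabilities at 0/1: replicated
  sets always carry their linear predictors alongside the response values.
* P7 under imputation-specific coefficients uses the full $M_2 \times M$
  grid of (dataset $j$, coefficient $k$) pairs — the only convention
  well-defined when $M \ne M_2$ — with a `paired` option for sensitivity
  checks; Rubin's rules treat the grid cells as a flat set of replicates.

## Limitations

* The synthetic covariate joint is exchangeable-Gaussian on the latent
  scale; real trial data have richer dependence, so MI-row table cells are
  matched qualitatively, not cell-by-cell.
* No MNAR mechanisms, no missing outcomes, no imputation of categorical
  variables, no optimism correction, and no derivation/validation splitting:
  the scope is performance assessment within the derivation data.
* Calibration output is the slope only; calibration plots should be drawn
  per imputation rather than pooled.

## A worked example

```{r example, eval = FALSE}
library(miperform)

full <- simulate_outcome(generate_covariates(708, seed = 1),
                         builtin_model("linear"), seed = 2)
md   <- apply_staged_mar(full, mar_stages("30"), seed = 3)
prim <- impute_chained(md, M = 5, seed = 4)
sec  <- impute_chained(md, M = 5, include_outcome = FALSE, seed = 5)

cs <- fit_per_imputation(prim, link = "identity")
p4 <- predict_per_imputation(cs, prim)   # ideal
p7 <- predict_per_imputation(cs, sec)    # pragmatic

pool_performance(full$y, p4, "mspe")     # pooled performance
evaluate_pooled_prediction(full$y, pool_on_response_scale(p4), "mspe")

pm <- fit_pattern_models(prim, enumerate_patterns(md), "identity")
pool_performance(full$y, predict_partial(pm, md), "mspe")
```
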