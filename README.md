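# flowcfr

Individualized treatment effects for the first escalation step in acute
respiratory failure: given an ICU encounter flagged as at risk of intubation,
should the first non-invasive support be **NIV** (non-invasive
positive-pressure ventilation) or **HFNC** (high-flow nasal cannula)?
flowcfr estimates, per encounter, the individualized treatment effect (ITE)
on the probability of subsequent invasive mechanical ventilation (IMV),

```
ITE = P(IMV | NIV) − P(IMV | HFNC),
```

from observational cohorts in which the administered arm is confounded by
measured covariates and by unmeasured severity. It is written for
biostatisticians and clinical-ML researchers studying counterfactual
modelling of treatment choice in critical care.

## The model

A three-stage counterfactual estimator:

1. **Balanced representation (Stage 0).** A staleness gate (learnable
   per-channel decay in the time since last measurement) and a feedforward
   encoder produce a representation φ; two arm-specific logistic heads
   predict the factual outcome. The loss is the factual cross-entropy plus
   λ times the **exact** empirical Wasserstein-1 distance between the
   per-arm representation clouds (quantile coupling in 1-D, a
   transportation-simplex solver otherwise):
   `L0 = BCE + λ · W1({φ}_NIV, {φ}_HFNC)`.
2. **Conditional outcome flow (Stage 1).** With Stage 0 frozen, a
   conditional normalizing flow models p(y | φ, a) over the uniformly
   dequantized, logit-transformed binary outcome, trained by exact
   change-of-variables maximum likelihood.
3. **Latent adjustment (Stage 2).** A second flow, conditioned on φ only,
   re-models the latent distribution through the composed likelihood — the
   mechanism intended to absorb arm-specific latent shifts from hidden
   confounding.

Inference pushes common standard-normal draws through Stage 2 then Stage 1
once per arm; the ITE is the difference of the two Monte-Carlo event
probabilities, with a ±0.001 indifference band (boundary inclusive) around
zero. Baselines: the Stage-0 heads alone (CFR), an X-Learner with penalized
base learners, and a Causal Forest adapter (skips with a diagnostic when the
grf backend is absent). A synthetic ICU cohort simulator with stored
potential outcomes, hourly measurement streams, and the full preprocessing
chain (hourly median binning, 24-h carry-forward, mean imputation, 72-h
baselines, short-term slopes, time-since-last-measurement) makes every claim
testable; see the methods vignette (`vignettes/flowcfr-methods.Rmd`).

## A worked example

Recover a constant planted risk difference of 0.10 on a confounder-free
simulated cohort, then run the concordance analysis on a planted-benefit
cohort where an oracle recommends each patient's truly better arm:

```r
library(flowcfr)

cfg    <- sim_config(n_encounters = 2000, gamma_hidden = 0,
                     tau_fn_id = "constant", tau_value = 0.10, seed = 42)
cohort <- simulate_cohort(cfg)
feats  <- features_from_cohort(cohort)
model  <- repflow_train(feats, cohort$a, cohort$y,
                        repflow_config(epochs = 60, patience = 12,
                                       batch_size = 64), seed = 1)
ite <- estimate_ite(model, feats, n_mc = 128, seed = 1)
ite[1:3, ]
#>   encounter_id engine_id   p_imv_niv p_imv_hfnc      ite band_label      n_mc
#> 1            1 repflow_cfr    0.5        0.609  -0.109   NIV_preferred    128
#> 2            2 repflow_cfr    0.156      0.156   0       Indifferent      128
#> 3            3 repflow_cfr    0.0781     0.0703  0.00781 HFNC_preferred    128
round(causal_metrics(ite, cohort), 3)
#>          pehe      ate_bias sign_accuracy
#>         0.085        -0.029         0.713
```

`ite` is negative where NIV is predicted to lower intubation risk; the mean
estimated effect sits within 0.03 of the planted 0.10 (ATE bias −0.029 at
this n; the per-encounter error, PEHE, is 0.085). The concordance analysis
on the planted-benefit cohort:

```r
rec <- label_concordance(oracle_recommendations, cohort_planted)
outcome_rates_by_group(rec)[, 1:5]
#>   actual concordant     n events  rate
#> 1 NIV    TRUE        1023    168 0.164
#> 2 NIV    FALSE        993    322 0.324
#> 3 HFNC   TRUE         987    176 0.178
#> 4 HFNC   FALSE        997    305 0.306
fit_concordance_logistic(rec)
#> <flowcfr_logistic> outcome outcome_imv, n = 4000, AUC = 0.738
#>   term            odds_ratio conf_low conf_high  p_value
#> 1 niv_concordant       0.350    0.284     0.430 2.64e-23
#> 2 hfnc_concordant      0.401    0.328     0.491 9.68e-19
#> ...
```

Concordant encounters show roughly half the IMV rate of discordant ones in
both arms, and the adjusted odds ratios for both concordance indicators are
strongly protective — the pattern the analysis is designed to detect when
individualized recommendations carry real benefit.
`autoplot()` methods draw the four-group bar chart, the ITE histogram and
the odds-ratio forest plot; `tidy()`/`glance()` return tibbles for all
fitted objects. `run_pipeline()` (or the thin `inst/scripts/flowcfr` CLI)
chains simulate → features → train → ITE → evaluation into a reproducible,
checksummed run directory.

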