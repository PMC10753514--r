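# tbmethods

Body-temperature measurement methods and resting metabolic rate in small
birds: a tested, reproducible analysis pipeline.

## The problem

Researchers measuring avian body temperature choose between sensors that
differ in invasiveness and placement — intraperitoneal (IP) and subcutaneous
(SC) temperature-sensing PIT tags, a cloacal thermocouple (CL), and a
cutaneous thermocouple glued to the skin (CU). A stressful method can
inflate both body temperature and metabolic rate; a peripheral sensor can
read low in the cold. Evaluating the methods requires an overnight
experiment in which five birds (one per method, plus an un-instrumented
control, C) share a multiplexed flow-through respirometry system while a
climate chamber steps through 25, 5, −15, 5, 25 °C, and every downstream
quantity — V̇O₂, V̇CO₂, RQ, resting metabolic rate (RMR), calibrated and
quality-controlled temperature profiles, heterothermy indices, and the
mixed-model comparisons — is derived from raw 1 Hz streams.

`tbmethods` implements that entire data path in R, together with a seeded
synthetic-data generator that emulates the raw streams (with ground truth
retained), so the pipeline can be validated end to end by parameter
recovery.

## What is computed

* **Gas exchange** (dry mass balance for a system measuring O₂ on dry,
  CO₂-free air and CO₂ upstream of the scrubbers):

  V̇O₂ = FRᵢ(1−FiCO₂)(FiO₂−FeO₂)/(1−FeO₂),
  V̇CO₂ = [FRᵢ(FeCO₂−FiCO₂) − FeCO₂·V̇O₂]/(1−FeCO₂),
  with water vapour scrubbed mathematically, f·BP/(BP−WVP), and
  RMR (W) = V̇O₂(16 + 5.164·RQ)/60. Incurrent reference fractions are
  interpolated between the trimmed means of the baselines bracketing each
  80-min cycle.
* **RMR extraction**: the most stable 2-min window (minimum SD, 1-s stride)
  per 10-min sample; RMR per bird × ambient temperature is the lowest
  window mean across cycles; mean body temperature is matched to the
  window (closed interval, nearest-reading fallback).
* **Calibration and QC**: per-method OLS of chamber reference on sensor
  reading; isolated PIT misreads >45 °C removed; thermocouple 30–50 °C
  window enforced; readings rounded to 0.1 °C and binned to 1-min means.
* **Heterothermy indices**: per-bird CV (%) and the consecutive disparity
  index D = Σ|ln(x₊₁/x)|/(n−1) of the binned night profile.
* **Inference**: heteroscedastic linear mixed models (random bird
  intercept, method-specific residual variances) with AICc selection over
  interaction candidates, Wald χ² tests, estimated marginal means with
  Bonferroni pairwise contrasts, Welch ANOVA + Games–Howell for the
  variability indices, and design balance checks.

## Worked example

```r
library(tbmethods)

cfg <- experiment_config(seed = 20220125)   # 13 birds/method, full design
exp <- generate_experiment(cfg)             # raw 1 Hz streams + ground truth
proc <- process_experiment(exp)             # calibrate, QC, extract
sel <- fit_candidates_and_select(proc$estimates, "rmr_w")
print(sel)
```

```
Mixed-model selection for rmr_w (ML fits, AICc):
               model     k logLik     AICc dAICc
1:    no_interaction    15 690.91 -1349.14  0.00
2:     method_x_tair    23 694.49 -1336.52 12.62
3:      method_x_age    19 692.77 -1343.21  5.94
4: both_interactions    27 696.35 -1329.66 19.49
selected: no_interaction (refitted with REML)
```

No method × temperature interaction for RMR: how body temperature was
measured did not alter metabolic rate. The marginal means then give the
thermal response:

```r
emmeans_grid(sel, "t_air")
#    t_air    emmean         se
# 1:    25 0.1728061 0.00145742
# 2:     5 0.2230491 0.00145742
# 3:   -15 0.3467532 0.00145742
```

an RMR increase of 29.1% from 25 to 5 °C and 55.5% from 5 to −15 °C, with a
fitted mass coefficient of 0.0251 W g⁻¹. For body temperature the
method × ambient-temperature interaction model wins, and its marginal means
show cutaneous readings 2.37–2.57 °C below every other method at 5 °C while
all methods agree at 25 °C. The variability stage reports CU profiles
68–78% more variable (CV) than the other methods and CL profiles 25% more
variable (D) than the implanted tags.

The same analysis, staged over intermediate CSVs with commentary, is in
`analysis/01_simulate.R` … `05_figures.R` (run them in order from the
repository root; tables land in `results/`).

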