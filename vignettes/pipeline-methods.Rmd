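---
title: "Methods: from multiplexed respirometry streams to method comparisons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from multiplexed respirometry streams to method comparisons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Avian body temperature can be measured with sensors that differ widely in
invasiveness: intraperitoneal (IP) and subcutaneous (SC) temperature-sensing
PIT tags, a cloacal thermocouple (CL), or a thermocouple glued onto the skin
(CU). If a method is stressful it can raise core temperature and metabolic
rate; if it is peripheral it can read low when the animal vasoconstricts in
the cold. `tbmethods` implements, as a tested pipeline, the complete data
path of a study design that compares these four methods (plus an
un-instrumented control group, C) in a small passerine across ambient
temperatures from thermoneutrality (25 degC) to far below it (5 and
-15 degC), with resting metabolic rate (RMR) measured simultaneously by
flow-through respirometry.

Because studies of this kind rarely deposit raw 1 Hz analyzer streams, the
package pairs the pipeline with a seeded synthetic-data generator whose
defaults encode the effect sizes such an experiment is expected to show.
Every downstream stage is therefore testable end to end: the generator
retains its ground truth, and the pipeline must recover it.

## The measurement design

Five birds share one respirometry night. An 80-min multiplexing cycle
consists of a 15-min baseline (animal-free incurrent air), five sequential
10-min bird channels, and a closing 15-min baseline. The climate chamber
steps through 25, 5, -15, 5 and 25 degC, holding each for 160 min (two
cycles) except the final morning 25 degC step (80 min, one cycle). A night
is therefore 9 cycles and 12 h; per ambient temperature a bird contributes
3 cycles (25 degC), 4 cycles (5 degC) or 2 cycles (-15 degC). Body
temperature is recorded at 1 Hz all night: PIT tags at 0.1 degC resolution,
thermocouples continuously but only within a 30-50 degC recording window.

## Gas exchange

The analyzer train meters dry incurrent air upstream (FRi, ml min^-1 STPD)
and samples excurrent air through a water-vapour meter, then a CO2
analyzer, then chemical H2O/CO2 scrubbers, then an O2 analyzer. CO2 is
therefore measured on wet air and is mathematically dried,
`f_dry = f_wet * BP / (BP - WVP)`, while O2 is measured on dry, CO2-free
air. From the dry mass balance (excurrent dry flow = FRi - VO2 + VCO2):

    VO2  = FRi (1 - FiCO2) (FiO2 - FeO2) / (1 - FeO2)
    VCO2 = [FRi (FeCO2 - FiCO2) - FeCO2 VO2] / (1 - FeCO2)

with FiO2/FeO2 on the O2 analyzer's dry CO2-free basis and FiCO2/FeCO2 dry
fractions. Metabolic power uses the oxy-joule equivalent
`RMR (W) = VO2 (16 + 5.164 RQ) / 60` with `RQ = VCO2/VO2`; an RQ outside
0.7-1.0 triggers a warning but is never clamped, since clamping would hide
analyzer problems.

Incurrent reference fractions at every instant are linearly interpolated
between the trimmed means of the two baselines bracketing each cycle
(anchored at the baseline midpoints). The first and last 60 s of each
baseline are discarded as a washout guard; the trim length matches the
~12 s mixing time constant of the plumbing (5 time constants ~ 60 s).
Analyzer drift that is slow relative to one cycle — the realistic regime —
is removed almost exactly by this interpolation; the generator's drift
model (a night-long linear component of 4e-4 plus a sinusoid of amplitude
1e-4 with an 8-h period) was chosen to be of that character while still
large enough that skipping the correction visibly biases VO2.

## RMR extraction and temperature matching

Within each 10-min bird sample, the most stable 2-min window is the
contiguous 120-sample window minimizing the sample standard deviation of
the watt series (stride 1 s; ties broken by the earliest start; the search
series is configurable to VO2, since acquisition software conventions
differ, but watts is the default because that is the quantity analysed
downstream). Per bird and ambient temperature, RMR is the lowest of those
window means across the available cycles — a minimum statistic, exactly as
such studies define RMR, which is why the package validates it against an
exhaustive window search rather than assuming unbiasedness. Mean body
temperature is the average of QC'd 1 Hz readings with timestamps inside the
window, closed on both ends; when a sensor dropped out entirely during the
window the single reading closest in time is used and flagged as a
fallback.

## Temperature calibration and QC

Sensors are bench-calibrated against the climate-chamber reference at 35,
40 and 45 degC (33 paired units in the default fixture). Ordinary least
squares of *reference on reading*, pooled per method, gives the map applied
downstream — this direction predicts true temperature from sensor output,
which is the direction the pipeline needs; per-unit fits are possible but
the pooled default mirrors how such calibrations are reported.

QC rules, in order:

* **Misread removal (PIT only).** A reading above 45 degC is removed when
  every other sample within +/-60 s is at or below 42 degC. The
  neighbourhood rule operationalizes "single erratically occurring": an
  isolated radio misread has normal readings around it, while genuine
  hyperthermia is sustained and is never removed. Removed samples are
  flagged, not dropped, and counted.
* **Range enforcement (thermocouples).** Values outside the closed
  [30, 50] degC recording window become missing with a flag (the recorder
  already refuses them; enforcement makes the rule idempotent on recorded
  data).
* **Rounding and binning.** All readings are rounded to 0.1 degC (the PIT
  resolution, applied to both sensor types for comparability) and then
  averaged in non-overlapping 1-min bins anchored at integer minutes from
  recording start. Rounding precedes binning deliberately; the order is
  observable (38.04 and 38.06 bin to 38.05, not 38.1) and tested. Empty
  bins stay missing.

## Variability indices

Per bird, over the full-night 1-min-binned profile: the coefficient of
variation `CV = 100 sd/mean` (n-1 denominator), and the consecutive
disparity index `D = sum |ln(x[t+1]/x[t])| / (n-1)`, the mean absolute log
ratio of consecutive values. The absolute value matters: without it the sum
telescopes to `(ln x_n - ln x_1)/(n-1)` and the index would measure net
drift, not variability. D is scale-invariant and order-sensitive — an
alternating high/low series scores higher than the same values sorted —
which is exactly what distinguishes it from the CV. Pairs spanning a
missing bin are skipped and the divisor reduced to the number of valid
consecutive pairs.

## Statistical models

The analysis table (one row per bird x ambient temperature) feeds linear
mixed models of RMR and matched body temperature with fixed effects of
method, ambient temperature (factor), age class and body mass, a random
bird intercept, and method-specific residual variances (nlme's `varIdent`).
The candidate set crosses the presence of method x ambient-temperature and
method x age interactions; candidates are fitted by maximum likelihood and
compared with `AICc = -2 logLik + 2k + 2k(k+1)/(n-k-1)` (k from the fitted
object's parameter count, n the number of observations), and the winner is
refitted by REML. nlme performs the likelihood maximization; AICc, the
selection, Wald chi-square tests (block Wald on each term's coefficients),
marginal means, contrasts, Welch's ANOVA and the Games-Howell test are
computed by this package, with the `emmeans` and `car` packages used only
as independent cross-checks in the test suite.

Marginal means are evaluated on a reference grid crossing the model's
factors, averaging over age with equal weights and fixing mass at its grand
mean — the standard reference-grid convention. Pairwise method contrasts
use a normal (z) approximation rather than Kenward-Roger or Satterthwaite
degrees of freedom; with ~65 birds and 195 observations the difference is
immaterial, and this is documented as a deliberate simplification.
Bonferroni families are the pairwise contrasts within each ambient
temperature for the interaction model (all method pairs per panel) and the
single family of method pairs for the additive model. The random intercept
is assessed by a REML likelihood-ratio test against the same model without
it (a generalized least-squares fit); the reported p-value uses the plain
1-df chi-square reference without boundary correction.

For the variability indices, Welch's heteroscedastic ANOVA
(`w_i = n_i/s_i^2`, Satterthwaite-type denominator df) and Games-Howell
pairwise tests (`q = |m_i - m_j| / sqrt((s_i^2/n_i + s_j^2/n_j)/2)`,
Welch-Satterthwaite df, studentized-range reference with k groups) compare
methods. Design balance is checked with one-way ANOVAs on the mass
variables and Pearson chi-square tests of the age x method and sex x method
tables.

## The synthetic generator

The generator emulates the complete raw data of one field season with the
default configuration as the study conditions:

* **Design:** 13 birds per method; one bird of each method per night;
  masses ~N(17, 1.3) g (capture mass sits ~0.3 g above the measurement
  mass, which is centred on the 17 g reference of the RMR model).
* **Metabolic truth:** `RMR(bird, T) = 0.18 W x ratio(T) + 0.026 W/g x
  (mass - 17 g) + bird intercept`, with ratio 1 / 1.29 / (1.29 x 1.53) at
  25 / 5 / -15 degC. The temperature effects are multiplicative (they are
  the percent increases the pipeline must recover); the mass effect is
  additive because the downstream model — like the study design it mirrors
  — fits a single mass coefficient common to all ambient temperatures. The
  absolute baseline 0.18 W at 17 g and the core temperature 38.0 degC are
  free choices, plausible for a resting great-tit-sized passerine at night;
  only ratios and differences carry information.
* **Within-night metabolic structure:** each 10-min sample contains a 3-min
  quiescent plateau at the bird's cycle level (the cycle level itself
  varies ~2% between cycles, scaled per method to motivate `varIdent`),
  placed uniformly at random between 60 and 420 s into the segment so the
  stablest-window rule has a correct answer clear of the washout transient;
  outside the plateau, activity raises and roughens the trace
  (`x (1 + 0.1 + 0.25|OU|)`, 30-s correlation time).
* **Analyzer model:** excurrent fractions follow from the inverse
  mass-balance equations, smoothed by a first-order washout (tau = 12 s) at
  channel switches, plus drift and white noise (O2 2e-5, CO2 5e-6).
* **Temperature truth:** core birds sit at 38.0 degC at 25 degC and 1.5
  degC lower below thermoneutrality; cutaneous streams are additionally
  2.35 / 2.7 degC below core at 5 / -15 degC. Night profiles add a smooth
  fluctuation (sum of sinusoids with 30-90 min periods, SD 1.09 degC) and
  minute-scale jitter (SD 0.15 degC; x1.36 for cloacal thermocouples).
  The slow SD and the cloacal jitter multiplier were calibrated once, by
  simulating the generator and measuring the indices, so that the
  cutaneous-vs-other CV ratio is ~1.7 and the cloacal-vs-implant D ratio is
  ~1.27 — the contrasts the design is meant to exhibit — and then frozen.
  Notably, most of the cutaneous CV excess emerges from the
  ambient-dependent skin-temperature deficit itself rather than from extra
  sensor noise, so `cu_noise_scale` defaults to 1.
* **Sensor artifacts:** per-method systematic miscalibration (offsets
  -0.3/+0.2 degC, gains 1.01/0.995) plus per-unit scatter, recovered by the
  calibration stage; PIT misreads as isolated spikes drawn uniform on
  (46, 50] degC at rate 2e-5 per sample (the lower bound sits 1 degC above
  the removal threshold so that calibration, which can shift readings by a
  few tenths of a degree, cannot move a spike below it — keeping the
  injected-vs-removed bookkeeping exact); thermocouple samples outside
  30-50 degC are never stored.

What the generator does **not** emulate: circadian drift in the underlying
set point, stress-induced hyperthermia dynamics after handling, chamber
temperature transients between setpoints, effective-volume equilibration
beyond the first-order washout, RQ drift within a night, sensor loss or
tag failure, and any correlation between activity and body temperature.
Passing recovery tests therefore demonstrate that the pipeline's
*estimators* are correct and unbiased under realistic noise — not that the
pipeline would be robust to every pathology of live-animal data.

## Numerical choices and degenerate inputs

* Stablest-window variance uses centred cumulative sums (numerically stable
  at 1e-5-level fractions); ties break to the earliest start, making runs
  deterministic.
* Baselines shorter than twice the trim are used untrimmed rather than
  erroring; a cycle without two baselines is a hard error naming run and
  cycle.
* `welch_anova` and `games_howell` refuse groups with zero variance or
  n < 2; the calibration fit refuses a single reference level.
* Empty temperature series pass through QC unchanged; an empty window match
  falls back to the nearest single reading, and a fully missing series
  yields a missing temperature, never a silent zero.
* Model candidates that fail to converge are flagged, excluded from
  selection with a warning, and never silently substituted.

## Problem sizes

The test suite exercises the full default design (13 birds per method, 9
cycles per night) once for model-level checks, and the end-to-end recovery
properties average 10 seeded replicates of the complete pipeline —
1.3 x 10^5 analyzer seconds and 2.2 x 10^6 temperature samples per
replicate — which keeps the whole suite in the minutes range while putting
the Monte-Carlo error of the recovered percentages well under the
tolerances being checked. Structural unit tests run on 2-birds-per-method
experiments.

## Known limitations

* The minimum-across-cycles definition of RMR is slightly downward-biased
  under noise, and ambient temperatures with more cycles (5 degC, four
  cycles) are biased a little more than those with fewer (-15 degC, two) —
  a property of the estimator itself, visible in the recovered -15 vs 5
  percent increase sitting ~2 points above its generating value. The
  package reproduces the estimator, bias and all, rather than "correcting"
  it.
* Wald tests use treatment contrasts and marginal (type-III-style) blocks;
  with interactions present, main-effect chi-squares depend on the contrast
  coding, as they do in any software using that convention.
* The z-approximation for contrasts is slightly anticonservative at these
  sample sizes relative to Kenward-Roger.
* Calibration is linear only; a sensor with genuine curvature over 35-45
  degC would need the (out-of-scope) nonlinear extension.
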