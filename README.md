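# hsrglyc

Analysis pipeline linking the **ex-vivo whole-blood heat shock response**
to **glycaemic status** in longitudinal rodent cohorts.

The heat shock response (HSR) — the anti-inflammatory chaperone program —
declines progressively under chronic positive energy balance, and its
decline precedes clinically visible glycaemic deterioration. A practical
readout is ΔHSP70: whole blood is split into a 42 °C heat-challenged
aliquot and a 37 °C control, HSP70 is quantified by immunoblot
densitometry in both, and

```
ΔHSP70 = HSP70(42 °C) − HSP70(37 °C)
```

on a two-stage normalized scale (per-lane GAPDH division, then division
by the per-round maximum so each experimental round tops out at 1).
`hsrglyc` is for biostatisticians and metabolic-physiology labs who want
that entire analysis — densitometry to clinical thresholds — as tested,
reusable code.

## What it computes

* **Densitometry:** two-stage normalization and per-animal ΔHSP70
  (`normalize_run()`, `delta_hsp70()`), with incomplete 37/42 pairs
  reported rather than dropped.
* **Glycaemic indices:** HOMA-IR = I₀(μU/mL)·G₀(mM)/22.5; QUICKI =
  1/[log₁₀ I₀ + log₁₀ G₀(mg/dL)]; unit conversions (1 μU/mL = 5.975 pM
  human insulin; 5.8 pg/fmol mouse insulin; 18.0182 mg/dL per mM
  glucose); Lee index; metabolic efficiency; status labels at the
  clinical cutoffs (all overridable).
* **Tolerance tests:** incremental AUC (oGTT) and inverted incremental
  AUC (ipITT) by the trapezoid method, with baseline-crossing segments
  split geometrically by similar triangles and only the excursion-side
  area counted.
* **5PL regression:** the asymmetric five-parameter logistic
  y = d + (a−d)/[1+(x/c)ᵇ]ᵍ — multi-start bounded Levenberg–Marquardt
  fitting (`fit_5pl()`), closed-form inversion (`invert_5pl()`),
  half-decline and inflection times (`characteristic_times()`), and
  likelihood-ratio pseudo-R² goodness of fit (`goodness_of_fit()`).
* **Trends and onsets:** OLS trends with 95 % confidence bands, slope
  comparisons, and threshold-crossing onset times (`fit_linear_trend()`,
  `crossing_time()`).
* **Thresholds:** clinical cutoffs mapped to ΔHSP70 levels by inverting
  the fitted index-versus-ΔHSP70 curve (`derive_thresholds()`).
* **Synthetic cohorts:** a seeded generator (`generator_config()`,
  `generate_cohort()`) reproducing the study's structure — two diet
  arms, timepoints 0–22 weeks, n = 6 per arm per timepoint — with
  noise-free truth available for every statistic, plus an end-to-end
  orchestrator (`run_pipeline()`) and a CLI (`inst/cli/hsrglyc`).

## Worked example

Simulate the default cohort, run the pipeline, and read off the fitted
half-decline times and ΔHSP70 thresholds:

```r
library(hsrglyc)

run <- run_pipeline(generator_config(seed = 7), seed = 7)
run
#> ΔHSP70 / glycaemic-status pipeline run (seed 7 )
#>   HFD: half-decline t1/2 = 2.75 weeks, R2 = 0.952, P = 1.37e-29
#>   NC: half-decline t1/2 = 10.72 weeks, R2 = 0.945, P = 2.67e-28
#>   ΔHSP70 thresholds (fasting glycaemia): normal fasting limit 0.1485, IGT onset 0.0920
```

The two `t1/2` values are the weeks at which each arm's fitted ΔHSP70
curve sits midway between its plateaus — the high-fat arm loses half its
heat-shock capacity roughly three times sooner than the chow arm (the
generating truths here are 3.14 and 8.24 weeks; single noisy cohorts
scatter around them). The thresholds are the ΔHSP70 levels at which the
fitted glycaemia-versus-ΔHSP70 curve crosses 5.6 mM and 6.1 mM: animals
above the first are predicted normoglycaemic, below the second in the
type-2-diabetes range. `R2` and `P` are the likelihood-ratio pseudo-R²
and χ² P-value of each 5PL against the overall-mean model.

Individual pieces work standalone:

```r
incremental_auc(c(0, 15, 30), c(5, 7, 3))   # 22.5 mM·min (crossing split at t = 22.5)
homa_ir(10, 5.625)                          # 2.5
p <- calibrate_5pl(7.2, 4.8, 0.2250, 5.6, 0.2125, 6.1)
invert_5pl(p, 5.6)                          # 0.225
```

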