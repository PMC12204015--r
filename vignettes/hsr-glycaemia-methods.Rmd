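---
title: "Methods: linking the whole-blood heat shock response to glycaemic status"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking the whole-blood heat shock response to glycaemic status}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hsrglyc)
```

## The problem and the statistic

Chronic positive energy balance progressively suppresses the heat shock
response (HSR), the anti-inflammatory program that resolves cellular
inflammation. A practical readout of organismal HSR capacity is an ex-vivo
whole-blood heat challenge: a blood sample split into a 42 °C-challenged
aliquot and a 37 °C control, with HSP70 expression quantified by
immunoblot densitometry in both. The statistic of interest is

$$\Delta HSP70 = HSP70_{42^\circ} - HSP70_{37^\circ},$$

computed on a normalized scale. Normalization is two-staged: each HSP70
band is first divided by the GAPDH loading control of its own lane, then
every ratio is divided by the highest ratio observed among all lanes of
the same *experimental round*, so the per-round maximum is exactly one and
every value lies in $[0,1]$ (hence $\Delta HSP70 \in [-1,1]$). The round
is modelled as an explicit identifier; one gel per round is the expected
usage. Taking the round maximum *jointly over both temperature arms* is a
deliberate reading of "the highest value among all animals in each round";
a per-arm maximum would change the scale of every delta and is not
implemented.

In a longitudinal two-arm mouse cohort (normal chow, NC, 16.6 MJ/kg versus
lard-based high-fat diet, HFD, 22.8 MJ/kg; terminal timepoints 0–22 weeks
on diet; six males per arm per timepoint), ΔHSP70 declines with time on
diet, and the decline parallels deteriorating glycaemic status. The
package quantifies both sides of that parallel and joins them by inverse
prediction.

## The 5PL model

ΔHSP70 trajectories (and glycaemic indices as functions of ΔHSP70) are
modelled with the asymmetric five-parameter logistic

$$y = d + \frac{a-d}{\left[1+(x/c)^b\right]^g},$$

with left plateau $a$ (the value at $x=0$), right plateau $d$, location
$c>0$, shape $b>0$ and asymmetry $g>0$. No published functional form
exists for this analysis; this is the standard asymmetric form used by
common curve-fitting tools, on the natural $x$ scale (weeks or ΔHSP70) —
a log-$x$ dialect was rejected because $x=0$ (week zero, absent response)
is a meaningful design point.

Two characteristic times are reported because the field's usage conflates
them:

* the **half-decline time** $x_{50} = c\,(2^{1/g}-1)^{1/b}$, where the
  response is midway between plateaus — this is what $t_{1/2}$ refers to
  throughout;
* the **geometric inflection** $x_{inf} = c\,[(b-1)/(bg+1)]^{1/b}$,
  defined only for $b>1$ and flagged otherwise.

### Fitting

`fit_5pl()` minimises the residual sum of squares by Levenberg–Marquardt
(damped least squares) from a deterministic multi-start grid: plateau
starts from the mean response at the extreme $x$ values, location start
from the $x$ whose response is nearest mid-range, and all combinations of
$b \in \{0.5, 1, 2, 4\}$, $g \in \{0.5, 1, 2\}$ (12 starts). $c$, $b$,
$g$ are optimised on the log scale. Convergence demands relative SSE
improvement below $10^{-10}$ or 500 iterations; the lowest-RSS start wins,
ties broken by start order. The fit is deterministic; the `seed` argument
is provenance only.

The optimiser is boxed: plateaus within the observed response range
± 25 % of its span, $c$ within a factor 100 of the sampled $x$ range,
$b \in [0.05, 50]$, $g \in [0.05, 20]$. The box matters. The 5PL
likelihood is nearly flat along a ridge where the lower plateau escapes
far below the data while $g$ collapses, which inflates $x_{50}$ by an
order of magnitude on designs whose right plateau is barely sampled (a
22-week series with $t_{1/2} \approx 8$ weeks is exactly such a design).
Constraining asymptotes to the vicinity of the data is standard practice
in sigmoid calibration fitting and removes the ridge without biasing
well-identified fits: noiseless data still recover their generating
parameters to $10^{-6}$ relative.

A minimum of $n \ge 6$ observations and three distinct $x$ values is
enforced — five parameters need at least that much design. Flat data fit
with $a \approx d$ and are flagged `degenerate` rather than rejected.

### Inverse prediction and thresholds

The fitted curve is inverted in closed form,
$x = c[((a-d)/(y-d))^{1/g}-1]^{1/b}$, for any response strictly between
the plateaus. `derive_thresholds()` maps clinical cutoffs (5.6 and 6.1 mM
fasting glycaemia; 7.8 and 11.1 mM two-hour postload; HOMA-IR 2.5; QUICKI
0.339 and 0.300; insulinaemia 5–15 μU/mL) to the ΔHSP70 levels at which
the fitted index curve crosses them, together with the healthy side
(derived from the curve's orientation and whether a low index value is
healthy). Cutoffs outside the open plateau interval are flagged
unresolvable — with the admissible interval reported — and the run
continues; a threshold can only be read off a curve that actually spans
it.

### Goodness of fit

Model adequacy is summarised by likelihood-ratio statistics under
Gaussian likelihoods at the MLE variance,
$\log L = -\tfrac{n}{2}[\ln(2\pi\,RSS/n)+1]$, against the overall-mean
null model:

* Maddala's $R^2 = 1-\exp\{2(\log L_0-\log L_1)/n\}$, which for Gaussian
  fits equals the classical $1-RSS_1/RSS_0$ identically (verified
  numerically in the tests);
* a maximum-adjusted ("normalized") $R^2$ dividing by the attainable
  maximum $1-\exp\{2\log L_0/n\}$, Nagelkerke-style, clamped to $[0,1]$.
  For continuous responses with small residual scale the null likelihood
  exceeds one and that "maximum" is vacuous; the normalized value then
  falls back to Maddala's $R^2$ itself. The exact normalization the
  source analysis performed through software-generated residual QQ plots
  is not reconstructable; this adjustment is the documented stand-in and
  deliberately pluggable (McFadden's $1-\log L_1/\log L_0$ is also
  reported);
* $\chi^2 = 2(\log L_1-\log L_0)$ with an upper-tail P-value at **1
  degree of freedom**, exactly as the source analysis prescribes for the
  fitted-versus-overall comparison. A 5-versus-1-parameter comparison
  conventionally uses 4 df, so `p_value_df4` is reported alongside,
  clearly labelled.

## Glycaemic indices and tolerance tests

HOMA-IR is $I_0(\mu U/mL)\cdot G_0(mM)/22.5$; QUICKI is
$1/[\log_{10} I_0(\mu U/mL) + \log_{10} G_0(mg/dL)]$ — base-10
logarithms, the convention of the index, since natural logs would change
values materially. Glucose converts at 18.0182 mg/dL per mM (molar mass);
mouse insulin converts from ng/mL through 5.8 pg/fmol to molar and then
through 5.975 fmol/μU to human-equivalent μU/mL. Status boundaries follow
the stated conventions: fasting 5.6 mM itself is already impaired (IFG is
$[5.6, 6.1)$), HOMA-IR exactly 2.5 is still normal (only values *above*
2.5 are IR), QUICKI exactly 0.339 is still normal. All cutoffs are
arguments, not constants — they are human-derived values applied to mice
by analogy, and a user may well want different ones.

Tolerance tests are summarised by incremental areas with each animal's
own $t=0$ value as its baseline (never a group-average curve): the oGTT
iAUC counts only area above baseline, the ipITT inv-iAUC only area below
it. Mixed-sign trapezoids are split at the exact linear-interpolant
baseline crossing (the similarity-of-triangles construction), and only
the excursion-side triangle counts. Samples exactly at baseline are
zero-height edges; touching without crossing synthesizes no crossing
point. The mirror identity
`inv_iAUC(v) == iAUC(2*baseline - v)` holds by construction, and
refinement (inserting a crossing as an explicit sample) and additivity
identities hold to $10^{-10}$.

Morphometrics: the Lee index $(\text{weight g})^{1/3}/(\text{length cm})$
and weekly metabolic efficiency (energy intake / weight gain, kJ/g).
Weeks without positive gain have undefined efficiency and propagate as
`NA` rather than raising — a zero-gain week is an ordinary observation,
not a user error.

## Linear trends and onset times

Fasting glycaemia, insulinaemia, QUICKI and HOMA-IR versus weeks are fit
by ordinary least squares with analytic standard errors and the pointwise
95 % confidence band $t_{0.975,\,n-2}\,\hat\sigma\sqrt{1/n +
(x_0-\bar x)^2/S_{xx}}$. Onset times (e.g., $T_{IR}$, the week the
glycaemia trend reaches 5.6 mM) are the threshold crossings of the fitted
line; a negative crossing is returned flagged `already_crossed`, not
suppressed. Two-group slope comparisons use the interaction-term t-test
of the pooled model (pooled residual variance).

## The synthetic cohort generator

No cohort data are deposited, so the generator is the package's
first-class data source and defines the study conditions every test and
recovery experiment runs under. Its defaults *are* those conditions and
are anchored to the published design and headline values:

* timepoints 0, 1, 4, 8, 10, 14, 18, 22 weeks, 6 animals per arm per
  timepoint; week-0 (just-weaned) animals are generated for glycaemic
  measurements but excluded from densitometry, matching the design's
  exclusion of just-weaned animals from the heat challenge;
* ΔHSP70 truth: declining 5PLs with plateaus 0.45/0.05, $b=2$, $g=1$, and
  $c$ chosen so the half-decline time is 8.24 weeks (NC) and 3.14 weeks
  (HFD);
* fasting glycaemia truth: lines with slope 0.05 mM/week (the two arms'
  published slopes are statistically indistinguishable) and intercepts
  back-solved so the 5.6 mM crossing sits at 13.1 weeks (NC) and 6.3
  weeks (HFD); insulinaemia lines rise from 8 μU/mL to cross 15 μU/mL at
  102.6 (NC) and 17.8 (HFD) weeks;
* oGTT truth: baseline plus the single-peak shape
  $A\,(t/t_p)\,e^{1-t/t_p}$ (peak increment 9 mM at 15 min by default),
  which peaks once and returns toward baseline; the implementation
  generalises it with a decay constant that reduces to this form at its
  default. ipITT truth: piecewise-linear drop to
  $\text{baseline}\times(1-0.35)$ at 30 min with partial linear recovery
  by 45 min;
* noise: additive Gaussian per channel — the simplest structure
  consistent with mean ± SD reporting — with SDs 0.03 (normalized
  densitometry fraction), 0.15 mM (glucose), 1 μU/mL (insulin). No noise
  model is published; these were chosen once as realistic for the
  respective assays and are not revisited;
* morphometry: deterministic smooth monotone (Michaelis-type) growth
  curves with group-specific plateaus, and constant weekly food masses
  whose products with the diet energy densities (16.6 / 22.8 MJ/kg) give
  the two arms similar energy intakes, as observed;
* the 37 °C arm is flat by default; an optional `baseline37_slope`
  exposes a drift over weeks, since whether the control arm trends with
  time is not settled.

Two generator mechanics deserve explanation. First, randomness is split
hierarchically: each animal's draws come from a stream seeded by a hash
of its identifier folded with the master seed, so identical configs give
byte-identical tables and enlarging the design never perturbs existing
animals. Second, within each experimental round (one round per
timepoint), the stored normalized fractions are *shifted* so the
brightest lane sits exactly at one. A shift preserves every pairwise
ΔHSP70 — unlike a rescaling — while emulating a round whose secondary
normalization is saturated; consequently the downstream per-round
max-division is a no-op and, at zero noise, the recomputed ΔHSP70 equals
the generating truth exactly. This is what makes the zero-noise
identifiability tests exact rather than approximate.

What the generator does *not* emulate: sex differences, housing
temperature, mechanistic body-weight dynamics, immunoblot imaging
artefacts, non-Gaussian assay error, or within-animal correlation across
channels. Passing tests therefore demonstrate that the estimators recover
what they claim under clean Gaussian conditions at the study's design and
effect sizes — not that they are robust to real blots or real glucometers.

## Recovery experiments and problem sizes

Three seeded experiments (`recover_half_decline()`,
`recover_thresholds()`, `recover_crossing()`) quantify estimator
performance at the study conditions, each averaging 50 replicates —
enough for the replicate mean's Monte-Carlo error to sit well inside the
effects of interest while keeping the full suite under a minute:

* half-decline recovery at the published arm values (3.14, 8.24 weeks)
  from weeks {1,…,22}, n = 6/timepoint, SD 0.03. The NC-like arm's mean
  recovers with a persistent ≈ +5–9 % skew: its right plateau is barely
  sampled by week 22, so $x_{50}$ has a right-skewed sampling
  distribution. The median is nearer the truth; the mean is reported
  because that is the quantity the recovery claim is about;
* threshold round trips through 5PLs calibrated (via `calibrate_5pl`,
  $g=1$ fixed — two anchor points identify exactly two free parameters)
  through the published threshold pairs: glycaemia (0.2250, 5.6) and
  (0.2125, 6.1) with plateaus 7.2/4.8 mM (this curve is intrinsically
  steep, $b \approx 15$ — a 0.5 mM index change across 0.0125 of ΔHSP70
  admits nothing gentler); QUICKI (0.2100, 0.339) and (0.1216, 0.300)
  with plateaus 0.28/0.40 ($b \approx 2.9$). Twelve observations at each
  of eight ΔHSP70 levels spanning 0.05–0.45, SDs 0.2 mM and 0.01;
* OLS crossing recovery of the 6.3-week glycaemia onset (SD 0.15 mM).

## Numerical choices, degenerate inputs, limitations

* All closed forms (evaluation, inversion, characteristic times,
  calibration) are exact expressions; the only iterative component is the
  bounded Levenberg–Marquardt refinement.
* Ties in a round's densitometry maximum need no tie-break (division by a
  shared maximum); a round with no positive signal is an error.
* `invert_5pl` refuses plateau and out-of-range responses by naming the
  admissible open interval; `crossing_time` refuses zero slopes.
* Saturated fits ($RSS=0$) report $R^2=1$, $\chi^2=\infty$, $P=0$ as
  documented flags; flat data where fitted and null models coincide
  report $\chi^2=0$, $P=1$.
* The index-versus-ΔHSP70 fits pool the two diet arms into a per-timepoint
  overall mean ΔHSP70 (n = 12 per point) by default, as the source
  analysis does; a per-group mode exists (`pool_groups = FALSE` semantics
  via per-group subsetting) but pooled is the default. With seven
  usable timepoints those fits sit at the five-parameter minimum and are
  the least stable part of the pipeline; the threshold round-trip
  experiments, which control the design, are the calibrated statement of
  threshold recoverability.
* No random-effects layer is fitted anywhere: all fits are fixed-effects
  least squares on per-animal observations.
* Mixed-model group comparisons, multiple-comparison procedures,
  normality screening and human-age mapping are intentionally out of
  scope.
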