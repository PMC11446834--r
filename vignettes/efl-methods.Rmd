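---
title: "Assessing expiratory flow limitation during exercise: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing expiratory flow limitation during exercise: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eflkit)
```

## The measurement problem

During heavy exercise a healthy adult's tidal expiratory flow can reach the
maximal flow the airways can deliver at that lung volume. This state —
expiratory flow limitation (EFL) — is assessed non-invasively by overlaying
the composite tidal flow–volume loop on the maximal expiratory flow–volume
(MEFV) envelope and measuring how much of the tidal volume is spent at
maximal flow. `eflkit` implements that pipeline end to end for incremental
cycle-exercise recordings (pneumotachograph airflow at 200 Hz with an
integrated volume channel), together with the between-day repeatability
statistics used to ask how stable the resulting EFL classification is, and
a synthetic two-visit study generator that provides ground truth for every
quantity the pipeline estimates.

Sign and axis conventions: expiratory flow is positive; the tidal volume
trace rises with inspiration; MEFV work is done on an absolute lung-volume
axis in litres above residual volume (RV), so 0 = RV and FVC = total lung
capacity. The analogue volume channel has an arbitrary additive offset —
only differences within a window are meaningful.

## The MEFV envelope from graded efforts

A single maximal forced expiration underestimates attainable flows at low
lung volumes because thoracic gas compression depresses measured flows at
high effort. The envelope is therefore built from *graded* FVC maneuvers
(roughly 20–100% of maximal effort, performed before and after exercise):
every maneuver is anchored at total lung capacity, interpolated onto a lung
volume grid in exact 0.01 L steps, and the envelope is the pointwise
maximum of flow across maneuvers (`build_mefv()`). Volumes covered by no
maneuver get flow zero, which makes the RV endpoint well defined.
Pre-exercise and post-exercise efforts of one visit are pooled (capturing
exercise-induced bronchodilation); envelopes are never merged across
visits. A minimum of eight maneuvers is the convention for measured data;
fewer is allowed with a message so that small constructed examples work.

The curvature of the descending limb is summarized by the slope ratio
(SR, `slope_ratio()`): at each grid point in the effort-independent region
(20–80% of FVC) the tangent slope dV̇/dV (central finite differences on the
grid) is divided by the chord slope to RV, V̇(v)/v. A straight limb through
RV gives SR = 1; concave limbs give SR > 1. Since the literature the SR
calculation derives from does not restate the chord's anchor, the to-RV
chord is this package's definition: it is the unique choice that makes the
power-law limb V̇ = k·v^a return SR = a exactly. Measured envelopes are
lightly smoothed (5-point moving average, `mefv_smoothing` in
`efl_config()`) before differentiation; analytic curves should be passed
with smoothing off, where the three closed-form cases (linear → 1,
quadratic → 2, square root → 0.5) are reproduced to better than 0.02.

## Drift correction, breath segmentation and compositing

Integrator drift in the volume channel is removed per analysis window by
ordinary least squares on the end-expiratory volumes (the volume minima at
inspiratory-onset zero crossings of flow, found with a ±0.05 L/s hysteresis
band to suppress chatter): the fitted line, re-zeroed at the window start,
is subtracted from the volume trace and the flow trace is untouched
(`correct_drift()`). The correction is idempotent — re-fitting the
corrected trace returns a slope of zero.

Breaths are delimited at inspiratory onsets (`segment_breaths()`);
incomplete first/last breaths are discarded and breaths with inspired
volume under `min_VT` (default 0.10 L — swallows, coughs) are dropped.
"Aberrant" breaths are otherwise left to an explicit exclusion list rather
than an automatic outlier rule, so any exclusion is auditable.
Ventilatory parameters are epoch averages over the complete breaths in the
~30 s window: VT is the mean expired volume, fB the breath count over the
spanned time, VE = VT × fB.

The composite tidal loop (`composite_average()`) resamples each breath's
limbs onto a common *relative-volume* grid (0..1 of that breath's own VT,
101 bins by default) and averages flow per bin, rescaling the grid to
0..mean VT. Relative-volume compositing (rather than time averaging) is
used because EFL is a flow-at-volume comparison. Limbs must be monotone in
volume; reversals up to 0.02 L (noise scale) are projected onto the
monotone hull and larger reversals exclude the breath with a warning. All
interpolation is linear — no splines — so constructed analytic cases are
exact up to grid resolution.

## Operating lung volumes and placement

Inspiratory capacity (IC, `measure_ic()`) is the excursion from the
baseline end-expiratory volume (mean over the preceding breaths' end
expiratory points, after drift correction across the combined tidal + IC
window) to the extreme volume of the IC maneuver. On this package's
polarity the extreme is a maximum; a `nadir` flag serves traces recorded
the other way. A maneuver excursion smaller than the preceding tidal
breath is flagged as a suspect (submaximal) effort but still returned.

`derive_volumes()` computes ERV = FVC − IC, placing the loop on the
absolute axis (EELV above RV = ERV), and also returns ERV + VT. That
second quantity is reported as `IRV_paper` because the source convention
for this analysis defines "IRV" as ERV + VT — which is end-inspiratory
lung volume above RV, not the conventional IRV = IC − VT. Both are
returned (`EILV_above_RV`, `IRV_conventional`) so downstream code never
has to guess.

## EFL detection and ventilatory capacity

`place_tidal_curve()` shifts the composite expiratory limb by ERV and
samples the envelope at the same volumes; `assess_efl()` marks a grid
point flow-limited when tidal flow meets or exceeds the envelope within
`flow_tol`, sums the volume-bin widths of limited points (half-width bins
at the ends so widths total VT), and calls EFL present when the overlap
reaches `threshold_pct` (default 5%) of VT. The strict meets-or-exceeds
default (`flow_tol = 0`) is the right semantics for exact constructed
curves; for measured data the pipeline default is `flow_tol = 0.05` L/s,
the scale of flow noise and of the flow offset induced by a ~0.02 L
placement error through the envelope's slope. Without that slack a
placement biased a few hundredths of a litre high can make the entire
genuinely-limited region fail a strict comparison. End-inspiratory volumes
that overshoot FVC by up to 0.05 L (measurement noise) are clipped with a
warning; larger overshoots are treated as calibration errors.

Ventilatory capacity (`ve_cap()`) asks how much ventilation the envelope
would permit at the current tidal volume and placement: the minimal
expiratory time is the volume integral of 1/V̇max across [ERV, ERV + VT]
(envelope flows floored at 0.05 L/s so the integral cannot diverge), and
V̇E,CAP = 60·VT/(TI + TE,min) with the stage's measured inspiratory time.
The cited convention for this quantity is not fully specified in the
source literature, so the TE,min integral with measured TI is this
package's reading; a `vecap_ti_mode = "fixed_fraction"` option solves TI
from a fixed duty cycle instead. Two structural consequences follow and
are tested: doubling the envelope strictly raises capacity, and VE ≤
V̇E,CAP whenever the tidal limb lies within the envelope.

## Repeatability statistics

Binary EFL agreement between visits uses Cohen's κ on the 2×2
participant-level table, with the McHugh bands (none ≤ 0.20, minimal
0.21–0.39, weak 0.40–0.59, moderate 0.60–0.79, strong 0.80–0.90, almost
perfect above). Continuous agreement uses the single-measure ICC from the
two-way ANOVA mean squares, with the Koo–Li bands (poor < 0.50, moderate
0.50–0.75, good 0.75–0.90, excellent > 0.90); shared band endpoints go to
the lower-named band. Because a repeatability design treats visit as a
random factor, the default form is ICC(2,1) (two-way random, absolute
agreement); ICC(3,1) (consistency) is selectable, and both match the
standard implementations (they were cross-checked against pingouin's
ICC(A,1)/ICC(C,1) to 6 decimals during development, and the test suite
keeps an independent aov-mean-squares oracle). κ's p-value is the
large-sample normal test of κ = 0 with the Fleiss null standard error.
The between-day coefficient of variation uses the within-subject SD
|x₁−x₂|/√2 per pair and reports the root-mean-square of those SDs as a
percentage of the grand mean — one of several conventions in use, stated
here explicitly since the quantity is not otherwise identifiable. Paired
comparisons and visit-wise frequency comparisons delegate to
`stats::t.test(paired = TRUE)` and `stats::fisher.test()`.

For matched-ventilation comparisons, `match_ve_stages()` searches the
stages above 75% of each visit's peak V̇O₂ and returns the pair minimizing
|ΔV̇E|, breaking ties toward higher work rate. Peak-exercise comparisons
use the last completed stage of each visit.

## The synthetic study generator

`gen_two_visit_study()` builds complete labelled studies so every pipeline
estimate can be checked against ground truth. Per participant, a true
physiology is drawn from priors that are ordinary for healthy adults: FVC
4.88 ± 0.99 L, PEF 9.5 ± 1.3 L/s, envelope curvature (true SR) 1.25 ±
0.2, peak work 211 ± 51 W reached in 20 W / 2 min steps from a 20 W
start, peak VT ≈ 49% of FVC, EELV falling from ≈43% of FVC at rest to
≈36% at peak, peak ventilation 105 ± 20 L/min (drawn directly, with
breathing frequency following, so demand sits near ~70% of capacity),
volume drift uniform in ±0.004 L/s, and Gaussian flow noise of 0.02 L/s.
The EFL propensity is a latent normal (mean −10, SD 48, truncated to
[0, 60]), giving ≈38% of participants a positive peak overlap target with
conditional magnitude ≈35 ± 18% — the regime in which the binary
classification is intrinsically unstable.

The true envelope is the power law V̇max(v) = PEF·(v/FVC)^SR, so the slope
ratio of the generated envelope is the curvature parameter itself. Four
graded efforts (25/50/75/100%) each attain the envelope exactly over
their own volume band (bands jointly covering 0..FVC; submaximal efforts
are effort-attenuated near TLC, the maximal effort carries a mild
gas-compression deficit at low volumes), so their pointwise maximum
reproduces the true envelope to within 1% wherever flows are appreciable;
a 0.02 L/s terminal flow floor lets every effort empty to RV in finite
time. Tidal breaths use a half-sine inspiration and an early-peaking
expiratory shape (fast rise, decaying plateau, linear terminal fall —
finite end slopes keep expiratory time close to its volume-mean
prediction). EFL is induced mechanistically: the desired expiratory flow
is clipped at the envelope, with the desired amplitude calibrated by
bisection so the clipped fraction of VT equals the stage's target exactly;
EFL-free stages instead cap desired flow at 92% of the envelope and
calibrate amplitude to the target expiratory time, so absence of EFL is
robust to estimation error. Stage EFL targets ramp in over the top ~45% of
the incremental protocol, so high-propensity participants also show
submaximal EFL. Each stage ends with an IC maneuver to total lung
capacity; drift is added linearly across the whole session on the volume
channel and noise on the flow channel.

Visit 2 re-runs the same protocol with each parameter multiplied by
(1 + CV·z), one standard normal draw per parameter per participant; the
default CVs (FVC 1.5%, PEF 3%, curvature 5%, VT 3%, fB 5%, EELV 4–6%,
EFL propensity 18%) are of the few-percent order seen in day-to-day
physiology. Determinism contract: all randomness derives from the study
seed through a fixed hierarchy (study → participant → visit → stage), and
each visit's measurement-noise stream is keyed on the visit's *realized
parameter vector*. The practical consequence — adopted deliberately — is
that a study generated with all CVs at zero produces byte-identical
visit-1 and visit-2 recordings, so the degenerate-repeatability limit
(κ = 1, ICC = 1, CV = 0%) is exact rather than approximate.

What the generator does not emulate: cardiogenic flow oscillations,
breath-to-breath shape variability beyond amplitude noise, genuinely
aberrant breaths (sighs, swallows) other than through the min-VT filter,
pre/post differences in bronchial tone (pre and post efforts share one
true envelope), gas-exchange measurement (stage V̇O₂/V̇CO₂ are schedule
values, not simulated signals), and any biophysical airway mechanics —
EFL is imposed by construction, not emergent. Passing tests therefore
show the pipeline recovers what it is defined to measure under controlled
violations of its assumptions (drift, noise, borderline overlap), not that
it is robust to every artefact of real recordings.

## Numerical choices and degenerate inputs

* Grids: MEFV on exact 0.01 L volume steps; composite loops on 101
  relative-volume bins; linear interpolation throughout.
* Finite differences: central within the SR averaging region, one-sided at
  the array ends; chord slopes under 0.01 L/s/L are skipped to avoid
  dividing by a vanishing chord; fewer than 10 usable points is an error.
* The V̇E,CAP integrand floors envelope flows at 0.05 L/s; an envelope that
  is zero across more than 20% of the tidal range is rejected as an
  inconsistent placement.
* Ties and boundaries: classification-band endpoints go to the lower band;
  stage pairing ties break toward higher work; κ with a constant rater and
  ICC with zero total variance return flagged undefined results instead of
  throwing.
* Windows are taken verbatim from the manifest (the analysis uses the last
  30 s of each stage); there is no automatic re-windowing, and sampling
  rates other than the declared one are an error, not a resample.

## Problem sizes

The test suite and the acceptance script exercise the full pipeline at the
study scale the method targets — 32 participants × 2 visits × (rest + up
to ~16 work stages) at 200 Hz — which runs in about a minute; property
checks that need replication (parameter recovery, borderline-κ
instability, envelope oracles) use 3–25 participants or 20–100 random
cases per property, sizes at which every assertion is comfortably
repeatable under fixed seeds.

## Worked example

```{r example, eval = FALSE}
study <- gen_two_visit_study(n_participants = 8, seed = 42)
result <- run_pipeline(study)

result$peak_report          # kappa, ICC, CV per parameter at peak
tidy(result$matched_report) # one row per parameter, broom-style
autoplot(result$analyses[[1]]$placed[["W180"]])  # loop-in-envelope overlay
```
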