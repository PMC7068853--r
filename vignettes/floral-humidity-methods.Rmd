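---
title: "Models and methods for floral humidity transect surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for floral humidity transect surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(floralhum)
```

# The measurement problem

A floral humidity survey measures how much a flower raises the relative
humidity of the air in its headspace, and how that elevation is arranged in
space. The design this package supports uses two DHT-22-class humidity
probes: a stationary *background* probe far from any flower, and a *focal*
probe stepped by a robot arm along two transects per flower — horizontal
(x: −30 mm to +30 mm in 5 mm steps, 13 points) and vertical (z: 5 mm to
30 mm, 6 points) relative to a *transect central point* 5 mm above the
flower's center. At each stop the probe settles for 30 s and then samples
for a 200-s measurement period (~100 readings), while the background probe
records simultaneously. After each flower, the focal probe parks beside the
background probe for a *probe-control* measurement. The whole sequence is
repeated as four replicate transects per day.

Three facts drive the statistical design:

1. **Sensors disagree.** Nominally identical probes differ by several
   percent RH. The probe-control periods let us regress one probe on the
   other and correct the focal scale (`fit_probe_calibration`,
   `apply_calibration`).
2. **Rooms drift.** Background humidity wanders on minute-to-hour
   timescales, so the flower's contribution is only identifiable as the
   difference between *simultaneous* focal and background readings
   (`compute_delta_rh`).
3. **Flowers differ individually.** Humidity intensity varies between
   conspecific flowers, so species-level structure is modelled with a
   per-flower random intercept.

# Calibration

For each day × replicate, all probe-control readings are pooled, paired by
nearest timestamp (tolerance: half the median sampling interval; unpaired
readings dropped), and fitted by ordinary least squares. The slope and
intercept (W, M) define the affine correction `W · focal + M`.

*Regression direction.* The correction should map focal readings onto the
background probe's scale, so the default fits **background ~ focal** and
uses the prediction as the corrected value. This choice makes the
self-consistency identity hold exactly: the mean ΔRH of the probe-control
periods, corrected by their own calibration, is zero by the algebra of OLS
residuals (a property the test suite asserts). The reverse direction is
available (`direction = "focal_on_background"`) for comparison with
pipelines that regressed the other way; for tightly correlated probes the
two differ negligibly.

Because the regressor (focal reading) carries sensor noise, the fitted
slope is attenuated by the classic errors-in-variables factor
`var(signal) / (var(signal) + var(noise))`. The calibration is therefore
only as good as the humidity range the probe-control periods span: a pair
of probes watching a perfectly constant room cannot be cross-calibrated.
This is not an implementation artifact but a property of the estimator,
and it shapes the synthetic generator's defaults (below).

# Measurement quality

**Repeatability.** The intraclass correlation of individual ΔRH readings,
grouped by measurement period, is computed from a one-way ANOVA variance
decomposition: `R = between / (between + within)`, with a negative
between-period component truncated at zero. The standard error and 95%
interval come from a parametric bootstrap (default 100 refits, matching
the survey's reporting; the interval is widened if necessary to contain
the point estimate). The estimator is exactly scale- and shift-invariant.

**Turbulence.** Probe motion stirs the headspace; if 30 s of settling were
not enough, the start of a measurement period should differ from its end.
`turbulence_change` compares the mean focal humidity in the first and last
20 s of each period. The non-directional change is reported as the
absolute difference by default; the squared difference is one flag away
(`convention = "squared"`). The absolute form was chosen as the default
because the survey-scale regression intercept (~0.1 %RH) reads naturally
as a magnitude in humidity units. `turbulence_regression` fits
`f_change ~ f_mean` by OLS and reports the conventional coefficient table.
Whether readings enter corrected or uncorrected is the caller's choice;
the default pipeline uses raw focal readings, since calibration is affine
and window means subtract.

# The humidity-structure model family

The x-axis full model is a quadratic in offset X with per-replicate
modifiers and a per-flower random intercept:

ΔRH&#95;xnt = I + i&#95;t + (A + a&#95;t)·X + (B + b&#95;t)·X² + ν&#95;n + ε

where i, a, b are indicator-coded shifts for replicates 2–4 (replicate 1 is
the baseline; the per-replicate modifiers are exactly zero there). The
eleven x-axis members (m0–m10) zero out subsets of {A, B, r, g, c}; the
five z-axis members (z0–z4) replace the polynomial by `B · ln Z` (Z ≥ 5 mm,
so no offset constant is needed). Interaction modifiers are never included
without their main term. The replicate effects are indicator-coded rather
than linear-in-t trends: replicate shifts need not be monotone (flowers
sometimes ramp up after the first transect), and the indicator form nests
cleanly across the family.

**Fitting.** Models are fitted by maximum likelihood (lme4, `REML = FALSE`)
with a single Gaussian random intercept per flower. REML likelihoods are
not comparable across different fixed-effect structures, and the whole
point of the family is AIC comparison, so ML is used throughout. A
zero-variance random intercept is a legitimate boundary estimate, reported
and flagged, not an error; single-flower data fall back to a fixed-effects
fit with a warning. The AIC parameter count is
`k = (free fixed effects) + 2` (flower-intercept variance and residual
variance); fixed-effects fallbacks count one variance. The test suite pins
the fitted log-likelihood against a dense multivariate-normal evaluation
of the marginal likelihood (tolerance 1e−6) and the zero-variance case
against closed-form least squares (1e−8).

**Selection.** All members of an axis are fitted; failures (e.g. replicate
terms demanded of single-replicate data) are recorded in the AIC table
with their message, never dropped silently. The *comparable best set* is
all models within ΔAIC ≤ 2 of the minimum (the standard
information-theoretic comparability band; configurable), and the *chosen*
model is the single lowest-AIC member, with exact ties broken toward fewer
parameters. Note that AIC is not a consistent selector: under a true null
model, each extra parameter retains a fixed probability of "paying its
penalty" by chance, so even for pure noise the flat model is chosen only
a bit over half the time on the x axis (the test suite measures these
rates by simulation). This is a property of AIC itself, shared by any
faithful implementation of the selection rule.

One enumeration quirk is worth recording: the printed definition of the
fourth-replicate indicator in the source material sets it for t = 5, an
evident typo for t = 4 (there are four replicates); the package implements
t = 4.

# Peak summaries

For the chosen x-axis model, the per-replicate peak offset is: 0 for flat
structures (any offset predicts the same value), ±30 mm for linear ones
(by the sign of the effective slope), and the vertex `−(A+a) / 2(B+b)` for
concave quadratics. The vertex is clamped to the sampled [−30, 30] mm
range: an out-of-range vertex is extrapolation beyond the transect, so the
boundary value is reported with a flag (large flowers can genuinely peak
at the transect edge). A convex quadratic — not observed in the survey but
possible in principle — peaks at whichever endpoint predicts more, also
flagged. The peak elevation ΔRH^max evaluates the fitted mean structure at
each replicate's peak with the flower random intercept set to zero and
takes the maximum over replicates; ties resolve to the earliest replicate,
which is closest to the fresh-cut state. A 0.01-mm grid search is the
oracle for all of these rules in the tests and the acceptance script.

Species are classified against the control baselines carried in the
summary table: the lidded water tube (TWL; humidity attributable to the
flower's own water supply), the open water tube (TW; the strongest
humidity any control produced), and a fixed 3 %RH intensity threshold.

# Phylogenetically controlled comparison

Across species, log ΔRH^max (natural log; back-transformed effect sizes
exponentiate) is regressed on flower span (mm), floral type
(flower/inflorescence dummy) and growth condition (outdoor dummy) by
generalized least squares whose residual correlation follows the
phylogeny. The GLS core is closed-form (Cholesky whitening, ML residual
variance); standard errors follow the residual-df convention of nlme,
against which the implementation is cross-checked in the tests.

Two correlation models are supported. Brownian motion: correlation =
shared root-to-ancestor height / tree height. Ornstein–Uhlenbeck: the
default is the fixed-root (Hansen) form on the height-normalized tree,
whose α → 0 limit is exactly the BM matrix — a continuity property the
tests assert — while the stationary form `exp(−α·d)` is available as
`ou_form = "stationary"`. The two parameterizations give numerically
different α for the same data, so fitted rates are only comparable within
one convention. When α is estimated, it is profiled over a log-spaced grid
(1e−4 to 1e3, 61 points) with local refinement by golden-section
optimization; the profile is invariant to shifting the response. The AIC
counts the coefficients, the residual variance, and α when estimated.

# The synthetic generator

`simulate_probe_log` emulates the measurement process end to end: a
sequential timeline of 230-s stops; background humidity as a mean level
(49.1 %RH, the survey's room) plus a sinusoidal daily drift plus a
spatially common slow wander; per-reading sensor noise; per-flower random
intercepts per axis; a per-period microclimate deviation; and a focal
probe whose recorded scale is distorted by a true (W, M), so the pipeline
must genuinely undo it. Timestamps are jittered (±0.2 s around a 2-s
cadence) so nearest-timestamp pairing is exercised rather than bypassed.

Noise defaults, chosen once for realism and internal consistency:

* **Sensor noise 0.2 %RH** per reading — the scale of the sensor's
  resolution and short-term scatter.
* **Daily drift amplitude 3 %RH** — ordinary indoor swings; a much flatter
  room would make Eq.-1-style calibration unidentifiable (see the
  errors-in-variables note above), which contradicts the measured
  behaviour of real probe pairs.
* **Common wander sd 4 %RH, 30-min correlation time** — slow room
  fluctuations seen identically by both probes. This cancels in the
  simultaneous subtraction (so it does not inflate ΔRH noise) but spreads
  the probe-control readings over a realistic humidity range, keeping the
  calibration's attenuation bias second-order.
* **Per-period microclimate sd 0.15 %RH** — period-mean scatter beyond
  sensor noise, matching the visible dispersion of period means around
  fitted transect curves in real surveys.
* **Miscalibration W = 0.96, M = 2** — within the sensors' stated
  inter-unit tolerance.

What the generator does *not* emulate: vapor physics (no boundary layers,
no dependence of emission on the flower's water status), heteroscedastic
positive-skewed scatter near flower centers, sensor quantization and
autocorrelation, or between-day weather. Passing recovery tests therefore
show that the estimation pipeline inverts the survey's statistical model,
not that the statistical model captures everything about real flowers.

`simulate_delta_rh` is the period-level shortcut (residual sd 0.15 %RH by
default, consistent with the reading-level defaults averaged over ~100
readings) used where thousands of fits are needed.
`simulate_phylo_traits` draws birth–death trees (ape::rphylo), log-normal
spans (median 35 mm, on the survey's scale), Bernoulli(0.5) dummies, and
multivariate-normal responses under BM, OU, or identity correlation.

# Problem sizes and numerical choices

The simulation studies in the tests and acceptance script use the survey's
own design: 6 flowers × 4 replicates × 13 x-offsets (312 period means per
species fit). Model-recovery rates use 100 seeded datasets per truth;
end-to-end reading-level recovery uses 20 seeded full runs (~110,000
readings each); comparative recovery uses 300–500 seeded 40-tip trees;
the vertex oracle uses 1000 random parameter draws against a 0.01-mm grid.
Optimizer slack of 1e−4 on log-likelihood nesting comparisons absorbs
lme4's convergence tolerance; likelihood-oracle agreement is asserted at
1e−6 and closed-form identities at 1e−8 or tighter. Degenerate inputs are
failed loudly and early: off-grid offsets, periods with fewer than two
retained readings, zero-variance calibration inputs, collinear GLS
designs, and species absent from the phylogeny all name the offending
record.

# Known limitations

* The calibration is OLS-based and inherits errors-in-variables
  attenuation; with quiet sensors or a humidity-varying room this is
  negligible, but a perfectly still room bounds what any pipeline could
  recover.
* AIC model selection retains its intrinsic overfitting probability under
  null structure; consumers who need a conservative structural claim
  should read the comparable best set, not only the chosen model.
* The OU rate is only interpretable within the package's height-normalized
  fixed-root convention.
* Repeatability is the plain Gaussian ICC; no link-scale or
  multi-factor variants are provided.
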