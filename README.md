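# floralhum

Flowers humidify the air immediately around them: nectar evaporates and
petals transpire, so the headspace a few millimetres above a floral display
is measurably more humid than the room it sits in. That elevation — a few
tenths to a few percentage points of relative humidity — is a candidate
close-range cue for insect pollinators, and may matter for pollen
viability, floral thermoregulation and fungal infection.

`floralhum` implements the full analysis pipeline for paired-probe humidity
transect surveys of cut flowers, in which a focal probe is stepped by a
robot arm across (x axis, −30 mm to +30 mm in 5 mm steps) and above
(z axis, 5 mm to 30 mm) each flower's headspace while a second, stationary
probe records background humidity. The package takes raw probe logs to
per-species humidity-structure models and comparative analyses:

* **Cross-calibration.** Paired sensors disagree by a few percent. During
  probe-control periods both probes sample the same air, and an ordinary
  least-squares fit per day × replicate gives the affine correction
  `f_corrected = W · f_uncorrected + M` that puts the focal probe on the
  background probe's scale.
* **Humidity differences.** `ΔRH = f_corrected − f_background` over
  nearest-timestamp pairs, averaged within each 200-s measurement period.
* **Measurement QC.** Within-period repeatability (intraclass correlation
  with a parametric bootstrap) and a regression of the non-directional
  start-vs-end change in focal humidity on the period mean, which screens
  for residual turbulence from probe movement.
* **Humidity-structure models.** Eleven x-axis models (flat, linear,
  quadratic; with or without per-replicate intercept and shape changes) and
  five z-axis models (flat or logarithmic in height), fitted by maximum
  likelihood as linear mixed models with a per-flower random intercept, and
  compared by AIC:

  `ΔRH_xnt = I_x + i_xt + (A_x + a_xt) X + (B_x + b_xt) X² + ν_xn + ε`

  with indicator-coded replicate modifiers that are zero on the first
  transect.
* **Summary statistics.** The peak offset `X^max` (0 for flat structures,
  ±30 mm for linear ones, the vertex `−(A+a)/2(B+b)` for concave
  quadratics, clamped to the sampled range) and the peak elevation
  `ΔRH^max`, maximized over replicate transects with the flower random
  intercept set to zero; classification of species against water-tube
  control baselines.
* **Comparative analysis.** Phylogenetically controlled generalized least
  squares of log ΔRH^max on flower span, floral type and growth condition,
  under Brownian-motion or Ornstein–Uhlenbeck residual correlation with
  profile-ML estimation of the OU rate, plus likelihood-ratio and AIC model
  comparison.
* **Synthetic data.** A generator that emulates the whole measurement
  process — drifting room humidity, probe miscalibration, sensor noise,
  per-flower variation, jittered sampling timestamps — with known ground
  truth, so every stage is testable without any external data.

The published 42-species survey summary (best models, peak offsets, peak
elevations, controls) ships as a fixture: `load_survey_summary()`.

## Worked example

Simulate one survey day for a species whose true x-axis structure is an
offset quadratic with replicate intercept shifts (model m7, true peak
1.275 %RH at X = 5 mm), with a miscalibrated focal probe (W = 0.95,
M = 2), then run the pipeline:

```r
library(floralhum)
truth <- transect_truth(W = 0.95, M = 2)
log   <- simulate_probe_log(truth, n_flowers = 6, seed = 42)

calib <- fit_probe_calibration(log)
calib
#> Probe cross-calibration (corrected = W * focal + M), direction: background_on_focal
#>   day replicate      W     M n_points r_squared
#>  day1         1 0.9440 2.317      600    0.9946
#>  day1         2 0.9413 2.437      602    0.9838
#>  day1         3 0.9320 2.838      601    0.9692
#>  day1         4 0.9477 2.116      604    0.9877

drh <- compute_delta_rh(log, calib)
sel <- select_transect_model(drh, "x")
sel
#> Model selection (x axis, synthetic): chosen m7
#>   comparable best set (delta AIC <= 2): m7
#>  model  k  logLik     aic delta_aic failed
#>     m7  8  115.43 -214.85      0.00  FALSE
#>    m10 14  116.48 -204.96      9.89  FALSE
#>     m3  5  -14.92   39.85    254.70  FALSE
#>  ...

delta_rh_max(chosen_fit(sel))
#> Peak humidity elevation 1.324 %RH at X = 4.97 mm (model m7, replicate 1)
```

The fitted calibrations recover the injected (W, M) up to the attenuation
expected from sensor noise, the true model family member is selected, and
the estimated peak (1.324 %RH at 4.97 mm) sits within a few percent of the
analytic truth (1.275 %RH at 5 mm).

Classifying the packaged survey summary against its control baselines:

```r
threshold_counts(load_survey_summary())
#> Classification of 42 species by peak humidity elevation:
#>   above TWL control (0.46 %RH): 30
#>   above TW control (1.17 %RH): 13
#>   above 3 %RH: 6
#>   peak at transect central point: 22
#>   peak >= 5 mm off-center: 5
#>   non-quadratic best x model: 3
```

Thirty of the 42 species exceed the humidity attributable to their
water-filled tube (TWL control), thirteen exceed the strongest control
signal of all (the open water tube, TW), and six exceed 3 %RH outright;
most species peak exactly over the flower's center.

`run_pipeline(config)` wires the stages together (calibrate → ΔRH → QC →
fit/select → summarize → optional comparative stage) and writes a
deterministic, seed-stamped CSV/JSON output bundle.

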