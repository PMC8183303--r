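# pufov

Tools for measuring the **peripheral useful field of view (pUFOV)** — how far
into the visual periphery a *change* to a stimulus (color, shape, or motion)
can still be detected under free viewing — from wide field-of-view
eye-tracking experiments on a three-screen driving-simulator projection.

The classic UFOV is measured with isolated stimuli, a fixation point and a
single monitor, and is reported as a hard cutoff. In a simulator none of
that holds: the projection spans well over 100° of visual angle, 150 stimuli
are on screen at once, the observer looks around freely, and the tracker's
gaze estimate is several degrees noisy. `pufov` implements the full analysis
chain for that setting:

* **Geometry** — a 3-D model of three angled canvases mapping
  (screen, pixel) ↔ viewing direction ↔ visual angle.
* **Stimuli** — a randomized 25 × 6 feature grid (square/triangle,
  red/green, 0°/45°, 200 px spacing, occlusion mask) and constrained
  schedules of 140 color/shape/motion change events per 5-minute video
  (1–2 s visible, ≤ 1 s same-type pauses, no same-type overlap).
* **Synthetic participants** — gaze streams, keypresses, and 21-point
  calibration runs simulated from known eccentricity-dependent detection
  profiles, with per-screen anisotropic tracker noise, so the whole chain is
  testable by parameter recovery.
* **Alignment** — assignment of noisy gaze samples to stimulus features via
  a Markov random walk over feature states with transition weights
  `exp(-d_i/sigma_T) - exp(-d_j/sigma_T)`, plus saccade segmentation with
  direction-based merging.
* **Metrics** — detection rates, gaze and keypress reaction times, saccade
  amplitudes (px and degrees), calibration error.
* **The pUFOV model** — per-change-type detection probability over
  eccentricity fitted as a Gaussian `p(e) = A exp(-e²/2σ²)` by weighted
  least squares, and one-way ANOVA comparisons between change types.

The central claim the package operationalizes: perception of change in the
periphery is not a hard boundary but a smooth, type-specific probability
profile — narrow for color, intermediate for shape, wide for motion.

## Worked example

A desk-scale simulated study — 10 participants, three 5-minute videos each,
one instructed change type per video:

```r
library(pufov)
cfg <- study_config(n_participants = 10, seed = 2026)
res <- run_study(cfg)
res$report$cohort
#>  change_type n_events n_detected      rate mean_gaze_rt_s mean_key_rt_s
#>        color     1400        231 0.1650000      0.3945592     0.7309467
#>        shape     1400        428 0.3057143      0.4385649     0.7319340
#>       motion     1400       1001 0.7150000      0.4966052     0.7404514
res$fits$motion
#> Gaussian perception profile: A = 0.945, sigma = 45.96 deg (rss 2.3450, 14 bins)
```

Reading the output: of 1400 scheduled color changes the simulated cohort
acknowledged 16.5 %, shape 30.6 %, motion 71.5 % — the characteristic
ordering of peripheral sensitivity. Mean keypress reaction times sit near
0.73 s for every type (the latency model is type-independent; only
*whether* a change is seen depends on type and eccentricity). The fitted
motion profile says: a motion change right at fixation is detected with
probability 0.945, and detectability falls to half that amplitude at
`sqrt(2 ln 2) * 46 ≈ 54°` of eccentricity. The generator's true motion
parameters were A = 0.95, σ = 50°; the fit recovers them from the noisy
pipeline within 0.5 % and 8 %.

The same workflow, staged with intermediate tables written to `results/`:

```sh
Rscript analysis/01_stimuli.R             # layout + grids + schedules
Rscript analysis/02_run_study.R           # simulate, align, score, fit
Rscript analysis/03_parameter_recovery.R  # pipeline vs. ground truth
Rscript analysis/04_figures.R             # profile curves, rates, RTs
```

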