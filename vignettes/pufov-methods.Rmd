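---
title: "Measuring the peripheral useful field of view: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the peripheral useful field of view: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pufov)
```

## The problem

The classic useful field of view (UFOV) is the area within which a stimulus
can be *identified* without eye or head movement, usually measured with
brief, isolated stimuli on a single monitor and reported as a hard cutoff.
Driving is different: a wide projection surrounds the observer, many stimuli
change at once, and what matters is whether a change is *detected* at all,
not identified. `pufov` implements the analysis chain for that setting — the
peripheral useful field of view — on a three-screen driving-simulator
geometry: stimulus generation, gaze-to-feature alignment, event scoring, and
a probabilistic representation of detectability as a Gaussian over
eccentricity,

$$ p(e) = A \, \exp\!\left(-\frac{e^2}{2\sigma^2}\right), $$

where $e$ is the angular distance between the current gaze direction and the
changing stimulus, $A$ the detection probability at fixation, and $\sigma$
(degrees) the width of the usable field for that kind of change. Because no
human data ship with the package, a synthetic-participant generator with
known $(A^*, \sigma^*)$ per change type closes the loop: every downstream
stage can be validated by parameter recovery.

## Simulator geometry

Three 3.05 m × 1.89 m canvases (1920 × 1200 px each) meet at 151°, the
center screen 3.75 m in front of the eye point and perpendicular to the
straight-ahead direction. `screen_layout()` models the three planes in 3-D;
pixels are 0-based pixel centers, x right, y down, and pixel-space distances
live on a single unrolled 5760 × 1200 canvas (global
$x = 1920\,\text{screen} + x$). All user-facing angles are degrees.

Two geometric caveats are computed rather than assumed:

* From the printed dimensions the horizontal × vertical coverage is
  123.1° × 28.3°. Published descriptions of comparable rigs quote larger
  figures (147°–149° × 39°), which cannot be reconciled with these screen
  sizes and distances; the layout therefore always reports geometry-derived
  coverage, keeps any quoted figure as documentation
  (`reported_coverage_deg`), and `layout_for_coverage()` solves the eye
  distance that realizes a quoted coverage (149° → 2.64 m).
* Under a 149°-coverage layout the outermost canvas point at eye height sits
  at 74.5° — half the coverage, the *maximum measurable* pUFOV eccentricity
  (`max_measurable_eccentricity()`). The outermost *grid* feature is inset
  480 px from the canvas edge and sits at ≈ 66.5°; both numbers are
  available, and the package uses the canvas bound when talking about what
  the rig can measure.

## Stimuli

`generate_grid()` draws 150 objects (40 × 40 px) on a 25 × 6 matrix with
200 px spacing spanning the unrolled canvas, each uniformly and
independently square/triangle, red/green, rotated 0°/45° — independent
uniform draws prevent grouping by position, shape, or color. An occlusion
mask (default: the lower center-screen rows, approximating a vehicle
chassis) marks features as invisible; change events are only placed on
visible features.

`schedule_events()` draws, per change type, 140 events per 5-minute video
with durations uniform in [1, 2] s and same-type gaps uniform in (0, 1] s.
Same-type events never overlap; different types may overlap in time but
never on the same feature (a feature cannot legibly change color and shape
at once). The sampler places events sequentially and rejects-and-resamples
a schedule that overruns the video — expected occupancy is
$140 \times 1.5 + 139 \times 0.5 = 279.5$ s of 300 s, so rejection is rare.
`validate_schedule()` re-checks every constraint and is run before any
schedule is used.

`state_at()` exposes the instantaneous stimulus state: color changes move
only the *a* channel of LAB (endpoints a = ±60 at L = 60, b = 45, keeping
luminosity constant; the paper-style single-channel manipulation with
declared default coordinates), shape changes interpolate a morph parameter
0 → 1, and motion wiggles the orientation as
$45° \sin(2\pi f t)$ with $f$ = 2 Hz by default — a declared default chosen
so that full oscillations complete within the minimum 1 s event duration.

## Synthetic participants

`participant_profile()` bundles the generator's assumptions:

| parameter | default | meaning |
|---|---|---|
| perception $(A, \sigma_e)$ | color (0.90, 12°), shape (0.95, 18°), motion (0.95, 50°) | Gaussian detectability per change type |
| gaze latency | 0.20 s + lognormal(log 0.22, 0.35) | event onset → saccade arrival |
| key latency | 0.15 s + lognormal(log 0.14, 0.35) | arrival → keypress |
| tracker noise | pooled mean abs. error 3.9°/3.4° (h/v), split 1.3/0.7/1.0 × for screens left/center/right | per-sample anisotropic noise |
| fixational jitter | 0.3° | oculomotor noise at rest |
| dwell | 0.4 s | time on target before returning |
| sampling rate | 60 Hz | gaze log rate |

The per-type $(A^*, \sigma^*)$ defaults mirror the qualitative ordering of
peripheral sensitivity established for these kinds of change — color
narrowest, motion widest — at magnitudes that yield recognition rates
between roughly 0.15 and 0.75 under this geometry. Latency defaults put the
mean keypress reaction near 0.75 s. The noise defaults invert the half-normal
mean ($E|X| = \sigma\sqrt{2/\pi}$) from the pooled mean absolute error and
apply the per-screen split matching a camera rig seated right of center
(best accuracy centrally, worst on the left screen). Angular noise becomes
pixel noise through the local pixel-per-degree scale of each screen, which
on the oblique side screens (≈ 47 px/°) yields per-sample noise of 240–300 px
— larger than the 200 px feature spacing, a point that matters below.

The behavioral model: gaze rests at the center-screen center. At each onset
of an instructed-type event, detection is a Bernoulli draw with
$p = A\exp(-e^2/2\sigma_e^2)$ at the *current* gaze position (the observer
may still be handling a previous event — there is no fixation cross, by
design). On detection, gaze jumps to the feature after the gaze latency
(instantaneously between samples; flight time is absorbed by the latency),
dwells, a keypress follows after the key latency, and gaze returns to
center. Non-instructed events never trigger responses; false alarms are not
modelled. Every simulated event's truth — detected, onset eccentricity,
arrival and keypress times — is recorded for recovery checks.

`simulate_calibration()` emits noisy gaze around 21 reference points (7 per
screen), from which `calibration_error()` reproduces the half-normal law
exactly in expectation — the package's self-check that noise generation and
error measurement are mutually consistent.

What the generator deliberately does *not* emulate: oculomotor dynamics
(main-sequence velocities, smooth pursuit), pupil/eyelid artefacts,
systematic (non-zero-mean) calibration residuals, inter-participant
variability in the perception profiles, and the driving task itself. Passing
recovery tests therefore demonstrate that the analysis chain is unbiased
under these idealizations, not that it is robust to every artefact of real
recordings.

## Aligning gaze to features

Tracker noise of several degrees makes naive nearest-feature assignment
jitter. The alignment treats every visible feature as a state of a Markov
chain; given gaze point $g_t$, the transition weight from feature $i$ to $j$
is

$$ T_{ij} = \big(1 - e^{-|g_t - f_j|/\sigma_T}\big) -
            \big(1 - e^{-|g_t - f_i|/\sigma_T}\big)
          = e^{-d_i} - e^{-d_j}, $$

with pixel distances on the unrolled canvas scaled by $\sigma_T$ (default
150 px — the horizontal tracker error expressed in pixels). Each sample
performs one random-walk update $v_t = T v_{t-1}$ and the aligned feature
$g'_t$ is the argmax of $v_t$ (ties to the lowest feature id; the initial
state is uniform; invalid samples hold the previous state).

Two ambiguities in that construction are resolved explicitly:

* **Orientation.** Whether rows or columns of $T$ index the destination is
  a genuine sign ambiguity. Under the row convention,
  $(v_t)_i = \sum_j T_{ij}(v_{t-1})_j = e^{-d_i} - C$ with $C$ independent
  of $i$ — the ordering follows proximity, as intended. The column
  convention inverts the ordering (the *farthest* feature wins), so the row
  convention is adopted.
* **Negative entries.** The weights can be negative and the update does not
  preserve a distribution; negatives are clipped to zero and the vector
  renormalized, which preserves the proximity ordering and keeps $v$ a
  distribution.

A corollary falls out of the algebra: after clipping and renormalization the
argmax is *always* the nearest visible feature — this "literal" mode has no
memory and degenerates to per-sample nearest-feature snapping (the test
suite asserts exactly this against a brute-force oracle). Because noisy data
benefit from hysteresis, the default "proximity" mode makes the memory
explicit: $v_t = \lambda v_{t-1} + (1-\lambda) w$ with
$w_i \propto e^{-d_i}$ and stickiness $\lambda = 0.5$. The recursive update
is an AR(1) filter per feature and is computed as such.

`extract_saccades()` turns every change of $g'$ into a saccade and merges
strings of saccades in similar directions (< 45°) separated by dwells
shorter than 0.1 s into one end-to-end saccade — both thresholds are
declared defaults, as no quantitative convention exists for "similar
direction". Amplitudes are reported in pixels (unrolled canvas) and degrees
(3-D angular distance).

## Scoring events

`match_events()` operationalizes a *correctly acknowledged* change — the
notion is not standard, so the rule is declared and configurable: an event
is detected iff the aligned track visits its feature within
[onset, offset + 1 s grace] and a keypress confirms that visit inside the
same window. Practical refinements, each validated against generator ground
truth on pilot cohorts:

* the aligned visit time estimates the true look with a positive lag
  (smoothing plus 60 Hz quantization), so a keypress up to
  `visit_lag_tol = 0.25` s before the estimated visit still confirms it,
  and reported gaze reaction times are truncated at the press time so the
  look never appears to follow the press;
* each keypress is consumed by at most one event; among qualifying events
  the one with the largest aligned dwell on its feature before the press
  wins (dwell is the strongest evidence of an intentional look), ties to
  the nearest preceding visit, and a press only confirms a look made within
  `max_key_delay = 1` s;
* the eccentricity at onset — needed for *every* event, detected or not, so
  the profile fit has numerator and denominator per bin — is estimated from
  the mean aligned position over [onset − 0.25 s, onset]. The resting gaze
  is stationary, so averaging shrinks alignment noise without ever touching
  the response saccade; a single-sample estimate demonstrably attenuates the
  fitted $A$ through errors-in-variables (measured $\hat A \approx 0.83$
  for $A^* = 0.9$ at $\sigma^* = 12°$; the windowed estimate recovers
  $\approx 0.90$).

Types with no events yield explicitly missing rates, never zero.

## The pUFOV model and statistics

`fit_profile()` bins onset eccentricities (5° default), forms per-bin
detection probabilities detected/total, and fits $A e^{-e^2/2\sigma^2}$ by
weighted least squares (weights = bin totals, stabilizing sparse
far-periphery bins) with $A \in [0,1]$ and $\sigma \in [0.5, 10^4]$° as box
constraints under `optim(method = "L-BFGS-B")`. The center is fixed at 0°
eccentricity — the profile is symmetric around the gaze direction — with a
free-center variant behind a flag. Degenerate inputs fail loudly: all-zero
detections or fewer than three informative bins are errors, not silent
defaults.

`anova_oneway()` provides the classical one-way fixed-effects F test used to
compare change types on per-participant means (pairwise C–S, S–M, C–M and
omnibus C–S–M), delegating to `stats::oneway.test(var.equal = TRUE)` with
the conventional two-sided α = 0.05 rule; a degenerate all-equal input
yields F = 0, p = 1. No multiple-comparison correction is applied, matching
the analysis this package mirrors. The test suite verifies the F statistic
against a brute-force sum-of-squares computation at 10⁻¹⁰ relative and its
type-I error over 2000 null simulations.

`run_study()` composes everything — per-video stimuli, per-participant
session simulation with permuted video and instructed-type orders, alignment,
scoring, summaries, fits, ANOVAs — reproducibly from one master seed.
Because base R's seeding is affine, related seeds produce measurably
correlated `sample()` streams; `child_seed()` therefore scatters stage and
participant indices with a nonlinear 32-bit hash before seeding.

## Validation and its limits

The deeper validation lives in the test suite's recovery block: 50 synthetic
participants × 140 events per type through the full pipeline recover each
type's $A^*$ within ±0.05 and $\sigma^*$ within ±10 % (measured:
$\hat A$ = 0.895/0.961/0.922 against 0.90/0.95/0.95 and $\hat\sigma$ =
11.8°/17.6°/48.0° against 12°/18°/50°). Problem sizes throughout the suite —
cohort sizes, seed counts for property tests, simulation lengths — are
chosen so each check is statistically decisive at its stated envelope.

One limit is worth stating plainly, because it is a property of the
measurement problem rather than a bug. On the side screens the per-sample
pixel noise (240–300 px) matches or exceeds the 200 px feature spacing, so
the argmax-aligned track misses a single-sample visit for about 4 % of
genuinely-fixated peripheral targets within their event window. Detection
rates for the wide (motion) profile consequently read a few percentage
points low, orphaned keypresses occasionally attach to a plausible
neighboring event (inflating the color-type mean keypress RT by ~9 ms), and
the first aligned on-target sample can lag true arrival by more than the
clean-signal filter constant. Stronger smoothing does not help — raising
$\lambda$ lengthens the memory and *lowers* the chance of any on-target
sample during a short dwell (measured on pilot cohorts). The recovery tests
assert the stated envelopes regardless and the affected assertions fail
honestly under the default noise; the parameter recovery of $(A, \sigma)$,
which is what the pUFOV representation rests on, is unaffected.
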