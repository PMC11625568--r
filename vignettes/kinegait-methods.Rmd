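---
title: "Estimating gait parameters from a single depth camera: methods and design"
author: "kinegait"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating gait parameters from a single depth camera: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinegait)
```

## The measurement problem

Marker-based optoelectronic motion capture is the clinical gold standard for
quantifying gait, but it needs a dedicated laboratory, trained staff and
marker placement on minimally clothed subjects. A single RGB-D camera with a
body-tracking model offers a markerless alternative: the camera sits at the
end of a short walkway, the subject walks toward it, and the tracker streams
3D positions of skeletal joints at a nominal 30 fps. `kinegait` implements
the estimation pipeline that turns such a stream into the spatio-temporal
gait parameters and pelvis-level center-of-mass (CoM) excursions used in
rehabilitation assessment — for healthy gait and for the asymmetric,
slowed gait typical of post-stroke hemiplegia — together with the
method-comparison statistics needed to validate one measurement system
against another.

The key physical idea is that in a frontal capture the camera's depth axis
*is* the walking direction. During stance an ankle is planted and its depth
is constant; during swing it advances one stride length. Gait events can
therefore be read off the ankle depth signal alone with a simple motion
threshold, and every spatial quantity is a difference of depth values at
event instants.

## Pipeline

The stages run in a fixed order; the analysis path contains no randomness.

1. **Ingest** (`read_mak_json()`): a documented JSON stream schema with
   per-frame timestamps and named joints. Positions are converted to meters,
   timestamps re-based to zero at the first frame. Frames missing a required
   joint (either ankle or hip) are dropped and counted; the resampler
   bridges the gaps. More than half the frames missing a required joint is a
   hard error.
2. **Resample** (`resample_uniform()`): camera timestamps jitter around the
   nominal frame interval, so each coordinate is interpolated onto a uniform
   50 Hz grid with a cubic spline. We use `stats::splinefun(method =
   "fmm")`, which reproduces cubic polynomials exactly; a natural spline
   (second derivative forced to zero at the ends) does not, and the
   difference is measurable exactly where we care — near the trial edges.
   Resampling also doubles the temporal resolution at which events can be
   placed (20 ms quanta instead of 33 ms).
3. **Filter** (`lowpass_filter()`): a third-order Butterworth low-pass at
   5 Hz removes tracking noise above the band of voluntary gait. The filter
   is applied forward and backward (zero phase): event *times* feed every
   temporal parameter, and a causal filter would shift them all by a fixed
   lag. The price is that the effective attenuation is $|H(f)|^2$; this is
   what the analytic checks in the test suite assert, against the
   bilinear-transform (pre-warped) magnitude response that a digital
   Butterworth actually realizes. Edge transients are suppressed by
   odd-reflection padding, with each pass offset-initialized so constant
   signals pass through exactly.
4. **Segment** (`label_phases()`): sample $i$ of an ankle depth series is
   labeled swing (1) when $|z_i - z_{i-1}| > \theta$ and stance (0)
   otherwise, with $\theta = 0.02$ m. At the 50 Hz analysis rate this is a
   1 m/s velocity gate. A tie at exactly the threshold counts as stance:
   motion requires strictly greater displacement, the conservative reading
   when equality is left undefined. Runs shorter than 3 samples (60 ms) are
   merged into their surroundings — the raw comparator chatters when the
   ankle velocity hovers near the gate, while true stance and swing phases
   last hundreds of milliseconds. The pre-debounce labels remain available
   (`raw_labels`) and are what the brute-force equivalence tests check.
5. **Events** (`extract_events()`): each 1→0 transition is a stance onset
   (initial contact), each 0→1 a swing onset (foot off), stamped with the
   time and ankle depth of the first sample of the new phase. Alternation
   per side holds by construction.
6. **Strides, steps, gating** (`build_strides_and_steps()`): a stride is
   the span between consecutive stance onsets of one foot; a step runs from
   a contact of one foot to the next contact of the other. Lengths are
   absolute depth differences (the subject approaches the camera, so depth
   decreases). Strides and steps are retained only when both bounding
   events lie inside the virtual gait-analysis path, the 1.5–4.5 m depth
   window where a frontal camera frames the whole body reliably.
7. **Parameters** (`gait_parameter_records()`): per stride — stride
   length/time, walking speed (length/time), cadence ($120/\text{stride
   time}$, two steps per stride), double support (time inside the cycle
   with *both* ankles stationary), foot off (own-side stance time as % of
   the cycle), and the step length/time of the step closing the cycle.
8. **CoM** (`com_from_hips()`, `excursions_per_cycle()`): the camera-side
   CoM proxy is the hip-joint midpoint (the marker-side construction,
   `com_from_pelvis_markers()`, nests the midpoints of the anterior and
   posterior superior iliac spine markers). Per gait cycle the excursion
   along each body-frame direction is reported in millimeters.

Axis roles are resolved through `axis_roles_for()`: the camera maps
ML/V/AP to x/y/z, a laboratory capture volume maps them to z/y/x. No
downstream code touches raw coordinate names.

## Design decisions that were genuinely open

**Step definition.** We adopt the conventional step — contralateral contact
to the next ipsilateral contact — so two successive steps tile one stride
and step length is about half a stride, the quantity clinicians expect. The
literal "one-foot step" reading (a single ankle's displacement between its
own events) equals a *full* stride length, because the planted foot does not
move; it is implemented behind `step_variant = "single_ankle"` for
completeness.

**Excursion definition.** "Maximum excursion within a cycle" is taken as
peak-to-peak (max − min), which matches the magnitudes a pelvis-level ML
sway of a few centimeters produces; maximum deviation from the cycle mean is
available via `mode = "from_mean"`. The cycle window for excursions is
closed (both bounding contacts included) so the AP excursion of a complete
cycle equals the full cycle progression — one stride length — rather than
falling one sample short; the timing quantities (double support, foot off)
use the half-open window so cycles tile the trial without double counting.

**Pooling.** Parameters are computed per stride for each leg and pooled.
Default `pooling = "trial_mean"` averages records within a trial before
summarizing across trials, matching an analysis based on a few consistent
trials per subject; `pooling = "stride"` pools stride-level records
directly. Dispersion is always the sample SD ($n-1$).

**Agreement statistics** (`agreement_table()` and friends): accuracy is
$100\% - \mathrm{MAPE}$ with the camera as the measured and the reference
system as the actual value; RMSE is $\sqrt{\sum_i e_i^2 / n}$; limits of
agreement are the mean difference $\pm 1.96$ sample SDs of the differences;
the difference orientation is measured − actual throughout. Normality
checking defaults to the Lilliefors variant of the Kolmogorov–Smirnov test
because the normal parameters are estimated from the data; the classic
variant is a flag. p-values are reported raw, with no multiple-testing
correction. Degenerate inputs are contracts, not crashes: identical systems
give $t = 0, p = 1$, accuracy 100%, $r = 1$, RMSE 0; constant nonzero
differences signal an infinite-$t$ condition.

## The synthetic gait generator

`simulate_walk()` exists so the whole pipeline can be validated against
known ground truth without human data. It emulates the capture, not the
anatomy:

* per-ankle depth alternates stance plateaus with swing transitions that
  advance one stride length following a minimum-jerk profile
  $10u^3 - 15u^4 + 6u^5$ (smooth, zero end velocity — the hard case for a
  velocity-gate detector, which is exactly what should be exercised);
* the hips translate toward the camera at the mean walking speed with a
  one-cycle lateral sinusoid (amplitude `ml_amplitude`) and a two-cycle
  vertical sinusoid (`v_amplitude`), so the true per-cycle CoM excursions
  are known in closed form (AP = stride length, ML/V = twice the
  amplitudes);
* frames are sampled at 30 fps with Gaussian timestamp jitter (2 ms SD) and
  iid Gaussian noise on every joint coordinate (3 mm SD by default, within
  reported body-tracking jitter magnitudes);
* asymmetry presets split the cycle between the two contacts in time and
  space by `step_ratio` (affected/unaffected) and scale the affected side's
  stance fraction by `stance_ratio`.

The `gait_preset()` central values — healthy: 1.40 m / 1.02 s strides, 60%
stance, 42/45 mm ML/V peak-to-peak sway; hemiplegic: 0.76 m / 1.62 s, 67%
stance, 92/28 mm ML/V, step ratio 0.8 — are group means reported for
healthy adults and post-stroke hemiplegic walkers measured with a reference
optoelectronic system. The hemiplegic stance-time asymmetry is not pinned
by published central values, so the preset keeps `stance_ratio = 1`.

**Operational stance and threshold calibration.** A subtlety deserves
honesty: "stance" in this method is *operationally defined* — an ankle is
stationary when its per-sample displacement stays under the gate. A
minimum-jerk swing leaves and re-enters the gate strictly inside its motion
window, so a purely kinematic generator would make the detector look biased
by construction. The generator therefore calibrates the motion window: it
widens the swing symmetrically with sub-gate "creep" tails (the slow ankle
roll after contact and heel rise before lift) solved so the comparator
crosses the threshold half a sample before each configured stance boundary.
`duty_factor` then parameterizes the stationarity-defined stance fraction,
and every recovery comparison is exact up to grid quantization. For gaits
too slow to stay above the gate for the full configured swing (the
hemiplegic preset is such a case: a 0.76 m advance cannot exceed 1 m/s for
0.53 s under minimum jerk), calibration is infeasible; the generator then
reverts to the kinematic window and the ground truth records the *analytic
gate-crossing instants* of the continuous noiseless model — the detector
then reports a longer stance than the kinematic one, which is precisely the
stance overestimation a threshold rule produces on slow real gait.
`truth$params` carries both `foot_off_pct` (operational) and
`foot_off_pct_kinematic`. Setting `calibrate_threshold = FALSE` forces the
kinematic variant for studying this weak spot.

**What the generator does not emulate** — and hence what passing recovery
tests do *not* demonstrate about real data: body-tracking dropouts and
depth-dependent bias, soft-tissue and tracker latency artifacts, curved or
hesitant walking paths, arm and trunk dynamics, foot-clearance kinematics
beyond a schematic lift bump, and any difference between the hip-midpoint
CoM proxy and a whole-body CoM. The recovery results certify the *pipeline
arithmetic* (resampling, filtering, thresholding, event bookkeeping,
parameter formulas), not the camera.

## Numerical choices

* Internal units are meters and seconds everywhere; CoM excursions convert
  to millimeters only at reporting.
* The resampling grid is $t_0 + k/50$ s spanning the trial; events are
  therefore quantized to 20 ms, and recovery tolerances in the tests are
  stated in these sample quanta (durations built from two boundaries may
  carry one quantum each).
* Filter padding: odd reflection, `max(24, 9 × order)` samples, each pass
  offset-initialized (constants are exact fixed points; DC gain 1 to
  machine precision).
* Debounce: 3 samples at 50 Hz; the threshold, the debounce length and the
  VGAP bounds are all configurable (`segmentation_config()`).
* Walks that would overrun the near bound mid-stride are truncated with a
  warning. Simulated trials add a lead-in before the first contact long
  enough that the first stance run survives debouncing on both sides.
* Problem sizes: validation runs use 6 strides per leg (~220 frames, ~7 s
  of walking) and 10 random repetitions where noise is involved — enough
  for every per-cycle quantity to appear at least a dozen times while
  keeping a full suite run in seconds.

## Known limitations

* Double support is the most fragile parameter: it is a short interval
  bounded by four independent event quantizations, and on fast gait the
  both-stationary window shrinks toward the grid resolution.
* The operational/kinematic stance distinction means `foot_off_pct` from
  slow walks is systematically larger than the kinematic stance fraction;
  consumers comparing against systems with anatomical event definitions
  should expect that bias and can quantify it via
  `foot_off_pct_kinematic`.
* The depth-axis geometry assumes a straight, frontal approach; `kinegait`
  provides an optional per-cycle linear detrend for ML/V for mildly
  non-aligned walks but no path reconstruction.
* Only pelvis-level CoM proxies are implemented; segmental whole-body CoM
  models are out of scope, as are joint angles and kinetics.

## Reproducing the validation numbers

`scripts/acceptance.R --seed <int> --out <path>` re-runs the full chain —
simulate both presets, analyze, compare with ground truth, exercise the
agreement statistics — and writes every headline quantity as JSON. The test
suite (`testthat`) contains the same checks plus the brute-force and
closed-form oracles for every statistic.
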