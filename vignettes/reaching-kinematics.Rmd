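---
title: "Quantifying reaching after stroke: the IoEE, StartReact, and their association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying reaching after stroke: the IoEE, StartReact, and their association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reachstart)
```

## The measurement problem

After a hemiparetic stroke, recovery of upper-limb reaching depends on how
much descending motor drive survives and how it is rerouted. Two
non-invasive measures speak to this:

* a **kinematic** measure of how far the elbow extends during a reach,
  obtainable from an ordinary webcam video processed by markerless keypoint
  tracking; and
* a **neurophysiological** measure, the StartReact effect, in which a loud
  startling sound delivered with a visual go-cue shortens EMG reaction time
  by engaging reticulospinal pathways; the size of the shortening indexes
  the strength of those connections.

`reachstart` implements both measurement chains and the correlation layer
that relates them to each other and to clinical scores (ARAT, MAS, grip
strength), plus a synthetic-data generator so that every stage can be
verified against known ground truth.

## The Index of Elbow Extension

Given per-frame pixel positions of the wrist, elbow and shoulder,

$$\mathrm{IoEE} \;=\; \frac{\max_f d_f(\text{shoulder},\text{wrist})}
{\max_f d_f(\text{shoulder},\text{elbow}) + \max_f d_f(\text{elbow},\text{wrist})},$$

with each maximum taken independently over that distance's valid frames.
The denominator estimates the summed projected segment lengths, so the
ratio is dimensionless: no pixel-to-metre calibration is needed, and a
camera angle that foreshortens all limb segments alike largely cancels.
For a rigid two-segment arm the triangle inequality confines the value to
$[0, 1]$: 0 when the wrist never leaves the shoulder, 1 when shoulder,
elbow and wrist become collinear at full extension.

Design choices worth knowing:

* **Independent maxima.** The three maxima are taken over each pair's own
  valid frames, a literal reading of the defining ratio. The alternative —
  all three distances from a single frame — is not used; it describes a
  different quantity (a per-frame extension ratio, maximised afterwards).
* **No clipping above 1.** With all three distances computed from the same
  frames the ratio cannot exceed 1 (triangle inequality, per frame). It
  *can* exceed 1 when confidence masking removes different frames for
  different pairs — e.g. the elbow drops out in the most extended frame.
  That excess is evidence of tracking trouble, so `compute_ioee()` reports
  the raw value with `exceeds_unity_flag` rather than hiding it.
* **Confidence threshold defaults to 0**, reproducing an unfiltered
  tracking export; real tracker output contains dropout, so the threshold
  is exposed (`confidence_threshold`) with per-pair, not global, masking.
* **Camera-angle robustness is conditional.** The cancellation argument
  holds exactly when the segments' orientations at their maximal-distance
  frames are similar. For a seated table-top reach — elbow extending while
  the upper arm stays within a few tens of degrees of the downward
  vertical, the geometry the generator defaults emulate — 2D and 3D
  estimates agree to better than 0.01 at a 30° camera azimuth. If the arm
  sweeps widely (e.g. raising to horizontal while extending), constant-
  length segments attain their 2D maxima in their most vertical frames and
  the index can be biased low by several hundredths. This is a property of
  the measure, not of the implementation.

The 3D reference measure is the interior elbow angle,
$\theta = \arccos\big(\hat{u}\cdot\hat{v}\big)$ with $\hat u, \hat v$ the
unit vectors from the elbow to shoulder and wrist; `max_elbow_angle()`
reports its per-frame series and maximum. The cosine is clamped to
$[-1,1]$ before `acos` so exactly collinear geometry survives rounding.

```{r ioee-demo}
arm <- arm_model(elbow_angle = seq(60, 170, length.out = 30))
reach <- simulate_reach(arm, camera_model(jitter_sd = 0))
glance(compute_ioee(reach$track2d))
glance(max_elbow_angle(reach$track3d))
```

## EMG onset detection and the StartReact effect

Each trial is a cue-locked voltage series (5 kHz in the emulated rig).
Analysis proceeds as:

1. **Rectification**: subtract the mean of the raw 200 ms pre-cue window
   (DC removal — electrode offset must not inflate baseline statistics),
   then take absolute values.
2. **Baseline**: mean and SD of the rectified signal over the same 200 ms
   window. Computing both on the *rectified* representation keeps the rule
   self-consistent, since the threshold is compared against rectified EMG;
   whether the original analyses did this on raw or rectified baseline is
   not documented, so it is a package decision.
3. **Onset**: the latency is the time from cue to the first rectified
   sample exceeding `mean + k * SD` (default `k = 5`) that stays above
   threshold for at least `min_supra` ms (default 5). The sustained-crossing
   guard replaces interactive review of spurious triggers (e.g. single-
   sample stimulus artifacts); skipped crossings set `flagged_artifact` so
   automated decisions remain auditable. No onset found is a valid outcome
   (`NA`), not an error, and such trials are excluded from condition means
   rather than imputed.

`summarize_conditions()` aggregates per cue condition — VRT (visual only),
VART (visual + quiet sound), VSRT (visual + startling sound) — and reports

$$\mathrm{StartReact} = \overline{\mathrm{VART}} - \overline{\mathrm{VSRT}} \quad\text{(ms)},$$

positive when the startling cue shortens reaction time.

```{r emg-demo}
ts <- simulate_trialset(latency_model(), n_per_condition = 20, seed = 42)
glance(summarize_conditions(ts))
```

## The statistical layer

* `cor_spearman()` ranks with midranks and computes the coefficient as the
  Pearson correlation of ranks. For `n <= 8` the two-sided p-value is an
  **exact permutation** value — all $n!$ orderings enumerated, p the
  proportion with $|\rho|$ at least the observed — giving a testable oracle;
  for larger n the usual t approximation on $n-2$ df applies (at the
  study-scale n = 15 its empirical size is about 0.05, verified by
  simulation in the test suite). Two-sided p-values throughout.
* `bh_adjust()` is the Benjamini–Hochberg step-up rule at a fixed FDR
  (default 5%). It returns reject/accept flags in input order and
  deliberately does **not** emit adjusted p-values: uncorrected p-values
  plus flags are the reporting convention the battery follows.
* `correlation_table()` runs the eleven-measure battery (MAS; ARAT total
  and four subscores; normalized grip; VRT, VART, VSRT; StartReact)
  against a target measure (IoEE by default) over complete cases, with BH
  applied once across the whole battery (`m = 11`); per-row m is
  configurable through `measures`.
* `normalized_grip()` is `100 * affected / less_affected` (each input the
  maximum over repeated dynamometer trials); `validate_arat()` enforces the
  subscale maxima 18/12/18/9 and the total-of-57 identity.

## What the synthetic generator emulates — and what it does not

The generator exists so that every downstream stage has ground truth; its
defaults are the emulated study conditions, chosen once:

* **Arm**: upper arm 0.30 m, forearm 0.28 m (adult male scale), elbow
  extending 60°→170° over 30 frames at 15 fps, upper arm near the downward
  vertical (azimuth default 30°) as in a seated reach to a table. Segment
  lengths are constant by construction — the property the IoEE denominator
  relies on.
* **Camera**: orthographic projection with a single azimuth per recording
  and Gaussian pixel jitter. Orthographic is the simplest model in which a
  camera angle affects each segment similarly, which is exactly the
  assumption behind the IoEE normalization; perspective effects at ~1.5 m
  are second-order for this purpose and are out of scope.
* **EMG**: latencies drawn per condition from truncated normals with the
  study-scale parameters (VRT 326 ± 96, VART 274 ± 89, VSRT 225 ± 80 ms),
  truncated to `[cue + 50 ms, trial end − burst]` so every trial is
  analyzable; 20 trials per condition in random order. The burst is a
  random-polarity carrier with per-sample magnitudes U(0.9, 1) × amplitude
  under a rectangular envelope, and the envelope gates the background noise
  out while the burst is on. Real EMG onsets are not rectangular and
  resting noise does not vanish; the design guarantees a zero-crossing-free
  rectified rise, which is the property an amplitude-threshold +
  sustained-crossing detector needs if it is to recover onsets at burst
  amplitudes as low as 5× the baseline SD. Passing detector tests therefore
  certify the detection logic, not robustness to physiological burst
  morphology.
* **Cohort**: one latent "damage" severity u ~ U(0, 1) per subject maps
  linearly into every measure plus independent Gaussian noise — the
  simplest mechanism realizing a shared-third-variable structure. IoEE
  decreases (0.88 − 0.45u, clipped to [0, 1]) and StartReact increases
  (15 + 75u ms) with damage, so their association is negative by
  construction. The default noise SDs (0.06 IoEE, 18.8 ms StartReact) were
  calibrated once by large-n Monte Carlo so the population Spearman rho is
  −0.70, the design point of the battery; clinical columns respect the
  ARAT subscale maxima and MAS ordinal levels. Real cohorts are not driven
  by a single uniform latent; recovery of rho here validates the
  estimation chain, not the biology.

All randomness flows from one explicit integer seed per call (child seeds
are derived internally), so identical spec + seed gives bit-identical
output while the caller's RNG state is left untouched.

## Numerical and degenerate-input conventions

* Pixel convention: origin top-left, y increasing downward (irrelevant to
  distances and angles, fixed for I/O round-trips). CSV numerics are
  written with 6 decimals; write-then-read is stable at that precision.
* Onset latencies are quantized to the sampling grid (0.2 ms at 5 kHz).
* A zero-SD baseline with an all-zero signal yields an absent onset, not
  an error; coincident elbow/shoulder/wrist points raise a
  degenerate-geometry error and are skipped (and counted) by
  `max_elbow_angle()`.
* Constant vectors make correlations undefined and error explicitly;
  complete-case analysis, no imputation, in the battery.
* The nape landmark is required, parsed and stored, but unused by the
  IoEE — it mirrors the tracked landmark set of the acquisition protocol.

## Problem sizes used in verification

The test suite and the acceptance script regenerate everything they
measure: 500 seeded trials (plus 500 burst-free) for detector recovery, a
300-trial equivalence sweep against a naive sample-by-sample scanning
oracle, 100 replicate cohorts of n = 200 for correlation recovery, and
10,000 null simulations at n = 15 for the size of the Spearman test.
These sizes give Monte-Carlo standard errors comfortably inside the
asserted tolerances while keeping a full run in tens of seconds.

## Known limitations

* The pipeline begins at keypoint tracks; video-to-keypoint inference and
  3D body-tracking models are external tools and out of scope.
* No trajectory smoothing or filtering is applied, matching an unfiltered
  tracking export; heavy dropout is handled by masking only.
* Trunk compensation is representable only as shoulder translation in the
  arm model; no trunk-lean metric is computed.
* The oblique-camera robustness of the IoEE is conditional on reach
  geometry (see above); a camera square-on to the movement plane is the
  reliable configuration.
* StartReact summaries at study scale (15 subjects × 20 trials) carry
  sampling SDs of several ms; single-subject effects should be read
  accordingly.
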