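---
title: "Quantifying leg tremor from high-speed leg-tracking data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying leg tremor from high-speed leg-tracking data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flytremor)
```

## The measurement problem

Action tremor in walking *Drosophila* shows up as rapid, involuntary
oscillation of the leg tip superimposed on the ordinary stride cycle.
High-speed video tracking (1000 frames/s over a 10 × 10 mm arena imaged at
512 × 512 px, i.e. 51.2 px/mm) yields per-frame claw positions for all six
legs. flytremor turns those trajectories into per-fly tremor statistics and
line-level screen calls, with a gait simulator providing ground truth for
validation.

The operational definitions are:

* **Shake**: an accepted turning point of a body-centred,
  body-size-normalised claw trace whose excursion from the previously
  accepted extremum is at least **3 normalised pixels**. The 3 px floor
  filters displacements attributable to tracking error (about 98% of tracked
  positions lie within 3 px of the true claw position, roughly a leg-tip
  width).
* **Tremor episode**: a run of **at least 3 shakes** (2 in the relaxed
  primary-screen mode) on one leg in which every inter-shake interval is
  **strictly under 100 ms** — one stride period at the ~10 Hz control stride
  rate, chosen so that oscillation faster than the stride cycle counts and
  the stride cycle itself does not.
* **Tremor rate**: episodes pooled over all six legs divided by the analysed
  bout duration (s⁻¹). A fly is **tremor-positive** if it has at least one
  episode; line **penetrance** is the tremor-positive fraction.

## Detection model

### Hysteresis turning-point scan

Shake detection is a zigzag scan with amplitude hysteresis, applied
independently to the anterior–posterior (AP) and medio-lateral (ML)
body-frame axes. Starting from the trace's first value, the scan tracks a
running candidate extremum; the candidate is *accepted* once the trace has
reversed away from it by the amplitude floor, after which the search flips
direction. Accepted extrema therefore alternate in polarity and are each at
least the floor apart — the standard way to count oscillation reversals with
an amplitude threshold while staying robust to sub-pixel jitter. An unreversed
final extremum at the trace end is never emitted, so a pure sinusoid of `k`
cycles yields `2k ± 1` shakes. Events on the two axes closer than 3 ms merge
into one shake (a single physical jerk registers on both axes).

`detect_shakes()` is deliberately *pure*: it scans whatever trace it is
given. Its correctness is established against an independently implemented
running-extremum oracle on hundreds of random traces (exact agreement).

### Why a gait high-pass is necessary

Normal walking itself produces large alternating AP turning points: at a
10 Hz stride rate and ~30 px stride half-amplitude, stride reversals are
~60 px excursions arriving every ~50 ms. Fed raw into the shake definition,
every walking fly would be continuously "tremoring" — while real control
flies show tremor rates near zero. The stride cycle must therefore be removed
before the amplitude test, and the package does this explicitly:
`summarize_fly()` and the pipeline pass body-frame traces through two
cascaded zero-phase (forward–backward) 2nd-order Butterworth high-pass
sections with a default cutoff of **25 Hz**, between the stride rate (~10 Hz)
and the tremor band used by the simulator (30–60 Hz). At these defaults the
stride component is attenuated by a factor of ~1600 (to ~0.04 px — far below
the 3 px floor) while 30–60 Hz oscillation keeps 45–90% of its amplitude, so
a twice-threshold tremor burst stays clearly supra-threshold. Zero-phase
filtering preserves event times; odd-reflection padding suppresses edge
transients, and simulated episodes are kept ≥60 ms from the bout edges.

This is distinct from *smoothing*: no low-pass denoising is applied by
default (an optional moving-average smoother exists behind
`smooth_window_ms`, off by default). The cutoff is exposed as
`detection_params(highpass_hz = )`; setting it to 0 disables gait removal,
which is the right choice for traces that are already oscillation-only (and
is what the oracle-equivalence tests use).

### Tunable parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `min_amplitude_norm_px` | 3 | norm. px | shake amplitude floor (tracking-error width) |
| `min_shakes` | 3 (2 relaxed) | — | shakes per episode |
| `max_gap_ms` | 100 | ms | strict inter-shake bound (one stride period) |
| `dedup_window_ms` | 3 | ms | cross-axis merge window |
| `highpass_hz` | 25 | Hz | gait-removal cutoff (0 = off) |

Body-size normalisation rescales displacements by `reference / body_length`;
the reference defaults to the fly's own length (identity) and the pipeline
uses the cohort mean, recorded in provenance. The walking-bout QC applies the
inclusive ≥1.5 body-length net-displacement rule.

## The synthetic walker

`simulate_walking_fly()` emits the stated world used throughout testing: a
straight-walking hexapod with tripod coordination ({L1, R2, L3} antiphase to
{R1, L2, R3}), sinusoidal AP claw excursion at 10 Hz (half-amplitude 30 px,
~0.5 body length peak-to-peak for a 128 px ≈ 2.5 mm fly), forward speed
`2 × amplitude × rate` ≈ 600 px/s ≈ 11.7 mm/s, and exact body-pose columns.
Tremor is injected as additive band-limited sinusoidal bursts (default
30–60 Hz, half-amplitude 6 px = twice the detection floor) along the AP axis
— a purely kinematic model, matching how tremor is defined and detected, not
a mechanistic neural oscillator. Real tremor frequency content is not
characterised; the 30–60 Hz band is a labelled placeholder chosen to sit
above the gait band.

**Tracking noise.** Per-axis error has marginal SD 1.29 px, the Gaussian
calibration of "98% of positions within 3 px" (3/2.326). Its temporal
structure matters more than its marginal: the 3 px amplitude floor is *meant*
to filter tracking error, which constrains the error process to rarely
produce ≥3 px reversals. An iid process at that SD violates this badly
(hundreds of spurious hysteresis events per second); adjacent 1 ms video
frames are nearly identical, so real localisation error is strongly
autocorrelated. The generator therefore uses slow AR(1) drift (correlation
time 250 ms, SD ~1.23 px) plus fast iid sub-pixel jitter (SD 0.4 px). Under
these defaults the full pipeline detects zero episodes on control flies and
recovers twice-threshold injected episodes with sensitivity ≥ 0.95 at FDR
≤ 0.05 (seeded tests).

**What a green test does not establish.** The simulator walks in a straight
line at constant speed with a stationary gait; real flies accelerate, turn,
pause and vary stride amplitude, and real gait has harmonics above 10 Hz that
a 25 Hz cutoff only partly rejects. Sensitivity/FDR results transfer to real
data only to the extent that stride energy stays below ~20 Hz and tremor
above ~30 Hz.

## Screen statistics

Screen design uses the per-line detection probability `1 − (1 − p)^n`: an
80%-penetrant line is detected with probability 0.992 by testing 3 flies
(the chance that none shows tremor is 0.2³). Penetrance is reported with
exact Clopper–Pearson intervals (beta-quantile form; coverage ≥95% by
construction, verified by sweep). Background rates print half-up at one
decimal (2/167 → 1.2%, 9/403 → 2.2%).

Group comparisons follow the screen's convention: Mann–Whitney U (normal
approximation, tie-corrected) for two groups; for more, Kruskal–Wallis
followed by Dunn's rank-based post-hoc z tests versus the control with
Bonferroni-style adjustment. "ANOVA with Dunn's correction" is interpreted as
the Kruskal–Wallis/Dunn pairing, since Dunn's test is defined on ranks; a
parametric ANOVA + t route is retained behind `parametric = TRUE`. The Dunn
statistics are implemented in-package (no installed package provides them)
with the usual tie correction, and validated against hand-computed examples.
Climbing–tremor correlation defaults to Pearson (an unqualified "r"
conventionally denotes Pearson, and climbing height is an interval-scale
score); Spearman is available via `method` when rank robustness is preferred.
Fly selection for recording follows the
"three poorest climbers" rule with deterministic lexicographic tie-breaking.

## Colocalisation

Neurotransmitter-identity calls use two standard readouts. (1) Spot-to-target
proximity: each spot (e.g. a Histone-RFP nucleus) is positive when its
nearest target point (e.g. a sampled GABA-immunostain surface) lies strictly
under 0.1 µm. Surfaces are represented as sampled point clouds and distances
are point-to-point — a documented approximation of mesh distance. The
nearest target is located with the fast quadratic-expansion distance form,
then the winning distance is recomputed by direct differencing so the strict
0.1 µm boundary is not blurred by floating-point cancellation. (2) Manders
coefficients on co-registered channels with the upper-right-quadrant ROI:
`M1 = Σ ch1 over (ch1 > t1 & ch2 > t2) / Σ ch1 over (ch1 > t1)`, and
symmetrically `M2`; both necessarily in [0, 1]. Thresholds are mandatory
arguments — the reference workflow sets them manually per image and a hidden
default would be arbitrary.

## Numerical and design choices

* **Frame convention**: 0-based frames, `t_ms = frame / fps × 1000`, pixel
  centres, y down (image convention).
* **Gap policy**: tracking dropouts ≤2 frames are linearly interpolated and
  flagged; longer gaps split the recording into bouts (a trajectory object
  holds one contiguous bout; the reader returns the longest by default).
* **Boundaries**: the episode gap bound is strict (<100 ms); the walking QC
  bound is inclusive (≥1.5 body lengths); the proximity rule is strict
  (<0.1 µm). Ties in climber selection break lexicographically.
* **Pose fallback**: when body-pose columns are absent, centroid = mean of
  the six claws (exact for the symmetric tripod layout) and heading = first
  principal axis, sign-fixed by the front legs. The PCA heading wobbles with
  gait phase (up to ~0.1 rad for the default layout), so supplied pose
  columns are preferred for real data; the fallback is exactly invariant
  under rigid whole-body motion.
* **Episode-count monotonicity**: widening `max_gap_ms` can merge two
  episodes into one, so the episode *count* is not monotone in the gap bound;
  the number of shakes covered by episodes is, and that is the invariant the
  tests assert.
* **Determinism**: every stochastic step takes a seed; identical config and
  seed produce byte-identical pipeline outputs (fixed-format TSV/JSON
  writers).

## Known limitations

* Tremor is characterised purely in the time domain (reversal counting); no
  spectral analysis is attempted.
* The detector's gait/tremor separation is a frequency split; tremor at or
  below ~20 Hz would be attenuated with the stride cycle, and gait harmonics
  above ~25 Hz in real recordings would leak into the shake count.
* The simulator's Bernoulli per-fly tremor status ignores within-line
  severity correlation, and injected bursts are pure tones rather than the
  broadband oscillation real tremor presumably is.
* Colocalisation operates on exported point sets and voxel arrays; no image
  segmentation or background subtraction is performed.
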