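---
title: "Measuring finger-pointing proprioception from hand-landmark streams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring finger-pointing proprioception from hand-landmark streams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(propoint)
```

# The measurement problem

Proprioception — the sense of limb position — is impaired by stroke and many
other conditions, yet it is rarely quantified: bedside finger-to-finger
pointing tests are scored pass/fail by eye. Markerless hand trackers make a
quantitative version possible with nothing but a webcam: both hands are
tracked as 21-landmark skeletons, the target hand is hidden from the
participant behind an opaque overlay, and the residual distance between the
pointing fingertip and the instructed target landmark when the movement
stops is the proprioceptive error.

`propoint` implements the full scoring pipeline over recorded landmark
streams, plus simulators that generate streams and robotic-assessment data
with known ground truth. This vignette explains the model, the parameters,
the numerical conventions, and what the synthetic experiments do and do not
establish.

# The error metric and its assumptions

A trial's raw signal is the per-frame 2D pixel distance between the pointing
index fingertip (landmark 8) and the instructed target landmark.

**Frontal-plane restriction.** Only image-plane (x, y) coordinates are used.
Monocular trackers infer depth, and those estimates are not reliable enough
to score; proprioceptive errors that are 3D in nature are assumed to
manifest in the frontal plane as well. The depth channel is preserved by the
I/O layer but a dedicated test perturbs it and asserts that no output
changes. The known blind spot: an error purely in depth projects to zero.
This is acceptable for populations whose endpoint errors are roughly
isotropic, but it bounds the metric's validity for pure-depth dysmetria.

**Hand-size calibration.** Pixel errors scale with camera distance. The
conversion uses the hand itself as the ruler:

$$\mathrm{error}_{cm} = \frac{\mathrm{handsize}_{cm}}{\mathrm{handsize}_{px}}\,\mathrm{error}_{px}$$

where $\mathrm{handsize}_{px}$ is the sum of 2D distances along the
hand-skeleton edges of the target hand in the same frame, and
$\mathrm{handsize}_{cm}$ is the participant's metric hand size. Both the
error and the hand size are homogeneous of degree one in pixel coordinates,
so any uniform rescaling cancels exactly; the test suite asserts relative
changes below $10^{-9}$ for scale factors between 0.25 and 4.

Two choices here were genuinely open:

* *Edge set.* "Sum of distances between the hand landmarks" admits many
  readings. The default is the standard 21-point skeleton connection set
  (six palm edges plus each finger's joint chain), truncated at the terminal
  landmark of the active pointing level, and it is overridable
  (`edge_set` argument) for comparability with other conventions. Truncation
  makes the TIP ⊇ PIP ⊇ MCP edge sets nested, which the tests check as a
  monotonicity property.
* *Aggregation of* $\mathrm{handsize}_{px}$. It is computed per frame from
  the target hand and smoothed with a running median (window 9 frames,
  `smooth_k`); the value at the stop frame enters the conversion. The median
  resists single-frame tracking glitches without biasing a stationary hand.
  With a time-varying camera scale the median mixes scales within half a
  window of a scale change; the drift test therefore uses `smooth_k = 1`,
  where the cancellation is exact per frame.

**Metric hand size.** Measured participants: a photo of the hand next to a
scale reference; `pixels_per_cm()` uses the perimeter of a US-letter page
(2 × (8.5 + 11) × 2.54 = 99.06 cm) by default. Unmeasured participants: sex
defaults of 49.87 cm (women) and 54.84 cm (men). The fake-hand control
object is fixed at 60 cm. An unspecified sex is a hard error rather than a
silent average: the two defaults differ by ~10 %, which propagates linearly
into every score.

**Landmark levels.** Participants who cannot extend the hand point to the
PIP or MCP joints instead of the fingertips. The level is fixed per session
and the hand-size sum uses the same level, keeping the ratio consistent. The
thumb has no PIP/MCP in the four-finger sense; the package substitutes its
IP joint (index 3) at PIP level and its CMC/MCP node (index 2) at MCP level
as the anatomically nearest skeleton nodes — a convention, stated here
because upstream descriptions leave it open.

# Stop detection

A movement is scored at the first frame $i$ where both:

1. $\mathrm{error}_{cm}[i] \le 15$ cm (proximity), and
2. the population SD of $\mathrm{error}_{cm}[(i-w+1)\,..\,i]$ is below 5 cm,
   with $w = \mathrm{round}(2\,\mathrm{s} \times fps)$ (movement has slowed
   or stopped).

Conventions fixed for reproducibility: the SD divides by $n$, not $n-1$ (the
window is the population of interest, and the convention must simply be
stated); both criteria are evaluated on the calibrated centimeter series,
because the radius is specified in centimeters; the earliest qualifying
index wins with no hysteresis; a series shorter than the window returns a
`too_short` flag rather than an answer. The implementation is a vectorised
cumulative-sum scan; the tests compare it index-for-index against a naive
$O(nw)$ re-scan on 1000 random series.

The 2 s / 60-sample equivalence pins the nominal frame rate at 30 Hz, which
is stored per stream; all sample windows are derived as
`round(seconds × fps)`, so other frame rates degrade gracefully. Dropped
frames are represented as absent timestamps, never interpolated; alignment
between the two hands is nearest-neighbour within half a frame period, and
unmatched frames are excluded and counted (`n_gap_frames`).

**Correction truncation.** Participants sometimes "correct" after their
initial movement, which would understate their deficit. The reference
procedure is manual annotation of the frame before the correction, and a
manual index always wins (clamped to the detected stop). An automated
heuristic is provided but OFF by default: it finds the first trailing-SD
plateau of at least 0.3 s below the SD threshold and, if renewed movement
follows, truncates at that plateau's last stable index. Because the trailing
window lags, the returned index can sit a few frames into the correction
onset; result records always state whether truncation was `manual`,
`heuristic` or `none` so downstream analysis can stratify.

# Protocols and cohort analysis

`unimpaired_15` is 15 trials, exactly 3 per finger, in seed-reproducible
random order; `stroke_30` is 30 trials, balanced at 6 per target by default
— the 30-trial variant's balance is not externally specified, and symmetry
with the 15-trial design was chosen (it is configurable).

Cohort scoring follows a deliberately simple, auditable chain:

* **Outlier removal** is a single pass per (group, task) on pooled
  trial-level errors: mean and population SD computed once, values strictly
  outside mean ± 2 SD removed, boundary ties kept. Trial-level pooling was
  chosen over participant-level because removal is meant to catch tracking
  or procedure failures, which are trial events. Note an algebraic corner:
  in a set of $n=5$ with four equal values, the lone value sits *exactly* on
  the 2-SD bound, so the strict rule keeps it — the tests freeze this
  behaviour deliberately.
* **Participant means** average kept trials; zero kept trials yields a
  flagged missing value, never a silent zero.
* **Normative flags** compare a participant mean to an upper-tail reference:
  `above_2sd` / `above_3sd` beyond the reference mean plus 2 or 3 reference
  SDs. Only the upper tail is flagged: unusually *small* errors are not a
  deficit.
* **Concurrent validity** is a Pearson correlation (`stats::cor.test`)
  between participant pointing means and an external measure, with missing
  pairs dropped and counted and zero-variance inputs rejected. Inferential
  machinery beyond this (ANOVA families, post hoc tests) is intentionally
  not re-implemented; the exported tidy tables feed standard tools.

# The Crisscross simulator

The robotic reference assessment moves index and middle fingers in opposite
directions at an identical speed drawn from
{8, 8.5, 9, 10, 10.5, 11.5, 12.5, 14, 16, 18} deg/s across 15–45° of
flexion; the participant presses a button at the perceived crossing, and the
error is the angular separation at the press, averaged over 20 movements.
Trajectories are ideal constant-velocity ramps — no robot dynamics — so the
crossing is exactly at the 30° midpoint for every speed and direction, and
angles at arbitrary times are evaluated analytically (a `dt`-sampled
trajectory is available for plotting). Two conventions are the package's
own: direction assignment is randomized per trial with equal probability,
and a press outside the motion span censors the trial with a flag rather
than clamping, which would bias the mean toward the range edge.

The simulator's one modelling assumption is a Gaussian press-latency:
press = crossing time + bias + $N(0, \sigma_t)$. Since the fingers separate
at relative speed $2v$, an unbiased participant's mean error has the
folded-normal closed form $2v\sigma_t\sqrt{2/\pi}$, which the tests verify
by simulation at $10^4$ trials within 3 %.

# The synthetic stream generator

`render_stream()` emulates what the scoring pipeline consumes: a static
target hand (a canonical 21-landmark template rescaled so its skeleton sum
equals a configured metric hand size) plus a pointing hand that translates
rigidly while its fingertip follows a minimal-jerk profile from a start
position to `target + bias + noise`, holds, and optionally "corrects" with a
second minimal-jerk segment. All centimeter geometry is multiplied into
pixels by a camera scale that may drift linearly over the trial, emulating a
change of distance from the camera. Tremor is low-amplitude (default
0.02 cm, capped at 0.05 cm) *rigid* per-frame jitter of the target hand —
rigid so the hand-size sum stays exact; per-landmark jitter would be a model
of tracking noise, which this generator deliberately does not include beyond
that option.

Choices and their reasons: minimal jerk because point-to-point reaches are
well described by it and its smooth deceleration exercises the stop detector
realistically (a movement that stops instantaneously would make stop
detection trivially easy); a 1.5 s reach plus 2.5 s hold at 30 fps so the
2 s stop window can fill after arrival.

**What passing synthetic tests shows — and does not.** The generator proves
the pipeline's arithmetic: with tremor off, the scored error equals the
constructed endpoint truth to machine precision, and with isotropic 2D
endpoint noise $\sigma$ the mean recovered error converges to
$\sigma\sqrt{\pi/2}$ (verified over 2000 full render-and-score trials within
2 %). It does not model real tracker behaviour: landmark jitter correlated
with pose, occlusion dropouts, hand-detection swaps, lens distortion, or
depth-dependent landmark bias. Results on real recordings inherit whatever
error the upstream tracker makes; the package's guarantees are about
everything downstream of the landmarks.

The joint-validity simulation draws a latent per-participant deficit that
multiplies both pointing endpoint noise and press-latency SD
(log-normal multipliers sharing a configurable fraction of their variance).
Its pointing side is simulated at endpoint level — radial magnitudes of 2D
Gaussian endpoints — rather than through full stream rendering: the
render-and-score path is already validated to reproduce endpoint truth
exactly, so rendering would add runtime, not evidence, to a correlation
property. With 16 participants sharing 80 % of deficit variance, the
pointing–Crisscross correlation is positive in ≥ 95 of 100 seeded cohorts,
and grows with the shared fraction.

# Numerical conventions and degenerate inputs

* Streams are validated at construction and at read time; invalid records
  are rejected with their line number, never repaired. Writers refuse
  non-finite coordinates. Round trips through JSONL and CSV preserve
  coordinates to full double precision.
* Indices into error series are 1-based (R convention); a constant series at
  30 fps first qualifies at index 60, the first full 2 s window.
* A degenerate (all-coincident) hand raises a zero-size error rather than
  producing an infinite calibration ratio.
* The occlusion polygon is the convex hull of the landmarks dilated by a
  margin via uniform scaling about the hull centroid (every edge moves
  outward by at least the margin); collinear landmark sets fall back to a
  margin-padded bounding box.
* Protocol generation and all simulators take explicit seeds and restore the
  caller's RNG state, so library calls never perturb a user's random stream.

# Problem sizes

The test suite and reference script run at desk scale by design: 1000 random
series for the stop-detector equivalence, 2000 rendered trials for the
radial-error recovery, $10^4$ trials for the folded-normal law, 100 cohorts
of 16 for the validity property — sizes at which the Monte-Carlo error is
comfortably inside each stated tolerance. The full suite completes in well
under a minute on a single core.

# Known limitations

* Pure-depth errors are invisible to a frontal-plane metric (discussed
  above).
* The sex-default hand sizes inject inter-individual variance into scores of
  unmeasured participants; measured calibration is preferred.
* The correction heuristic truncates with a trailing-window lag and is not a
  substitute for the manual procedure it defaults away from.
* The generator's tremor model is not a tracker-noise model; robustness
  claims are limited accordingly.
* Live capture is out of scope: the package consumes recorded streams, and
  any camera adapter must simply emit the documented JSONL/CSV format.
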