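---
title: "Methods: oculomotor measures, the synthetic gaze generator, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: oculomotor measures, the synthetic gaze generator, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(noisegaze)
```

## The problem

Oculomotor inhibitory control is commonly probed with two paradigms. In the
*prolonged fixation* (PF) task the participant fixates a central point for
60 s; failures of inhibition show up as large gaze excursions (intrusive
saccades) and reduced time on target. In the *memory-guided saccade* (MGS)
task a peripheral disc is flashed for 300 ms at 10° eccentricity in one of
the four diagonal directions while the participant keeps fixating; only
after the central point extinguishes (the go cue) may the gaze move to the
remembered location. Premature saccades (anticipatory), slow or inaccurate
responses, and wrong-quadrant landings all index distinct failure modes.
Studies of this kind compare a clinical group against controls across
stimulation conditions (here: no noise, auditory white noise, and visual
pixel noise at two transparency levels) with repeated measures within
participant.

`noisegaze` implements the full measurement chain from raw 600 Hz binocular
gaze samples to group × condition model reports, together with a synthetic
gaze generator whose presets plant every measured quantity, so the chain can
be validated by parameter recovery rather than by eye.

## Coordinate model

Trackers of this class report gaze in normalized screen coordinates with
(0,0) the upper-left and (1,1) the lower-right corner. All analysis
thresholds, however, are stated in degrees of visual angle. The package
converts per axis through the tangent plane:

$$x_{deg} = \arctan\!\big((x_{norm} - 0.5)\, w / d\big),$$

with $w$ the physical screen width and $d$ the viewing distance (defaults
527 mm and 630 mm; a 23.8″ 16:9 panel viewed from 63 cm), and the y sign
flipped so that up is positive. Distances between gaze points are planar
Euclidean in this per-axis degree space — the standard small-angle treatment
in eye-tracking work. At the eccentricities that matter here (≤ 12°) the
difference from the exact 3D gaze-vector angle is far below the 2° decision
thresholds. How the original tracking stack computed its degrees is not
documented publicly; the tangent-plane choice is ours and is stated rather
than asserted as identical.

## Fixation detection

The detector follows the windowed two-means clustering family:

1. invalid runs shorter than 100 ms are linearly interpolated per eye
   (longer runs — blinks, track losses — are left invalid and naturally
   split fixations);
2. the two eyes are averaged where both are valid, otherwise the valid eye
   is used;
3. inside every 200 ms window (stepped by 20 ms, plus a final flush window
   so trailing samples are covered) the trace is clustered into two means,
   and each cluster switch distributes weight 1/(switches in window) to the
   switch sample; per-sample weights are means over covering windows;
4. samples with weight at or below mean + 2 SD form fixation candidates;
   candidates closer than 0.7° with gaps under 30 ms are merged; candidates
   shorter than 40 ms are dropped. Centroids are means of member samples.

The hot loop (windowed 2-means with temporal-half initialisation and Lloyd
iterations) is implemented in C++ for throughput; a full 60 s PF trial
(36,000 samples) is processed in well under a second. Numerical notes: a
constant window is degenerate for 2-means — it yields no switches and hence
zero weight, so a perfectly still recording becomes a single fixation; the
threshold comparison is `<=` so the all-zero-weight case keeps all samples
as candidates. Linear rather than shape-preserving-spline interpolation is
used for short gaps; on all fixtures the difference stays far below the 2°
thresholds downstream.

A classic dispersion detector (I-DT; 1° maximum dispersion, 100 ms minimum
duration) ships as an alternative backend and is used in the tests as a
structural cross-check. Exact numeric equivalence with any published
implementation is not claimed — agreement is asserted at the level of the
thresholded measures.

Saccades are *derived*, not detected: each pair of consecutive fixations
defines one saccade with onset at the first fixation's offset and amplitude
equal to the centroid distance. This is the right operationalization for a
measurement chain whose every quantity is fixation-based; velocity-based
onsets and main-sequence kinematics are out of scope.

## The six measures

* **Fixation ratio** (PF): duration of fixations strictly within 2° of
  center over total fixation duration.
* **Intrusive saccades** (PF): saccades with amplitude ≥ 2°, counted from
  the first on-center fixation onward, so initial approach saccades are
  excluded no matter how many there are. Both legs of an excursion count
  (each is a large saccade); a one-way switch counts excursions instead.
  The `<` / `≥` boundary pair makes correctness and intrusiveness exactly
  complementary at 2°.
* **Anticipatory saccades** (MGS): saccades ≥ 2° with onset in
  [flash onset, go + 80 ms) — too early to be a reaction to the cue. The
  window starts at flash onset because earlier events are not analyzed; the
  upper edge is half-open and complementary to the response window.
* **Latency** (MGS, correct trials): go cue → onset of the response saccade,
  the first ≥ 2° saccade with onset in [go + 80 ms, go + 1000 ms].
* **Gain** (MGS, correct trials): response amplitude / 10°. Corrective
  saccades after target reappearance are ignored.
* **Correct-trial classification** (MGS): (i) ≥ 1 fixation overlapping
  [flash onset, go]; (ii) every such fixation < 2° from center (including
  partially overlapping ones); (iii) a response saccade exists; (iv) its
  landing fixation is ≥ 2° from center; (v) the landing lies in the flash
  quadrant. All failed criteria are reported. "Target offset" is read as the
  go cue: the flash is extinguished 2–3.5 s before the response is allowed,
  so anchoring (iii)–(iv) at flash offset would make most well-performed
  trials ill-defined; the alternative reading remains available behind
  `target_offset = "flash_offset"` for sensitivity analyses, and the
  recovery suite uses the default. Latency and correctness are both anchored
  to the response saccade's onset so they can never disagree. Landings
  exactly on a quadrant axis match no quadrant (they fail v); with diagonal
  flash directions this set has measure zero under the generator.

## Data quality and exclusion

Following the minimal-reporting conventions for eye-tracking research, the
package reports per eye (never averaged): sample-to-sample RMS precision
(pairs bridging invalid gaps are skipped, so blinks cannot inflate noise
estimates), accuracy as the mean offset against validation targets
(unweighted mean over targets), and data loss as the invalid-sample fraction
(counted over samples at the nominal rate; timestamps here are regular by
construction).

Trials are excluded when loss exceeds 20% **in both eyes** — the literal
reading of a "loss from both eyes" rule; a config switch provides the
stricter either-eye variant. The scope window is the whole trial for PF and
flash onset → target reappearance for MGS. Exclusion is idempotent,
order-independent, and the pipeline's accounting reconciles exactly:
simulated trials = kept + excluded, with both loss values logged per
exclusion.

## The synthetic generator

The generator is first-class, tested code. Each group × condition preset
plants:

* fixational jitter (Gaussian per sample and eye; 0.06° ADHD / 0.045° TDC,
  chosen so the derived RMS-S2S precision lands at the 0.07–0.08° the
  hardware class achieves);
* a per-trial constant calibration offset (SD 0.35° per axis, matching
  ~0.6° mean accuracy offsets);
* binocular blinks (12/min × 260 ms ADHD, 10/min × 250 ms TDC ≈ 4–5% loss)
  plus rare gross track-loss episodes (25–50% of the scope window, with
  probability 0.03 ADHD / 0.015 TDC) that drive the exclusion-rule paths at
  roughly the observed 3–4% exclusion rates;
* the behavioral parameters transcribed from the published group means
  (fixation ratio, intrusive count, anticipatory count, latency mean/SD,
  gain mean/SD, proportion correct) for all eight cells. Latency means for
  the auditory cells are not printed (that contrast showed no latency
  effects) and reuse the no-noise values; those presets carry an
  `interpolated` flag.

Three couplings make the planting exact in expectation:

* **Anticipatory saccades are out-and-back excursions.** Each event jumps
  ≥ 2.5° away for 150–350 ms and returns, producing exactly two countable
  saccades, so events are Poisson with half the planted count mean. The
  implied per-trial count SD (for the ADHD no-noise cell, ≈ 1.17) happens to
  sit close to the published trial-level SD (1.28).
* **Correctness has a closed form.** Any delay-window excursion breaks
  criterion (ii), so
  $p_{correct} = e^{-\mu/2}\,(1 - p_{break})\,(1 - p_{quad})$, where $\mu$
  is the planted anticipatory mean; $p_{quad}$ (the probability the response
  is launched into a wrong quadrant) is solved per cell from the planted
  proportion correct. Presets whose proportion would exceed the anticipatory
  ceiling are rejected at construction.
* **Latency and gain are truncated to the valid response region with
  re-solved locations.** Latency is 80 ms + lognormal truncated to
  [85, 995] ms, with the log-mean found by root solving so the *truncated*
  mean equals the planted mean (plain rejection sampling would bias the
  slowest cell by about −7 ms). Gain is Normal truncated to [0.21, 1.6]
  (location re-solved likewise); the lower bound keeps every response
  saccade at or above the 2° detection and eccentricity thresholds, so
  criterion failures cannot silently distort the planted proportion.

Two deliberate realism choices protect the recovery contract: blinks are
suppressed during the response epoch (go − 50 ms to go + 1050 ms), mirroring
blink inhibition around goal-directed saccades, so a blink can never eat the
response onset; and corrective saccades are only emitted when the landing
error is at least 1° (the saccadic dead zone) — a sub-degree corrective
would land within the detector's 0.7° merge radius and pull measured gain
toward 1.

PF trials plant excursions as Poisson with half the intrusive mean and scale
dwell durations so the expected on-center time fraction equals the planted
fixation ratio.

**Participant heterogeneity.** Presets carry a `participant_sd` field for a
participant-level shift, but it defaults to zero: the generator's primary
contract is exact recovery of planted cell means at the pre-registered
tolerances (±0.02 ratio and gain, 10% counts, ±10 ms latency, ±0.03
proportion at full cell size), and a between-participant variance component
matching the intraclass correlations such studies report would consume most
of those bands with cluster-level sampling noise. The statistics module is
instead calibrated against measure-level tables generated with explicit
random intercepts (see the test suite), which exercises exactly the code
that consumes heterogeneity.

What the generator does **not** emulate: saccade velocity profiles (planted
saccades are instantaneous plateau jumps — irrelevant to fixation-based
measures, and a detector stress-test would need a main-sequence ramp),
smooth pursuit, microsaccades below the merge scale, pupil dynamics, head
movement, monocular loss asymmetries, and any within-participant correlation
structure across conditions. Passing recovery tests therefore validates the
measurement chain's correctness on signals with realistic noise, blinks and
loss — not the detector's behavior on kinematically faithful saccades.

## Statistics

Measure-specific transforms mirror common practice for these outcomes:
rank-based transformation for the two PF measures, log(x+1) for
anticipatory counts (zeros are common), log for latency, square root for
gain. "Rank-based" is under-specified in the field; the default here is
rank-based inverse normal with Blom offsets, $\Phi^{-1}((r - 3/8)/(n +
1/4))$ with ties sharing mean rank, and plain mid-ranks are available. All
transforms are strictly monotone, so cell orderings survive.

The model contract is `value ~ condition * group + (1 | participant)` with
treatment coding (no-noise reference), a type III ANOVA with Satterthwaite
degrees of freedom (delegated to `lmerTest`), and Bonferroni-adjusted
pairwise contrasts of estimated marginal means (`emmeans`). The auditory
contrast (2 conditions) and the visual contrast (3 conditions sharing the
no-noise cell) are fit as separate models, driven by the `conditions`
argument. Singular fits are flagged in the report, never silently dropped.
Descriptive summaries aggregate trials → participant → cell and attach
t-based 95% CIs over participant means (the pooled-trial alternative is a
one-line change at the call site). Marginal/conditional R² reporting is
intentionally omitted.

## Stimuli

Auditory noise: integers uniform on [0, 225] per channel, affinely mapped
onto the symmetric 16-bit range, 48 kHz stereo PCM WAV (a minimal WAV
reader/writer is built in; round-trips are bit-exact). Visual noise:
per-refresh blending `out = (1 − α)·image + α·noise` with fresh uniform
noise each 60 Hz frame; blending is affine in α by construction. The bound
**225** (not 255) is reproduced verbatim from the source description; it may
well be a typo for the full 8-bit range, so `max_value = 255` is a supported
switch, but the printed value is the default. Sound-pressure calibration is
hardware-dependent and out of scope.

## Problem sizes and tolerances

The recovery suite runs the study-sized cells: 52 participants × 30 trials
for the MGS recoveries (gain ±0.02, anticipatory mean ±10%, proportion
correct ±0.03, latency ±10 ms) and 52 one-per-participant PF trials
(fixation ratio ±0.02, intrusive mean ±10%). Unit and property tests use
desk-scale fixtures (1–3 s traces, 100–300 seeded repetitions); the model
stage's type I error is calibrated over 200 small null cohorts (12 + 12
participants) against a 2–8% acceptance band. The end-to-end demo cohort in
the README uses 5 + 5 participants × 5 trials per condition, which completes
in well under two minutes.

## Known limitations

* The tangent-plane degree conversion and the detector re-implementation
  are documented equivalents, not bit-level reproductions of any vendor or
  published implementation.
* The fixation-based saccade onset is late relative to a velocity-based
  onset by up to one sample; latency estimates inherit a sub-millisecond
  mean bias (measured ≈ −0.8 ms), far inside the ±10 ms recovery band.
* Excluded trials are dropped, not imputed; with loss processes that
  correlate with behavior, recovered cell means are conditional on
  retention, as in the real analysis.
* The generator's correctness coupling means anticipatory-rich cells cannot
  plant arbitrarily high proportions correct; the constructor rejects such
  presets loudly rather than silently clipping.
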