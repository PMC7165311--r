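---
title: "Validating fall re-enactments with slope-constrained DTW"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating fall re-enactments with slope-constrained DTW}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fallwarp)
```

## The problem

A real-world fall recorded by a lower-back accelerometer is a short
triaxial trace — typically a hundred seconds of walking, a violent
transient, a ground phase, and a recovery — with no video to say what the
body actually did. Re-enactment closes that gap iteratively: a protocol of
postures and movements is hypothesized from the signal, performed in the
laboratory under safe conditions with the same sensor configuration, and
revised until the re-enacted signal resembles the original. `fallwarp`
supplies the two quantitative ingredients this loop needs: a similarity
score that tolerates timing differences, and (because real fall
repositories cannot be redistributed) a seeded simulator that generates
fall-like recordings with known ground truth.

## The alignment model

Two recordings of "the same" fall never agree in timing: each phase runs
shorter or longer in the re-enactment. Dynamic time warping absorbs this by
finding, over all monotone pairings of query samples to template samples
permitted by a step pattern, the pairing minimizing the accumulated local
distance. `fallwarp` fixes the conventions as follows.

**Roles.** The real-world (reference) signal is the *query*; the
re-enacted signal is the *template*. The pattern family is asymmetric:
every rule advances the query index, every query sample is matched, and
only the template axis may be stretched, compressed, or (with open ends)
left partially unmatched.

**Step pattern.** The Sakoe–Chiba asymmetric pattern with slope parameter
P = 1 (`asymmetric_p1()`) admits three rules into cell (i, j): a flat rule
from (i−1, j−2) through (i, j−1) (weights 0.5/0.5, local slope 1/2), the
diagonal from (i−1, j−1) (weight 1), and a steep rule from (i−2, j−1)
through (i−1, j) (weights 1/1, slope 2). P = 1 therefore confines the local
slope to [1/2, 2]: the warp can at most halve or double the local tempo.
Per rule the weights sum to the query advance, so along any complete path
they sum to the query length N.

**Open begin / open end.** With `open_begin` the first query sample may
match any template sample at cost d(1, j) — the skipped template prefix is
free; with `open_end` the path may stop at any template column, the
minimum over the last row deciding (earliest column on ties). Both default
to *on* in the comparison layer (`compare_axes()`, the CLI), because a
re-enactment trial records lead-in and lead-out that the reference event
does not contain. The open ends free the *template* only; the query is
always fully matched. That asymmetric reading is forced by the pattern
family (the query drives the normalization) and by the role assignment
above; a symmetric "free query ends" variant is deliberately not offered.

**Score.** The normalized distance is the cumulative weighted cost divided
by N. Since path weights sum to N, it is a weighted mean local cost per
query sample — comparable across events of different lengths, which is the
point: no common time base exists between a real fall and its re-enactment.
There is no natural threshold for this score; it is a relative measure for
ranking successive re-enactments of the same reference.

**Per-axis alignment.** Comparisons run univariately per axis (x sagittal,
y mediolateral, z vertical), yielding three scores per trial; the vertical
axis is usually the most informative for falls but no combined score is
canonical, so the iteration report stores all three and uses their
unweighted mean only to flag a best iteration. A multivariate mode (3-D
Euclidean local distance, pass matrices to `dtw_align()`) exists but is not
the default.

## Numerical choices

- The DP is computed row-vectorized over the template axis in doubles;
  results are deterministic. Tests compare at absolute tolerance 1e-9.
- Ties in the cell-wise minimum are broken by preferring the diagonal
  rule, then the flat rule, then the steep rule, so backtracked paths are
  reproducible.
- The backtracked path includes the interior cells of multi-cell rules;
  `warp_template()` needs them to know which template samples to repeat.
  It assigns query index i the template sample at the *largest* template
  index paired with i.
- Infeasible alignments (the slope bounds admit no path — e.g. closed-end
  with M outside [(N−1)/2 + 1, 2(N−1) + 1]) raise a typed condition
  (`fallwarp_infeasible_error`) naming both lengths, rather than returning
  infinity that would propagate silently into reports.
- Series shorter than 2 samples are rejected; no windowing band is applied
  beyond the slope constraints themselves.
- Percent improvement between consecutive iterations is
  100·(previous − current)/previous, reported as `NA` when the previous
  distance is 0 (a perfect predecessor admits no relative improvement).
- Phase transfer maps a start boundary through the first matching path
  pair and an end boundary through the last matching pair of its final
  sample; where a steep/flat rule stalls the destination axis the mapped
  end may overlap the next mapped start by one sample, and is clipped to
  it so a tiling stays a tiling.

## The simulator

`simulate_fall()` exists so the alignment machinery can be exercised, and
its conventions tested, without access to restricted fall repositories. It
generates the canonical six-phase structure of a stumble-forward fall —
(1) prefall steps, (2) stumble/fall/impact, (3) rest, (4) raising the
upper body, (5) rest, (6) straightening up to standing — at 100 Hz in
units of g, with ground-truth annotations tiling the signal.

The kinematic model is a single-angle rigid-trunk approximation: the
sensor sits near the trunk's center of mass and, in a static posture with
trunk pitch θ (0° upright, 90° horizontal forward bend), reads gravity as
z = cos θ, x = sin θ, y = 0. Movement phases decorate this:

- *steps*: upright gravity plus a vertical sinusoid at the step frequency
  (default 1.8 Hz, amplitude 0.25 g) and a quarter-amplitude mediolateral
  sway at half that frequency (body sway alternates sides every two steps);
- *fall/impact*: total magnitude decays linearly to 0 over the freefall
  duration (default 0.3 s — the sensor approaches free fall), then a
  half-sine transient along the end-posture direction peaks at
  `impact_peak_g` over the impact duration (defaults 3 g, 0.15 s), then
  the static end-posture reading (default pitch 70°, kneeling with the
  trunk bent forward);
- *rest*: the static reading;
- *raise/stand*: pitch follows a cosine ramp between the endpoint angles,
  with a 4 Hz vertical transient whose amplitude decays linearly to zero
  by phase end.

The default protocol's phase-3 duration (1.5 s, hands touching the ground)
and phase-5 duration (4 s, resting on the knees with the upper body
upright) follow the written re-enactment instructions for this fall
paradigm; every other duration and amplitude is a package default chosen
to give a plausible lower-back trace, and is documented as such rather
than measured from data. Sensor noise is i.i.d. Gaussian per axis and
sample (default sd 0.02 g); an optional symmetric clip emulates a ±2 g
device range. Phase sample counts round half away from zero; zero-length
phases contribute no samples and no annotation. One top-level seed drives
per-phase noise substreams derived deterministically, so a simulation is
bit-for-bit reproducible and editing one phase leaves the other phases'
noise untouched.

What the simulator does *not* emulate — and what passing tests therefore
do not show about real data: multi-segment body dynamics (roll and yaw are
absent; the trunk is rigid), realistic impact spectra (real impacts
against hard ground are impulsive and device-saturated; the half-sine is
synthetic by construction), 1/f sensor noise, quantization, and the
heterogeneity of real fall paradigms. The simulator validates the
alignment and reporting machinery, not biomechanics.

`perturb_protocol()` models between-trial variability: per-phase duration
offsets (clamped at 0.1 s for originally positive phases) and independent
uniform 1 ± scale factors on the amplitude/frequency parameters. Pitch
angles and the freefall/impact sub-durations stay fixed — they define the
movement paradigm rather than its execution quality.

## The convergence study

`reenactment_convergence()` restates the workflow's premise as a testable
property: simulate a reference from a protocol; at each perturbation scale
(defaults 0.5, 0.2, 0.05) draw perturbed protocols (duration jitter up to
±2·scale seconds per phase, parameter scale as above, fresh noise seeds),
simulate, and score against the reference. The acceptance suite requires
the mean per-axis normalized distance over 20 replicates to decrease
strictly across 0.5 → 0.2 → 0.05 under a fixed seed. The study sizes —
the 14.5 s / 1450-sample default recording, 20 replicates, three scales —
keep the full study around a minute on one core while leaving the
monotonicity comfortably clear of sampling noise.

## I/O conventions

Signals interchange as plain CSV (`time,x,y,z`; seconds and g; one header
row, comma separator, dot decimal) written at full double precision, so
write–read round-trips are exact given the rate and a second write is
byte-identical. Rate inference uses 1/median inter-row gap and rejects
grids whose gaps deviate from the median by more than 1% (real phone logs
jitter slightly; anything worse is not a constant-rate recording).
Resampling, when two devices differ in rate, is linear interpolation over
the common time span — the simplest defensible choice, recorded so it can
be revisited; no other preprocessing (filtering, trimming) is applied
anywhere. Protocols serialize as YAML with 17 significant digits (exact
for doubles); unknown keys are schema errors. Annotations use 0-based
half-open index intervals, which keep the uniform-grid arithmetic free of
off-by-one ambiguity.

## Known limitations

- The alignment is univariate per axis by default; cross-axis coupling in
  the warp is only available through the non-default multivariate mode.
- Open begin/end free template samples only; a recording where the
  *reference* carries extraneous lead-in must be trimmed by the caller.
- The simulator's realism limits are listed above; distances measured on
  simulated pairs are not calibrated against distances on real recordings,
  and the package deliberately offers no "similar enough" threshold —
  stopping the re-enactment loop remains a human judgment.
- Memory for one alignment is O(N·M) (two dense tables); at 100 Hz this is
  comfortable for minutes-long events but not for hour-scale recordings.
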