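---
title: "Methods: simulating and analysing sEMG-driven grip rehabilitation sessions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing sEMG-driven grip rehabilitation sessions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semgrip)
```

## The system being modelled

`semgrip` re-implements, as testable software, the signal path of a wearable
grip-rehabilitation system: a forearm band records single-channel surface
EMG (sEMG) of the finger flexors at 500 Hz; an acquisition module calibrates
a trigger threshold and converts squeezes into click events; the clicks
drive an adaptive obstacle-jumping game; and an offline pipeline computes
spectral fatigue metrics from the recorded signal. Because no raw
recordings from the original feasibility study were published, the package
ships a synthetic-sEMG generator with known ground truth; all end-to-end
claims are made, and tested, against that generator.

## The synthetic sEMG generator

Surface EMG at rest and during moderate contraction is well approximated by
a band-limited, zero-mean stochastic interference signal. The generator
synthesises each 1 s block in the frequency domain: complex Gaussian
coefficients are scaled by the square root of a spectral template and
inverse-transformed, so the realised power spectrum follows the template
exactly in expectation. The template is a Gaussian bump centred on the
target median frequency (MDF), truncated to the 20–250 Hz band, with its
width set to one third of the distance to the nearest band edge. That
width keeps the in-band template effectively symmetric, so its median — and
hence the signal's MDF — equals the target; it is the one free shape choice
the physics does not dictate, and it was fixed once, before any tests were
written.

Grip events multiply this carrier by a trapezoidal envelope: 50 ms linear
rise and fall ramps around a plateau at `burst_gain` times the resting RMS.
Ramps avoid the step discontinuities that would otherwise inject broadband
artifacts, and they give onset times an unambiguous definition (the foot of
the rise). Fatigue is modelled as a linear MDF drift, realised as a
piecewise-constant MDF per 1 s synthesis block; spectra are constant within
a block, which keeps synthesis simple and makes the drift exactly
recoverable by block-wise analysis. An optional DC offset and quantisation
step mimic an ADC front-end; the detection path is deliberately insensitive
to both.

Defaults: 500 Hz sampling, resting RMS 1 (arbitrary units), burst gain 5,
1 s bursts roughly every 6 s, target MDF 60 Hz. The 60 Hz default sits in
the range typically reported for forearm flexor sEMG during light gripping;
the amplitude scale is arbitrary because every downstream statistic is
either difference-based or normalised. What the generator does *not*
emulate: motor-unit structure, tremor, movement artifacts, electrode lift,
or mains hum. Passing end-to-end tests therefore demonstrate the internal
consistency of the stack under clean physiology-like input, not robustness
to real-world artifacts.

## Calibration and trigger detection

The acquisition module's amplitude statistic is the absolute difference of
consecutive raw samples, averaged over a rolling window of the last 300
measurements (0.6 s at 500 Hz). During warm-up the average uses the
available prefix rather than zero-padding, avoiding a spurious quiet start.
Calibration replays the device's four-state sequence — 5 s standby
(discarded), 5 s relaxed grip, 3 s maximal squeeze — and takes the mean
rolling amplitude of the relax and squeeze windows as the two anchors. The
trigger threshold is `rest + 0.60 × (max − rest)`: of the readings of
"60% difference between relaxation and contraction", this is the only one
bounded by both anchors, and the fraction is exposed as a parameter.

Calibration is declared failed when the squeeze mean is not at least 1.5×
the rest mean — a concrete stand-in for "fails to reliably detect muscle
activity" — signalling the caller to raise the sensor gain and retry.
Detection emits an event at each rising crossing of the same rolling
amplitude above the threshold, then ignores crossings for a 0.3 s
refractory period so one sustained squeeze yields one click; 0.3 s is
comfortably below any plausible inter-squeeze interval in a jumping game.
Calibration and detection intentionally share the same statistic so their
units agree. The rolling window introduces a detection latency of roughly
0.35 s after burst onset (the window must fill with burst-level amplitudes
before the 60% point is crossed); evaluation accounts for it by shifting
ground-truth onsets by a configurable `latency_allowance_s` before
tolerance matching.

## The headless game

The game is simulated on a fixed 20 ms tick with a deterministic, seeded
RNG. Obstacles spawn ahead of the character every 2 s (± uniform jitter)
and arrive after `spawn_distance / game_speed`; a trigger starts a 0.7 s
jump; an obstacle is cleared only if the character is airborne for its
entire passage, so wider (large) obstacles demand better-timed jumps — the
package's concrete reading of "difficulty scales with obstacle size".
Three levels increase speed (1, 1.3, 1.6 units/s) and the large-obstacle
probability (0, 0.5, 1); coins appear from level 2 as added decision load,
never cost lives, and are excluded from the success-rate denominator.
Every 15 s the obstacle success rate decides the level: ≥ 0.8 up, ≤ 0.4
down, otherwise hold; the dead-band keeps "moderate" play stable. A third
collision pauses the game 5 s, restores three lives and resets to level 1;
resets are logged as difficulty changes with a `reason` of `"reset"`.
The 15 s evaluation window is the default; the alternative ~1 min reading
that also circulates for this class of game is available by setting
`window_s`. All numeric choices (speeds, spawn cadence, jump length,
level-2 large-obstacle probability 0.5) are package defaults fixed in
`game_config()`; only their ordering and structure are externally
constrained.

## The offline analysis pipeline

The pipeline bandpasses the raw recording with a 4th-order Butterworth
design applied forward–backward (zero phase, so peak timing is preserved),
with odd-reflection padding to suppress edge transients. At 500 Hz the
nominal 250 Hz upper edge sits on Nyquist and is unrealisable; it is
clamped to 99% of Nyquist. Normalisation to [−1, 1] is computed once per
recording — per-segment normalisation would force the mean peak amplitude
(MPA) towards a constant across games and erase exactly the between-game
differences of interest — followed by rectification.

Peak picking smooths the rectified signal with a 0.3 s moving average and
takes one candidate per contiguous envelope excursion above `min_height`
(default 0.1 normalised units), then keeps the taller of any two candidates
closer than `min_separation_s` (default 0.5 s). The excursion rule matters:
a rectified interference signal has hundreds of raw local maxima per
contraction, and only an envelope-level definition yields one peak per
grip. MPA is the mean rectified height of the surviving peaks.

MDF is computed on the bandpassed, pre-normalisation signal — rectification
distorts the spectrum, and the fatigue literature defines MDF on the raw
interference signal — via Welch averaging (1 s Hamming windows, 50%
overlap). The median is the frequency where in-band cumulative power
reaches half the total, linearly interpolated within the crossing bin; when
the cumulative power plateaus at exactly half (two equal-power tones), the
plateau midpoint is returned. The fatigue statistic is
`100 × (MDF₃ − MDF₁)/MDF₁` between the last and first game segments, and a
per-minute MDF series is emitted for trend plots.

## Event matching and statistics

Detections are matched to ground truth one-to-one within a ±0.2 s closed
tolerance window. Truth events are processed in increasing time, each
taking the *earliest* unused in-window detection. For equal-width windows
this greedy rule provably attains the maximum number of pairs (it is the
classic greedy solution of convex bipartite matching); a nearest-detection
rule, though intuitive, can drop a feasible pair when two truth events
compete for two detections, and the test suite checks the implemented rule
against brute-force optimal matching on random instances. F1 is
`2TP/(2TP + FP + FN)`, defined as 0 (with a warning) when all counts are
zero. Group comparisons use two-sided t-tests (Welch by default, pooled and
paired variants by flag) at a deliberately liberal alpha of 0.25 — in a
small exploratory cohort the goal is flagging candidate trends, not
confirmation — and the suite verifies the empirical type-I error matches
that nominal level. Questionnaire aggregation reports per-question mean ±
sample SD and a grand mean defined as the mean of the six question means;
no SD is attached to the grand mean because no defensible derivation from
per-question SDs exists without raw responses.

## The protocol runner and problem sizes

`run_protocol()` chains every stage deterministically from one master seed:
calibration stream → threshold → 15 min of gameplay recording (three
contiguous 300 s games; rest periods are neither recorded nor advance the
fatigue clock) → trigger detection → per-game replay through the game →
per-segment metrics → tolerance matching. With the default −2%/min drift
test configuration, game midpoints sit at 2.5 and 12.5 gameplay minutes, so
the expected MDF change is 100 × (0.75 − 0.95)/0.95 ≈ −21.1%; repeated
seeds spread about ±2 percentage points around it, and tests allow ±3.
The test suite runs shortened 3 × 60 s protocols for speed and reserves the
full 3 × 300 s session for the acceptance checks; a full protocol takes a
few seconds of CPU.

## Known limitations

* The simulator's spectral template is a single Gaussian bump; real sEMG
  spectra are skewed and multi-modal, so absolute MPA/MDF values are not
  comparable to hardware recordings — only their relative changes are
  meaningful here.
* The gain-retry ladder in `run_protocol()` cannot rescue a subject whose
  contraction contrast is genuinely absent (amplitude ratios are
  gain-invariant); it models the procedural loop, not the analog physics of
  a pre-ADC gain change.
* The game's jump-timing mechanic (a jump must span the obstacle's whole
  passage) is one concrete choice among several compatible with the stated
  difficulty structure.
* Whether the original firmware emitted edge- or level-based triggers per
  packet is unknowable from the outside; the package emits both an edge
  event list and a per-sample activity trace, and evaluation uses edges.
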