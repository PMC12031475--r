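# semgrip

Surface-EMG grip detection, adaptive serious-game simulation and
muscle-fatigue analysis.

`semgrip` is an R re-implementation of the software stack of a wearable
grip-rehabilitation system for people with weakened hand grip (for example
from Parkinson's disease, ALS or MS, or simply ageing). The hardware records
single-channel surface electromyography (sEMG) of the finger flexor muscles
at 500 Hz through a textile forearm band, turns squeezes into click events,
and lets the user play an adaptive obstacle-jumping game by gripping a
resistive ball. The package is for researchers who want to study, stress or
extend that signal path without the hardware: every stage is ordinary,
seeded, testable R code.

It covers five things:

* **Synthetic sEMG** (`simulate_session()`, `simulate_cohort()`): band-limited
  stochastic signals with a controllable median frequency (MDF), rest/burst
  envelopes with known grip-event ground truth, and an optional linear MDF
  drift emulating muscle fatigue.
* **Calibration and trigger detection** (`run_calibration()`,
  `detect_triggers()`): the device's four-state calibration (5 s standby,
  5 s relax, 3 s maximal squeeze), its amplitude statistic
  (|difference of consecutive samples|, rolling mean of 300), and the
  threshold rule *rest + 0.60 × (max − rest)* with a refractory trigger
  emitter.
* **A headless adaptive game** (`run_game_session()`): three difficulty
  levels with increasing speed and obstacle size, coins from level 2, three
  lives, success-rate-driven level transitions every 15 s, and a 5 s
  pause-and-reset on the last life; logs clicks, difficulty changes and
  outcomes.
* **Offline signal analysis** (`bandpass()`, `normalize_rectify()`,
  `find_activity_peaks()`, `median_frequency()`, `segment_metrics()`):
  20–250 Hz zero-phase bandpass, per-recording normalisation, rectification,
  envelope peak picking, Welch-based MDF, and the fatigue statistic
  100 × (MDF₃ − MDF₁)/MDF₁ across the three games.
* **Evaluation** (`match_events()`, `f1_score()`, `compare_groups()`,
  `summarize_useq()`): one-to-one event matching within ±0.2 s,
  F1 = 2TP/(2TP + FP + FN), two-sample t-tests at the study's liberal
  alpha = 0.25, and questionnaire aggregation. Published study aggregates
  (demographics, pooled confusion counts, per-question satisfaction means)
  are bundled as `ref_*()` tables.

`run_protocol()` chains everything into the full feasibility protocol —
calibrate, then three 5-minute games with the recording analysed per game —
deterministically from one master seed.

## Worked example

Simulate one subject with a −2 %/min fatigue drift and run the whole
protocol:

```r
library(semgrip)
r <- run_protocol(session_config(seed = 1, mdf_drift_pct_per_min = -2))
print(r)
#> <protocol_result>
#>   calibration: threshold 1.846 (gain 1)
#>   151 ground-truth squeezes, 156 detected triggers
#>   detection: TP=141 FP=15 FN=10 F1=0.9186
#>   MDF per game: 57.3, 50.3, 44.3 Hz
#>   MDF percent change (Game 3 vs Game 1): -22.71%
```

The subject squeezed 151 times over 15 minutes of gameplay; the calibrated
threshold detected almost all of them (F1 0.92 — fatigue shifts the signal's
spectrum and lowers the amplitude statistic, which costs a few detections;
without drift the same seed gives F1 ≈ 0.99). The per-game median frequency
falls from 57.3 Hz to 44.3 Hz, a −22.7 % change against the −21.1 % expected
from the configured drift: the pipeline recovers the planted fatigue.

The published aggregates reproduce directly:

```r
counts <- ref_detection_counts()            # pooled TP/FP/FN per group
f1_score(counts$tp[1], counts$fp[1], counts$fn[1])
#> [1] 0.834341                              # healthy-group F1
mean(ref_useq_means()$mean)
#> [1] 4.65                                  # questionnaire grand mean
```

A command-line wrapper with `simulate`, `calibrate`, `detect`, `play`,
`analyze`, `evaluate` and `protocol` subcommands is installed at
`system.file("cli/semgrip.R", package = "semgrip")`; every stage reads and
writes plain CSV.

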