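# wristintake

Semi-hierarchical recognition of **eating and drinking** from a
wrist-worn IMU (tri-axial accelerometer + gyroscope at 100 Hz), aimed at
free-living, real-time use — the sensing side of meal/hydration
reminders for independently living older adults.

Eating and drinking are asymmetric targets: a meal is many minutes of
low-energy manipulation, a drink is one gesture of a few seconds. The
pipeline therefore runs two binary branches with different
segmentations and fuses them under daily-evidence rules:

```
100 Hz stream ──► downsample (50 Hz) ──► causal Butterworth low-pass ──► half-Gaussian smooth
      │
      ├─ eating branch:   fixed 10 s windows ─► 33 features ─► RF ─► p_class(i)
      │                       E1: p_meal(i) = Σ_{n=0..N} p_class(i−n)·p_time(i−n) / N  > 0.5
      │                       minute vote (>3 of 6 windows) ─► E2: runs ≥ 5 min ─► meals
      │
      └─ drinking branch: dynamic fixed windows (DFW, reset every 10 s) on ‖gyro‖
                              ─► 33 features ─► RF ─► D1: ≥1 rotational peak > 60 deg/s ─► drinks
```

`p_time` is a time-of-day meal prior: the clipped sum of three unit-peak
Gaussians at 08:00, 12:30 and 20:00 (σ = 1.5 h). The dynamic windows
split where a descending run of the gyroscope magnitude exceeds
`max(floor, 3 · robust-sd of the previous 2 s)`, placing boundaries at
the end of a gesture's descending flank. Class imbalance is handled by
SMOTE + ENN (implemented in the package); classifiers are 100-tree
probability random forests (`ranger`). Everything is seeded and
reproducible.

Because the recordings this class of system is validated on are
private, the package ships a **synthetic day generator**: meals with
hand-to-mouth gestures and pre-meal energy bursts, 5–8 s two-peak drink
gestures, walking/desk/idle background, and the classic confusers
(board games over a table, nail biting) as hold-out distractors. Every
stage of the pipeline is tested against this generator's known ground
truth.

## Worked example

```r
library(wristintake)

cfg  <- intake_config(seed = 1)
demo <- run_demo(cfg)   # ~2 min: synthetic cohort -> train -> unseen 16 h day
demo$eval
#> <intake_eval> 16.00 h scored; weighted F1 = 0.997
#> overall 10 s confusion (rows = truth):
#>        pred
#> truth   eat drink other
#>   eat   213     3     0
#>   drink   0    43     0
#>   other   3    15  5483
#> eating: sens 1.00 spec 1.00 FP/h 0.19 | drink events: 34 TP, 33 FP, 0 FN
c(demo$fp_minutes_raw, demo$fp_minutes_restricted)
#> [1] 47  3
```

Reading those numbers: all three planted meals and all 34 drink events
are recovered on a day the models never saw; the raw eating classifier
marks 47 false-positive minutes (mostly during the afternoon board-game
block), which the time-of-day gate plus the 5-minute rule cut to 3; the
3-class weighted F1 on the 10 s grid is 0.997.

Per-result-type `tidy()` / `glance()` methods return tibbles, and
`autoplot()` works on streams, timelines, predictions and evaluations.
A thin command-line wrapper with `simulate / preprocess / segment /
featurize / train / predict / evaluate / demo` subcommands lives at
`inst/cli/wristintake.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/wristintake.R", package = "wristintake"))')" demo --seed 1 --out-dir out/
```

## Package layout

* `R/stream.R`, `R/config.R` — stream/label containers, CSV and config I/O
* `R/preprocess.R` — downsample, Butterworth, half-Gaussian smoothing
* `R/segment.R` + `src/dw_scan.cpp` — FW / DW / DFW windowing
* `R/features.R`, `R/select.R` — 33 features, two-stage selection
* `R/balance.R`, `R/models.R` — SMOTE+ENN, branch forests, timeline
* `R/postprocess.R` — meal prior, E1/E2/E3, D1, fusion
* `R/evaluate.R` — confusion, PRF, sens/spec/FP-h, event matching
* `R/synthetic.R`, `R/training.R` — day generator, training cohort
* `vignettes/eating-drinking-recognition.Rmd` — methods and design notes
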