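# nldbench

Offline benchmarking of linear and nonlinear intracortical finger-velocity
decoders on synthetic spiking-band-power (SBP) sessions.

## The problem

Brain-machine interfaces for dexterous finger control map 96 channels of
SBP — the rectified 300–1000 Hz band of the intracortical signal, averaged
into 50 ms bins — onto the velocities of two finger groups (index, and
middle-ring-small), measured in flex/s on the normalized [0, 1] flexion
range. Nonlinear decoders have overtaken linear ones on this task, and the
interesting question is *where* the advantage comes from. The answer this
package is built to measure: hand movements spend most of their time nearly
still and a small fraction at high speed; a linear readout must trade off
those regimes with one global degree of shrinkage, while a nonlinear decoder
can suppress its output during holds and still reach full speed during
reaches, matching the true, heavy-tailed velocity distribution.

`nldbench` implements the complete offline comparison as a tested R package:

* a **synthetic session generator** — two-DOF random-target trials
  (minimum-jerk reaches, corrective submovements, holds) and a per-channel
  kinematics-to-SBP encoding (softplus tuning with threshold offsets,
  context shifts that move tuning while behavior stays fixed) with known
  ground truth;
* the **SBP feature chain** (anti-aliased decimation to 2 ksps, zero-phase
  300–1000 Hz bandpass, rectification, 50 ms binning) and 150 ms
  time-history windows;
* **trial-level data preparation**: failure removal, middle-600 trim,
  final-100 holdout, shuffled five-fold 400/100 splits, and the mixed/full
  multi-context training sets;
* **decoders** under one train/predict contract: ridge regression
  (λ = 0.001), a dual-state movement/posture decoder with an adaptive LDA
  state threshold, a temporally-convolved feedforward network (TCN) with
  batchnorm/dropout ablations, an LSTM, ReFIT-style velocity relabeling and
  fine-tuning, and triangular velocity redistribution — the networks,
  backpropagation and Adam implemented natively on BLAS;
* **metrics**: pooled MSE, top/bottom-decile speed-regime statistics,
  velocity-PMF KL divergence, median prediction deviation across decoder
  instances, and trial metrics (time-to-target, orbiting time/rate, Fitts
  throughput);
* **statistics**: paired and pooled two-sample t-tests, two-proportion
  z-test, and a nested two-way ANOVA (runs within days), all calibrated at
  alpha 0.01.

## A worked example

Train a linear and a nonlinear decoder on one synthetic session and compare
them on the held-out trials:

```r
library(nldbench)

em      <- generate_encoding_model(96, "saturating", seed = 100)
session <- generate_session(task_config(n_trials = 600, seed = 1), em,
                            c(normal = 600), seed = 1)
folds   <- prepare_session_folds(session, seed = 1)
ds      <- make_decoder_dataset(session)
train   <- folds$split$folds[[1]]$train

rr  <- train_velocity_decoder("rr",  session, train, dataset = ds)
tcn <- train_velocity_decoder("tcn", session, train, dataset = ds, seed = 1)

for (dec in list(rr, tcn)) {
  pv <- predict_velocity(dec, session, folds$holdout, dataset = ds)
  cat(sprintf("%-4s holdout MSE: %.4f (flex/s)^2\n", dec$kind,
              mse(pv$pred, pv$true)))
}
```

```
rr   holdout MSE: 0.0522 (flex/s)^2
tcn  holdout MSE: 0.0368 (flex/s)^2
```

The TCN's pooled holdout MSE lands about 20–30% below ridge on sessions like
this; its predicted-velocity histogram is also much closer to true hand
control (KL divergence 0.085 vs 0.354 nats against the hand-control PMF on
this session), because it holds near zero during postures and reaches higher
peak speeds — exactly the regime behavior the benchmark is designed to
expose.

## The analysis workflow

The paper-style studies are numbered drivers over the package functions;
each writes its tables under `results/`:

```sh
Rscript analysis/01_simulate_sessions.R      --seed 1   # session + behavior shape
Rscript analysis/02_prepare_folds.R          --seed 1   # protocol counts
Rscript analysis/03_decoder_comparison.R     --seed 1   # RR vs TCN vs LSTM
Rscript analysis/04_stability_ablation.R     --seed 1   # BN/DP ablations
Rscript analysis/05_context_generalization.R --seed 1   # context shifts
Rscript analysis/06_statistics.R             --seed 1   # calibration, DS threshold
```

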