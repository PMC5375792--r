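# ppghr — heart rate from wrist PPG under strong motion artifacts

Optical wrist sensors (photoplethysmography, PPG) carry a cardiac spectral
line at HR/60 Hz, but during running the arm's motion couples into the
optical path and can drown that line in artifacts that occupy the very same
0.5–3 Hz band. Because the artifact is spectrally aligned with the wrist's
accelerometer signal while the heartbeat is not, the two can be separated.
`ppghr` is for researchers and engineers working on wearable heart-rate
estimation who need a complete, testable reference pipeline for this
separation problem — including a synthetic treadmill-session generator so
every stage runs and is verified without any external recordings.

## The method

Per 8 s window (2 s shift, 25 Hz analysis rate, band-passed 0.4–4 Hz):

1. **Motion reference by PCA.** Standardize the three acceleration channels,
   eigen-decompose their correlation matrix (cyclic Jacobi), and take the
   first principal component's scores as the reference artifact series
   *a(l)*.
2. **Adaptive cancellation (LMS).** For each PPG channel *y(l)*, an
   order-25 tap-delay filter predicts the artifact from *a(l)* and outputs
   *e(l) = y(l) − w′ a⃗(l)*, updating *w ← w + μ e(l) a⃗(l)* with μ = 0.005,
   weights continuing across windows of a session.
3. **Joint sparse spectra (MMV / Regularized M-FOCUSS).** The two cleansed
   channels form *Y = Φ X + V* on a redundant M×N DFT dictionary
   (M = 200, N = 1024, Φ\[m,n\] = e^{j2πmn/N}); iteratively reweighted
   ridge-regularized minimum-norm steps (reweighting by row norms
   c\[i\]^{1−p/2}, p = 0.8, λ = 1e−10) recover a row-sparse X, and
   S\[i\] = |x̂ᵢ|² is the spectrum. The acceleration triplet is solved on the
   identical grid.
4. **Spectrum subtraction.** After unit-energy normalization over bins
   0–199, subtract the per-bin maximum of the three acceleration spectra
   from each PPG spectrum, clip at zero, and zero everything below 1/5 of
   the post-subtraction maximum.
5. **SVM peak tracking.** Candidate peaks (strict local maxima above
   0.7·max) are described by the coefficient ratio *C = coe/coe_max* and
   the distance to the previous estimate *S = |f − f_prev|*; a linear SVM
   labels them true/false. One true peak is taken directly; several resolve
   to the nearest; none triggers a ±0.02 Hz prediction step along the trend
   of the last ten estimates. Finally BPM = f × 60.

Agreement metrics (AAE, AAEP, Bland–Altman limits u ± 1.96σ, Pearson r) and
stratified 10-fold cross-validation of the peak classifier are built in.

## Worked example

Train the peak classifier on synthetic sessions, then estimate a 300 s
moderate-artifact treadmill session it has never seen:

```r
library(ppghr)
cfg    <- default_config()
corpus <- simulate_training_corpus(5, cfg, seed = 100)   # 5 x 150 s sessions
model  <- train_classifier(corpus[, c("C", "S")], corpus$label)
rec    <- simulate_session(sim_config(alpha = 1, seed = 42), cfg)
trace  <- estimate_session(rec, cfg, model)
evaluate_trace(trace$bpm_est, trace$bpm_true)
```

```
<eval_report>
  windows        147
  AAE            0.934 BPM
  AAEP           0.695 %
  Bland-Altman   u=0.187, sigma=3.097, LOA=[-5.883, 6.256] BPM
  Pearson r      0.9934
```

The trace itself records one row per window with the estimate, the ground
truth, and a provenance flag saying which rule produced the estimate:

```
> head(as.data.frame(trace), 3)
  window_index window_start_s  bpm_est bpm_true        flag
1            1              0 82.03125 80.66618 initialized
2            2              2 80.56641 80.99960       rule1
3            3              4 82.03125 81.33302       rule1
```

`rule1`/`rule2` mark windows decided by the classifier (123 and 14 of the
147 windows here), `predicted` marks windows bridged by the prediction
mechanism (9 here). The AAE of 0.93 BPM is below one grid bin
(25/1024 Hz × 60 ≈ 1.46 BPM); the wider Bland–Altman limits reflect a few
prediction-bridged windows during the fastest heart-rate ramps.

A thin command-line front end over the same functions is installed at
`inst/cli/ppghr.R` with `estimate`, `train`, `evaluate` and `simulate`
subcommands, reading the MATLAB-matrix dialect (6×T: ECG, 2×PPG, 3×accel at
125 Hz) and a CSV dialect (`ppg1,ppg2,accx,accy,accz` plus a `# fs=125`
line); ground truth is a companion per-window BPM vector.

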