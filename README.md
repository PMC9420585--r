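# pulseseg

Single-period segmentation of wrist (radial) pulse waveforms into systolic
and diastolic phases.

Time-domain analysis of the arterial pulse starts by cutting the signal
into beats and splitting each beat at the **dicrotic notch** — the trough
left by aortic valve closure — into a systolic phase (main-wave onset to
notch) and a diastolic phase (notch to the next onset). Classical
detectors handle this well when the notch is distinct, but fail on
"flat top" morphologies (string-like / fine pulse types) where the tidal
wave merges with the main wave and the notch nearly disappears. This
package implements, tests and compares two segmentation routes:

* a **bidirectional LSTM sequence labeller**: per-record z-scored samples
  feed two stacked BiLSTM layers (encoder and decoder) and a per-timestep
  softmax over three classes — background, systole, diastole — trained
  with Adam (initial learning rate 0.001) on per-sample cross-entropy;
* a **slope-sum-function (SSF) baseline**: the windowed slope sum
  `s_k = sum_{i=k-w+1..k} max(x_i - x_{i-1}, 0)` with an adaptive
  threshold for beat onsets plus a rebound-based local-minimum rule (with
  an inflection fallback) for the notch.

Around them sit the full pipeline stages:

* a **seeded simulator** generating the seven classical pulse
  morphologies (normal; slippery variants; flat-top string/fine variants)
  as three-Gaussian beats with exact onset/notch ground truth, heart-rate
  jitter, white noise, 50 Hz powerline pickup and sub-0.4 Hz respiratory
  drift — labelled pulse recordings are not publicly available, so the
  synthetic world is the test bench;
* **preprocessing**: zero-phase order-4 Butterworth low-pass at 20 Hz,
  then removal of baseline wander by zeroing the deepest approximation
  band (0-0.35 Hz) of a 10-level sym8 wavelet decomposition;
* **annotation handling**: parsing of LabelMe-dialect JSON rectangles and
  the pixel-to-sample mapping `S = round(P / W x L)` (image width 2264 px,
  record length 2160 samples at 720 Hz), plus stratified 8:1:1
  train/validation/test splitting;
* **evaluation**: boundary-tolerance accuracy (both phase boundaries
  within +/-50 ms) for systole, diastole and whole period, overall and per
  pulse type.

## Worked example

Generate a record, preprocess it, and segment it with the slope-sum
baseline:

```r
library(pulseseg)

r <- generate_record("slippery", seed = 7)     # 3 s at 720 Hz, with noise
rec <- preprocess(r$record)                    # smooth + de-drift
res <- ssf_segment(rec)
head(res$segments)
#>     record_id start  end phase
#> 1 slippery_s7   186  363     1
#> 2 slippery_s7   363  709     2
#> 3 slippery_s7   709  924     1
#> 4 slippery_s7   924 1307     2
#> 5 slippery_s7  1307 1532     1
#> 6 slippery_s7  1532 1945     2
```

Each row is a half-open sample interval (0-based); phase 1 is systole,
phase 2 diastole — three complete beats here, each split at the detected
notch. Scoring against the simulator's exact truth:

```r
v <- match_periods(res$segments, r$truths, tolerance_s = 0.05, fs = 720)
score(list(v), "slippery")
#> Segmentation report (+/- 0.05 s boundary tolerance, 3 periods)
#>   Systolic phase : 100.0%
#>   Diastolic phase: 100.0%
#>   Whole period   : 100.0%
```

All three beats of this record are recovered with both boundaries inside
the 50 ms tolerance. On flat-top types (`string`, `fine`, `fine_string`)
the same call shows the baseline failing where the notch is weak — the
regime the learned segmenter is built for.

The full experiment — 140 synthetic records in the standard composition,
stratified 8:1:1 split, BiLSTM training with early stopping, and a
head-to-head evaluation of both methods on the identical test split — is
one call:

```r
res <- run_experiment(experiment_config(scale = 0.1, seed = 1))
res$lstm_report; res$ssf_report
```

or from a shell:

```sh
Rscript inst/cli/pulseseg.R run-all --scale 0.1 --seed 1 --out run_out
```

The CLI also exposes the individual stages (`synth`, `preprocess`,
`convert-labels`, `ssf`, `train`, `predict`, `evaluate`).

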