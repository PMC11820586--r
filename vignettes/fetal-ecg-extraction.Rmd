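---
title: "Separating fetal from maternal ECG with a W-shaped recurrent-residual attention network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating fetal from maternal ECG with a W-shaped recurrent-residual attention network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A maternal abdominal ECG (maECG) is a mixture: a large maternal ECG (MECG),
a fetal ECG (FECG) an order of magnitude smaller with a narrower QRS
complex, and noise (baseline wander, muscle activity, powerline
interference). Fetal heart-rate and morphology assessment needs the fetal
component on its own, but fetal and maternal beats overlap in time and
frequency, so linear filtering cannot separate them. `r2wnet` treats the
separation as supervised signal-to-signal regression: a dual
encoder–decoder network reads one abdominal channel and reconstructs the
fetal and maternal components simultaneously.

## The synthetic data generator

Real annotated abdominal recordings are scarce, so the package ships a
generator that emulates the structure of the synthetic fetal-ECG corpora
used in this literature and produces ground truth for every record:

* **Beat model.** Each heartbeat is a sum of five Gaussians (P, Q, R, S, T)
  whose centres, widths and amplitudes are expressed as fractions of the RR
  interval (`beat_morphology()`). The fetal morphology has a roughly
  half-width QRS and smaller P/T waves than the maternal one; RR intervals
  carry multiplicative Gaussian jitter (3% by default).
* **Mixing.** `mix_abdominal()` rescales the fetal component so its R-peak
  amplitude is a fixed fraction of the maternal one
  (`fm_amplitude_ratio`, default 0.25 — published descriptions of the fetal
  QRS give no numeric ratio, so it is an explicit parameter), then adds composite noise: white + 0.3 Hz baseline wander +
  50 Hz powerline in fixed power shares (0.60/0.25/0.15). Noise power is
  calibrated against the *fetal* component: `noise_snr_db` is
  `10·log10(P_fetal/P_noise)`, with the five standard study levels 0, 3, 6,
  9, 12 dB. Calibration is exact by construction, and the injected noise
  vector is stored so `mixture − maternal − fetal = noise` holds to machine
  precision.
* **Events.** `apply_scenario_events()` reproduces the usual scenario
  taxonomy: C0 noise only; C1 band-limited amplitude modulation of the
  fetal component (fetal movement); C2 a heart-rate ramp implemented as a
  zero-phase time warp of the component with annotations mapped through
  the inverse warp; C3 a slow EMG-like burst (uterine contraction) added
  to the noise; C4 ectopic beats with inverted polarity and doubled QRS
  width inserted mid-diastole into both components; C5 a second fetal
  train at a distinct rate (twin stub). After any event the stored noise
  is rescaled so the requested fetal-referenced SNR still holds.

What the generator does *not* model: electrode geometry and projection of
a cardiac dipole onto multiple leads, realistic coloured EMG spectra,
amplitude drift of real electrodes, or fetal movement re-orienting the
fetal axis. Tests passing on this generator therefore show that the
architecture, training loop and scoring work as specified — not that the
trained desk-scale weights would transfer to clinical recordings.

## Preprocessing

The conditioning chain follows the standard recipe for this family of
models: band-pass 3–100 Hz, resample to 250 Hz, cut into 1024-sample
windows overlapped by 24 samples at both ends (hop 976), and Z-score each
window independently.

Numerical choices:

* The band-pass is Butterworth (high-pass order 4 near 3 Hz, low-pass
  order 6 near 100 Hz) applied forward–backward, because zero phase
  preserves R-peak timing on which the 31.25 ms detection tolerance
  depends. Since two passes double the attenuation, the design corners are
  pre-warped so the *combined* magnitude is −3 dB exactly at 3 and 100 Hz;
  the passband is flat within ~1 dB from 5 to 90 Hz. 50 Hz interference is
  inside the passband and deliberately left for the network.
* Resampling is zero-phase: a forward–backward Butterworth anti-alias
  filter followed by exact integer decimation (spline interpolation for
  non-integer ratios). An off-the-shelf polyphase resampler was rejected
  because its uncompensated decimation delay (three samples at 2:1) is of
  the same order as the detection tolerance.
* Z-scoring is per window, after segmentation, with the standard deviation
  floored at 1e-8 so flat windows map to zeros rather than NaNs.
* Inversion (`stitch_segments()`) uses overlap-discard: each window
  contributes only its trusted centre; the 24-sample margins exist to
  absorb edge effects, so they are dropped rather than cross-faded. The
  round trip is exactly lossless, and when tail anchoring makes the final
  window overlap more, the later window owns the contested samples.
* Training targets are expressed in the mixture window's normalised units:
  the fetal target is divided by the window's scale only (a zero-baseline
  component), while the maternal target is shifted and scaled like the
  mixture itself. Predictions invert the same transforms.

## The network

Two five-level attention R2U-Nets share one input window and form a "W":
the maternal branch (kernel size 5) reconstructs the MECG, the fetal
branch (kernel size 3) the FECG. Channel widths double per level —
64/128/256/512/1024 at full width, scaled by `width_multiplier` for
desk-scale work.

* **Recurrent-residual convolution (RRC) blocks.** Each block computes
  `z = conv_f(x)` once, unrolls `y_0 = act(z)`,
  `y_t = act(z + conv_r(y_{t−1}))` for `t = 1..T` (default `T = 2`), and
  returns `x' + y_T`, where `x'` is the input or a 1×1 projection when
  channel counts differ (the residual form assumes equal shapes and is
  silent about the first block of a level). With zero weights the block is
  the identity. The `forward`, `residual` and `recurrent` variants used in
  the block-type ablation drop the recurrence and/or the residual.
* **Attention gates.** Skip connections are replaced by additive attention:
  `α = sigmoid(Φ(relu(W_u·u + W_g·g + b_g)) + b_Φ)` with the decoder-side
  gating signal `g` already upsampled to the skip's length; the gated skip
  is `α ⊙ u` with `α ∈ [0,1]` broadcast over channels. The gate's internal
  width is half the gated feature width, the convention of the attention
  U-Net lineage.
* **Cross-branch fusion.** At every encoder level the fetal features are
  fused as `tanh(fetal − maternal)` — subtraction removes what the
  maternal encoder explains, tanh bounds the result to (−1,1). Fusing at
  *all* levels (not only the bottleneck) is the default: the subtraction
  belongs to the encoder stage, and applying it at every resolution lets
  the decoder gate maternal-free features throughout; `fusion_levels`
  exposes the bottleneck-only alternative. Whether fused maps should also feed the fetal encoder's descent
  was genuinely open; both wirings are implemented
  (`fuse_feedforward`), and the default feeds fusion only to the decoder
  skips and bottleneck, which keeps the two encoders' feature streams
  independent and trains more stably in practice.
* **Decoder and heads.** Upsampling is linear interpolation followed by a
  convolution rather than transposed convolution (avoids 1D checkerboard
  artefacts). Activations are Leaky ReLU by default (`relu` available to
  match the block equations literally). Output heads are linear 1×1
  convolutions: Z-scored targets exceed (−1,1), so a tanh output head
  would clip R peaks; tanh appears only inside the fusion. No batch
  normalisation anywhere.

Everything is implemented with explicit forward/backward passes over
channels×length matrices, with the convolutions as im2col+GEMM kernels in
C++ (RcppArmadillo). The gradients are exact; the test suite checks them
against central finite differences and checks the blocks and gates against
scalar-loop oracles.

## Training

Both branches are trained jointly by `train_r2wnet()` (or the `r2wnet()`
fitting front end): loss `w_f·MAE(fetal) + w_m·MAE(maternal)` with equal
weights, Adam, gradient-norm clipping at 5. The reference configuration
(`preset = "reference"`) is learning rate 1e-4, batch size 32, 30 epochs
at full width; the desk preset is learning rate 1e-3, batch size 8, 8 epochs
at width 1/8, sized so a full study run (about 186 training windows from
seven 120 s records) trains in roughly two minutes on one CPU core.
Records are split into training and validation *by record* — never by
window, because adjacent windows overlap and would leak. The best
validation epoch's weights are kept. All randomness (initialisation,
shuffling, the generator) flows through explicit integer seeds, so runs
are bit-reproducible.

On synthetic data the maternal branch is supervised by the clean maternal
component. For real fine-tuning data without a maternal reference the
sensible target is the abdominal mixture itself (fetal energy treated as
residual); this package's scope is the synthetic path, so that fallback is
documented but training requires both truth channels.

The ablation harness (`ablate()`) re-trains the desk model along one axis
at a time — loss (MAE vs MSE), depth (4/5/6), block type
(forward/residual/recurrent/RRC) — with a shared seed and identical
splits, and reports one comparable metric row per variant. The harness
asserts nothing about which variant wins: orderings observed at desk scale
on synthetic data do not carry evidential weight for full-scale training.

## Evaluation

* **Signal quality** (`signal_metrics()`): MSE, MAE and
  `SNR = 10·log10(Σy² / Σ(y−ŷ)²)` against the identically preprocessed
  fetal truth. `evaluate_record()` also reports the *mixture's* SNR
  against the same truth (`snr_in_db`), so the network's improvement is
  `snr_db − snr_in_db`.
* **Fetal QRS detection**: a classic Pan–Tompkins chain (band-pass,
  derivative, squaring, moving-window integration, adaptive dual
  thresholds with refractory period and search-back). The fetal profile
  uses an 8–25 Hz pass band, 80 ms integration window and 200 ms
  refractory period — chosen for the narrower fetal QRS and rates up to
  240 bpm; the maternal profile uses 5–15 Hz / 150 ms / 250 ms.
* **Matching and scores**: predicted peaks match true peaks one-to-one,
  greedily by time difference within 31.25 ms, ties toward the earlier
  prediction. For physiological peak trains (true peaks farther apart than
  twice the tolerance — guaranteed by refractoriness) this greedy rule is
  provably optimal, and the tests confirm agreement with an exhaustive
  optimal matcher. SE, PPV and F1 are reported in percent. The F1 is the
  harmonic mean of SE and PPV; the count-ratio variant `TP/(TP+FP+FN)`
  sometimes printed as an "F1" formula in this literature is the Jaccard
  index of the two peak sets and is exposed separately as
  `f1_jaccard_pct`. Published per-record tables in this area print
  `mean ± std` with the population (n) denominator;
  `aggregate_reports()` follows that convention and also offers pooled
  counting.

## Problem sizes and what the checks mean

The package's own acceptance workflow (`scripts/acceptance.R` and the
matching tests) trains the width-1/8 model on seven 120 s synthetic
records of scenario C0 at 6 dB (≈186 windows, 8 epochs) and evaluates on
five held-out 60 s records — sizes chosen so the whole workflow runs in a
few minutes on one CPU core while still leaving the untrained model far
from the target. Under those conditions the trained model must raise the
fetal SNR well above the mixture's and support fetal QRS detection at the
31.25 ms tolerance; the repeated-seed test accepts two of three seeds to
absorb training stochasticity. These are functional checks of the
implementation at desk scale, not reproductions of full-scale published
performance, which required the real PhysioNet databases and GPU-scale
training.

## Known limitations

* Single-channel input only; no multi-lead joint modelling.
* The generator's simplifications listed above; in particular, noise is
  calibrated against fetal power, so mixture-level SNRs are much lower
  than the nominal level.
* Training at full width (width_multiplier 1) is supported but not
  practical on a single CPU core.
* The WFDB reader covers formats 16 and 212 with single-segment,
  single-file records — enough for the usual abdominal-ECG databases, not
  a general WFDB implementation.
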