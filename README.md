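# r2wnet — fetal ECG extraction with a W-shaped recurrent-residual attention network

Non-invasive fetal monitoring records the maternal abdominal ECG (maECG):
a mixture of a large maternal ECG (MECG), a much smaller fetal ECG (FECG)
with a narrower QRS complex, and noise. Clinicians need the fetal
component on its own — for fetal heart rate and beat morphology — but the
two ECGs overlap in time and frequency, so no linear filter separates
them. `r2wnet` is an R implementation of a supervised separation approach
for people working on fetal-ECG signal processing: it learns the mapping
from a single abdominal channel to both underlying components.

## The model

The separator is a "W"-shaped network: two five-level attention R2U-Nets
that share one input window. The maternal branch (convolution kernel 5)
reconstructs the MECG; the fetal branch (kernel 3) reconstructs the FECG
after cross-branch feature subtraction. Its building blocks:

* **Recurrent-residual convolution (RRC) blocks** — with `z = conv_f(x)`
  computed once, the block unrolls

      y_0 = act(z),   y_t = act(z + conv_r(y_{t-1})),  t = 1..T  (T = 2)

  and returns `x' + y_T` (residual; `x'` is a 1×1 projection when channel
  counts differ).
* **Additive attention gates** replace skip connections:

      α = σ₂( Φ( σ₁(W_u·u + W_g·g + b_g) ) + b_Φ ),   output α ⊙ u

  with `u` the encoder features, `g` the decoder-side gating signal,
  `σ₁ = ReLU`, `σ₂ = sigmoid`, so `α ∈ [0,1]` per sample position.
* **Cross-branch fusion** — at each encoder level the fetal branch keeps
  `tanh(fetal − maternal)`, removing what the maternal encoder explains.

Training minimises `MAE(fetal) + MAE(maternal)` with Adam (reference
setting: learning rate 1e-4, batch 32, 30 epochs; a desk preset trains a
width-1/8 model on one CPU core in about two minutes). Extraction quality
is scored with MSE/MAE and `SNR = 10·log10(Σy²/Σ(y−ŷ)²)`; fetal QRS
detection runs Pan–Tompkins on the reconstruction and matches peaks to the
annotations one-to-one within 31.25 ms, reporting SE, PPV and
harmonic-mean F1 in percent.

Everything runs on synthetic data from the built-in generator
(Gaussian-PQRST beats, calibrated noise, the standard C0–C5 event
scenarios, ground-truth components and R-peak annotations), and the I/O
layer reads PhysioNet-style WFDB records if you have real data.

## Worked example

```r
library(r2wnet)

# six 60-second training recordings + one held-out test recording
specs   <- lapply(1:7, function(i)
  scenario_spec("C0", noise_snr_db = 6, duration_s = 60, seed = i))
records <- lapply(specs, simulate_record)
records[[1]]
#> <ecg_record> 15000 samples x 3 channel(s) @ 250 Hz (60.0 s)
#>   roles: abdominal_mixture, maternal_truth, fetal_truth
#>   R peaks: fetal 140, maternal 80
#>   meta: scenario=C0, noise_snr_db=6, fm_amplitude_ratio=0.25, seed=1

fit <- r2wnet(records[1:6],
              config   = r2wnet_config(width_multiplier = 1/8),
              training = train_config(preset = "desk", epochs = 6, seed = 1),
              seed = 1)
fit
#> <r2wnet> fitted W-shaped fetal/maternal ECG separator
#> <r2wnet_config>
#>   depth 5, channels 8/16/32/64/128
#>   kernels maternal 5 / fetal 3, recurrence T = 2, rrc blocks
#>   fusion at levels 1,2,3,4,5, attention on, activation leaky_relu
#>   534,954 parameters, trained on 6 record(s), 6 epoch(s)
#>   final train loss 0.18897, best validation loss 0.18608 (epoch 6)

evaluate_record(records[[7]], fit)
#> <metrics_report>
#>   MSE 0.0007  MAE 0.0133  SNR 2.82 dB (mixture -12.96 dB)
#>   FQRS: SE 88.57%  PPV 100.00%  F1 93.94%  (140 true beats)
```

Reading the report: in the raw mixture the fetal signal sits at
−12.96 dB relative to everything else (maternal ECG + noise); after six
epochs the reconstruction reaches +2.82 dB — a ~16 dB improvement — and
Pan–Tompkins on the reconstruction finds 100% of its detections correct
(PPV) while recovering 88.6% of the 140 true fetal beats, i.e. F1 93.9%.
Longer training (the desk preset's default 8 epochs on 120 s records)
pushes SNR and F1 higher; `plot(fit)` shows the loss curves and
`plot(fit, records[[7]])` overlays the reconstruction on the fetal truth.

The same pipeline is scriptable from a shell via the thin CLI:

```sh
Rscript inst/cli/r2wnet-cli.R simulate --n 4 --scenario C0 --noise 6 --seed 1 --out data/
Rscript inst/cli/r2wnet-cli.R train    --data data/ --preset desk --out ckpt/
Rscript inst/cli/r2wnet-cli.R evaluate --checkpoint ckpt/ --data data/ --out report.tsv
```

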