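# tcvaegan

Label-conditioned generation of multichannel EEG segments with a
**transformer conditional VAE-GAN**, plus the spectral evaluation suite and
downstream-classifier protocols needed to judge such a generator.

## Who this is for

Researchers in affective computing / EEG-based emotion recognition who need
(i) class-conditional synthetic EEG windows for data augmentation, and
(ii) a principled, multi-axis way to measure how close generated signals
come to real ones — in time-domain morphology, spectral envelope,
feature-space distribution and label-relevant content. Everything runs on
one CPU; a built-in synthetic cohort generator with EEG-like structure
(1/f background, class-dependent band power, cross-channel mixing) makes
the whole pipeline testable without any external recordings.

## The model

Windows `x ∈ R^{B×T×C}` (T = 400 samples at 200 Hz, C channels) with labels
`y ∈ {0,1,2}` pass through:

- a **transformer encoder** (2 layers, 4 heads, 256-dim embedding), mean-
  pooled over time to `z_input`;
- a **label-conditioned latent head**: `[z_input, e_y] → (μ, log σ²) ∈ R^128`,
  sampled by the reparameterization trick `z = μ + σ ⊙ ε`, `σ = exp(0.5·log σ²)`;
- a **transformer conditional decoder**: `[z, y_onehot]` replicated T times
  as memory, target initialized as zeros + learnable positional encodings,
  projected back to `x̂ ∈ R^{B×T×C}`;
- a **1-D convolutional discriminator** (kernels 5/5/3, stride 2, LeakyReLU)
  emitting one logit per window.

The generator objective combines six terms — reconstruction MSE, latent KL
`−½Σ(1 + log σ² − μ² − σ²)`, non-saturating adversarial `E[−log D(x̂)]`,
Pearson correlation complement `1 − corr(x̂, x)`, temporal smoothness
`1/(T−1) Σ‖x̂_t − x̂_{t+1}‖²`, and Welch-PSD MSE — with **batch-wise dynamic
weights**: z-score the six losses, softmax, clip to `[0.1, 0.4]`,
renormalize to sum one (not trainable, no gradient). With six terms the
saturating bounds are `0.4/0.9 = 0.444…` and `0.1/0.9 = 0.111…`. Training
alternates one discriminator update with two generator updates (Adam,
lr 1e-3 / 1e-4, batch 64, 100 epochs by default).

Evaluation (`evaluate_generation()`): channel-wise paired Pearson and
Spearman correlations, spectral KL divergence, normalized PSD-MSE and
spectral earth mover's distance on band-limited (0.5–45 Hz) Welch spectra,
and a Fréchet distance on 12-dimensional spectral–temporal window
embeddings (log band powers, spectral centroid/entropy, RMS, AR(4)
Yule-Walker coefficients). Downstream: trial-level stratified 80/10/10
splits, a frozen real-trained CNN scoring generated windows (congruence),
and class-balanced augmentation with real-only validation/test.

Since no autodiff framework is involved, the networks and all gradients are
implemented in the package itself — a small reverse-mode tape over R arrays
with compiled (RcppArmadillo) attention and convolution kernels, every
adjoint verified against finite differences in the tests.

## Worked example

```r
library(tcvaegan)

# 1. Simulate a small emotion-labelled cohort (18 trials, 8 channels, 200 Hz)
cfg <- synthetic_cohort_config(n_trials = 18, trial_len = 1000,
                               n_channels = 8, fs = 200, seed = 1)
trials  <- generate_cohort(cfg)
windows <- segment_cohort(trials, win_len = 400, hop = 200)
print(windows)
#> <eeg_window_batch> 72 windows of [400 x 8] @ 200 Hz; labels: 0:24 1:24 2:24

# 2. Train a narrow conditional VAE-GAN for 10 epochs
mcfg <- model_config(T = 400, C = 8, d_embed = 16, n_heads = 2, n_layers = 1,
                     d_ff = 64, latent_dim = 8, dropout = 0,
                     disc_channels = c(8, 16, 16), disc_fc = 32)
model <- fit_tcvaegan(windows, mcfg,
                      train_config(batch_size = 16, epochs = 10, seed = 1))
attr(model, "update_counts")
#>   D   G
#>  50 100
log <- attr(model, "training_log")
round(log[c(1, 10), c("epoch", "L_recon", "L_corr", "L_spec", "d_loss", "L_gen")], 3)
#>    epoch L_recon L_corr L_spec d_loss L_gen
#> 1      1   2.228  1.003  0.001  1.645 4.334
#> 10    10   1.067  0.998  0.001  1.212 0.767

# 3. Paired evaluation of reconstructions against the real windows
recon  <- sample_windows(model, mode = "reconstruction", x = windows, seed = 1)
report <- evaluate_generation(windows, recon, paired = TRUE)
print(report)
#> <metric_report> 72 real vs 72 generated windows (paired)
#>   pearson    0.0030 +/- 0.0091
#>   spearman   0.0028 +/- 0.0100
#>   kl         0.6112 +/- 0.1256
#>   fid       34.4419 +/- 0.9574
#>   psd_mse    0.0024 +/- 0.0013
#>   emd        6.4793 +/- 2.2687
```

Reading the numbers: 50 discriminator and 100 generator updates confirm the
1:2 schedule over 5 batches × 10 epochs; the total generator loss falls
from 4.33 to 0.77 as reconstruction error drops. A smoke run pulls the
generated spectra toward the real ones — the spectral divergences (KL,
PSD-MSE, EMD in Hz) sit below an untrained model's and keep falling with
more epochs — while paired time-domain correlation is still near zero —
faithful waveform reconstruction needs the full-width model and many more
epochs than a smoke run (see the methods vignette for what each scale can
and cannot show). For class-balanced augmentation and distribution-level
scores, draw from the prior instead:

```r
gen <- sample_windows(model, labels = rep(0:2, 20), mode = "prior", seed = 2)
```

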