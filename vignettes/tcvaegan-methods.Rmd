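---
title: "Conditional transformer VAE-GAN for EEG synthesis: model, objectives and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conditional transformer VAE-GAN for EEG synthesis: model, objectives and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Emotion-labelled EEG is expensive to collect: film-elicitation protocols,
multi-channel amplifiers, compliant participants and careful artifact
cleaning yield small corpora, which limits deep classifiers trained on them.
A label-conditioned generative model that produces realistic multichannel
EEG segments addresses this twice over — it enables class-balanced data
augmentation, and the quality of its samples is itself a probe of what the
model has learned about the signal's structure. EEG is a hard target for
generative modeling: it is non-stationary, mixes rhythms at several time
scales (the classical delta/theta/alpha/beta/gamma bands over a 1/f
background), and couples channels strongly.

`tcvaegan` implements a conditional variational autoencoder-GAN hybrid with
transformer sequence blocks for this setting, together with the full
spectral evaluation suite and downstream-classifier protocols needed to
judge such a generator, and a synthetic cohort generator that reproduces
the statistical structure the pipeline assumes, so that everything is
testable end to end on one CPU without any external recordings.

# Data model and preprocessing

The unit of data is a *trial*: a `[time x channels]` matrix at a nominal
200 Hz with one categorical emotion label (3 classes by default). Trials
are assumed to be already down-sampled, band-limited to 0-45 Hz and
artifact-cleaned; the loaders validate sampling-rate metadata but do not
filter. Preprocessing follows two steps, in this order:

1. **Per-channel z-scoring at trial level** (`zscore_per_channel()`).
   Windows are *not* re-normalized afterwards; window-level statistics
   therefore retain within-trial amplitude dynamics. A constant channel is
   an error by default (silent zeros would hide a dead electrode), with an
   opt-in zeroing policy.
2. **Sliding-window segmentation** (`segment_windows()`): length 400
   samples, hop 200 (2.0 s windows, 50% overlap), count
   `floor((N - 400)/200) + 1`; every window inherits its parent trial's
   label. A trial shorter than one window yields an empty batch with a
   warning rather than an error, so ragged cohorts survive batch loading.

On disk, cohorts are exchanged as one EDF file per trial plus a
tab-separated `trials.tsv` manifest (`file`, `label`, `subject`,
`session`); the trial label travels in the EDF recording-identifier field.
The EDF reader/writer implemented here is deliberately minimal (16-bit
samples, one data record per trial) — enough for round-trips within the
format's quantization, not a general acquisition-format library. Because
published trial matrices appear in both orientations, the loader takes an
explicit `orientation` flag instead of guessing from the shape.

# The generator

Four blocks, all implemented as explicit forward computations with
hand-derived adjoints on a small reverse-mode tape (see *Numerics* below):

**Transformer encoder.** Windows `[B, T, C]` are projected channel-wise to
`d_embed` (default 256), passed through `n_layers = 2` post-norm encoder
layers (multi-head self-attention with `n_heads = 4`, position-wise
feed-forward of width `4 * d_embed`, residual connections and layer norm),
and mean-pooled over time to a fixed-length representation `z_input`
`[B, d_embed]`.

**Label-conditioned latent head.** The label `y` in `{0, 1, 2}` is mapped
by a learned fully connected embedding to `e_y` of dimension `d_embed`;
`[z_input, e_y]` feeds two *independent* linear heads producing the
posterior mean and log-variance, each of dimension `k = 128`. Sampling uses
the reparameterization `z = mu + exp(0.5 * logvar) * eps`, `eps ~ N(0, I)`,
with `logvar` clamped to `[-10, 10]` before exponentiation purely as an
overflow guard (inactive in the operating range).

**Conditional decoder.** `[z, y_onehot]` is mapped to `d_embed` and
replicated `T` times as the decoder *memory*; the target sequence is
initialized as zeros plus a learnable positional-encoding matrix
`P [T, d_embed]`. Two decoder layers (self-attention, source-target
attention over the memory, feed-forward) and a final linear map to `C`
produce `x_hat [B, T, C]`. Decoding is one parallel pass with full
self-attention — the training-time computation — rather than autoregressive
generation; nothing in the model is trained with a causal mask, so a
step-by-step pass would compute the same function at higher cost.

**Discriminator.** Input transposed to `[B, C, T]`, three 1-D convolutions
with kernel sizes 5, 5, 3, all stride 2 and LeakyReLU (slope 0.2), then
flatten and two fully connected layers to a single raw logit per window.
"Same"-style zero padding is applied *before* each stride-2 step, so the
temporal length follows `ceil(T/2)` per layer (400 -> 200 -> 100 -> 50) and
the flatten dimension is computed from the configured `T`, never assumed
(zero-padding cannot preserve the temporal dimension under stride 2, so
the stride determines the lengths). The discriminator
emits logits rather than probabilities; the adversarial losses apply the
sigmoid internally through numerically stable softplus forms.

Two conditioning paths coexist deliberately: the *encoder side* uses the
learned embedding `e_y` (a richer, trainable representation for inference),
the *decoder side* the raw one-hot (an unambiguous class indicator for
generation).

# The six-term objective and dynamic weighting

The generator minimizes a weighted sum of six terms, each a batch mean:

| term | definition | role |
|---|---|---|
| `recon` | mean squared error between `x_hat` and `x` | time-domain amplitude |
| `kl` | `-0.5 * sum(1 + logvar - mu^2 - exp(logvar))`, batch-averaged | latent regularization |
| `adv` | non-saturating `E[-log D(x_hat)]` on logits | realism |
| `corr` | `1 -` mean per-sample, per-channel Pearson correlation | waveform morphology |
| `smooth` | `1/(T-1) * sum_t \|\|x_t - x_{t+1}\|\|^2`, batch-averaged | temporal smoothness |
| `spec` | MSE between Welch PSDs of `x_hat` and `x` | spectral envelope |

The weights are recomputed every batch: the six scalar losses are z-scored
(epsilon `1e-8` on the SD), softmaxed, clipped to `[0.1, 0.4]` and
renormalized to sum to one, all outside gradient flow; the weights are not
trainable. With six terms, a single dominant loss saturates at weight
`0.4/(0.4 + 5*0.1) = 0.444...` while the rest sit at `0.1/0.9 = 0.111...`.
One subtlety worth recording: those two numbers bound the *single-dominant*
configuration, not every input — when two softmax weights hit the 0.4 clip
the renormalized minimum is `0.1/1.2 ≈ 0.083`. The property tests assert
sum-to-one and the attainable range; `scripts/acceptance.R` recomputes the
saturating closed forms.

Loss-specific design choices:

- The Pearson term reduces over samples *then* channels; a zero-variance
  channel series contributes correlation 0 with a warning (penalizing a
  flat generation instead of crashing mid-training).
- The training-time Welch settings are 1.0 s Hann segments with 50%
  overlap over the full band up to `fs/2` (three averaged segments per
  400-sample window; capped at the window length for shorter windows). The
  evaluation metrics use the stricter 2.0 s Hamming / `nfft = 1024` /
  0.5-45 Hz settings; the two are deliberately separate because the latter
  are tied to evaluation.
- The discriminator loss is plain binary cross-entropy with targets 1
  (real) and 0 (fake); no label smoothing.

# Training schedule

Adam for both networks — generator `lr = 1e-3`, discriminator `lr = 1e-4`,
betas `(0.9, 0.999)` — batch size 64, 100 epochs, no learning-rate
schedule. Each iteration updates the discriminator once on real windows
versus freshly generated reconstructions (detached), then the generator
twice; update counts are exact by construction and asserted in the tests.
Adversarial training uses the *reconstruction* path (encode real windows,
sample the posterior, decode), which also feeds all six losses in a single
forward pass. For generation after training, `sample_windows()` offers two
modes: `reconstruction` returns `x_hat` paired index-to-index with its
input (the mode the paired Pearson/Spearman metrics require) and `prior`
draws `z ~ N(0, I)` and decodes with requested labels (the mode used for
distributional metrics and class-balanced augmentation). All randomness —
shuffling, posterior draws, dropout — derives from the single training
seed, so identical configurations reproduce identical loss trajectories.

Ablation switches reproduce the removal-style variants, each altering
exactly one component (asserted by parameter-diff tests): `no_cvae`
(deterministic latent = posterior mean, KL dropped), `no_gan` (no
discriminator, adversarial term dropped, weighting over the remaining
five), `no_label` (label embedding and one-hot zeroed and frozen),
`no_pos` (positional matrix zeroed and frozen), `no_pearson` (correlation
term dropped), `no_transformer` (encoder reduced to the channel projection
plus pooling), `cnn_encoder` (attention replaced by a stride-2 convolution
stack with global average pooling).

# Evaluation suite

All metrics are reported per channel with mean ± SD aggregates
(`evaluate_generation()`):

- **Pearson / Spearman** between paired real and generated windows,
  computed per window and channel along time, then averaged over windows.
  Spearman uses average ranks; without ties it equals the classical
  `1 - 6 sum(d^2) / (n(n^2-1))` formula, with ties it is Pearson on ranks.
- **Spectral KL divergence**: Welch PSDs (2.0 s Hamming, 50% overlap,
  `nfft = 1024`), band-limited to 0.5-45 Hz, normalized to sum to one;
  `sum(P log(P/Q))` in natural log with the real spectrum as `P` and a
  `1e-12` floor on `Q`. The direction follows the convention that the real
  signal is the reference.
- **PSD-MSE**: the same band-limited PSDs, L1-normalized over the band to
  probability-like envelopes, compared by discrete MSE on the Welch grid —
  insensitive to amplitude scale and phase by construction.
- **Spectral EMD**: PSDs normalized to densities over frequency, CDFs
  built, and the area between them integrated over 0.5-45 Hz; reported in
  Hz. The densities are piecewise linear on the Welch grid, so their CDFs
  are piecewise quadratic; the grid is refined 1024-fold before the
  trapezoidal rule, otherwise the integral loses accuracy wherever the CDF
  difference changes sign inside a bin (the tests hold it to a dense-grid
  oracle at 1e-6).
- **Frechet distance (FID)** on spectral-temporal embeddings: per channel,
  0.30 s windows with 0.15 s hop; per window a 12-dimensional feature
  vector (five log band-energy integrals, spectral centroid and entropy of
  the band-normalized periodogram, time-domain RMS, and AR(4) coefficients
  via Yule-Walker). Real and generated features are pooled and z-normalized
  feature-wise, split, summarized by means and covariances (symmetrized,
  diagonally loaded by `1e-6 *` mean diagonal), and compared by
  `||mu1 - mu2||^2 + Tr(C1 + C2 - 2 (C1 C2)^{1/2})`. The matrix square
  root is computed entirely by SVD — `sqrt(C1)` from the SVD of `C1`, then
  the SVD of the symmetrized product `sqrt(C1) C2 sqrt(C1)` — which equals
  `sqrtm(C1 C2)` in trace for SPD inputs; a direct `svd(C1 %*% C2)` is
  *not* a square root of a non-normal product, so the symmetrized route is
  used and verified against an eigendecomposition oracle. AR(4) on 60
  samples is noisy but captures short-range temporal dependence cheaply;
  no order fallback is applied. The Yule-Walker solve is a direct Toeplitz solve on biased
  autocovariances of the demeaned window.
- Because one value per channel is reported, the spectral metrics and the
  FID features operate on per-channel series formed by concatenating all
  windows of each side; the paired correlations remain per-window.

# Downstream protocols

A small reference CNN (three stride-2 convolutions mirroring the
discriminator's footprint, global average pooling, linear head) is the
probe classifier; it is deliberately small, fast and reproducible, since
its job is to probe label-relevant structure, not to maximize accuracy. Splits are *trial-level*, stratified by label,
80/10/10 with at least one trial per class per partition; all windows
inherit their parent trial's split, so no window of a held-out trial can
reach training (audited over random plans in the tests). The classifier is
trained on real training windows only, its best-validation-epoch weights
are frozen, and:

- **Congruence** scores generated windows against their conditioning
  labels with the frozen classifier. Scoring identical real test windows
  reproduces the real-only scores exactly; label-shuffled windows collapse
  to chance.
- **Augmentation** retrains the classifier with identical hyperparameters
  on real training windows plus class-balanced prior-mode generated
  windows (default ratio 1:1, exposed), evaluating on the untouched
  real-only test split.

Accuracy, precision, recall and F1 are macro-averaged over the three
classes (chosen for class symmetry; empty denominators contribute 0), and
AUC is one-vs-rest macro computed from the Mann-Whitney rank statistic;
tests pin these against confusion-matrix and `pROC` oracles. Where a
study would average over subjects, the synthetic harness substitutes seeds
and says so in its outputs.

# The synthetic cohort generator

`generate_trial()` builds each channel source as a sum of five
band-limited stochastic oscillators — white noise filtered by a zero-phase
4th-order Butterworth band-pass into delta (0.5-4), theta (4-8), alpha
(8-13), beta (13-30) and gamma (30-45) Hz, each rescaled to SD
`exp(0.5 * band_weights[band])` for the trial's class — over a `1/f^a`
background (default exponent 1.0, SD `noise_sd = 0.5`, low-passed above
45 Hz). Filtered noise rather than sinusoids yields non-stationary,
stochastic rhythms with realistic bandwidth. Sources are mixed across
channels by a fixed per-cohort matrix `(1 - m) I + m Q` with `Q` random
orthogonal and `m = channel_mixing = 0.5`, inducing cross-channel
correlation without pretending to be a head model; each channel is then
z-scored. The default class profiles differ chiefly in the alpha/beta
balance (alpha-dominant "neutral", beta-raised "positive", low-alpha
"negative"), an effect size around one log unit of band power — strong
enough that the reference classifier separates classes well above chance
on a few dozen trials, and analytically checkable: because mixing
preserves expected band shares and z-scoring fixes total power, the
expected band share is `exp(w_band) / (sum(exp(w)) + noise_sd^2)`, which
the tests verify against Welch estimates over 100 trials.

Every trial draws from its own stream derived from
`(cohort seed, trial index, label)`, so single trials are bitwise
reproducible in isolation. Class counts in a cohort differ by at most one,
with remainders assigned to lower class indices.

What the generator does *not* emulate: volume conduction and electrode
geometry, ocular/muscle artifacts, inter-subject variability, and
long-range non-stationarity beyond what band-filtered noise provides.
Tests passing on this data demonstrate the pipeline's correctness and the
direction of its training signal — not clinical-grade realism, and results
on real recordings will differ.

# Numerics

No automatic-differentiation framework is used: the package carries a
small reverse-mode tape (`R/autograd.R`) over plain R arrays, with the two
hot kernels — multi-head scaled-dot-product attention and strided 1-D
convolution via im2col — in compiled code (RcppArmadillo). Attention
scores are held transposed so softmax reductions run down columns. Every
op's adjoint, including the Welch-PSD loss gradient (propagated through
the windowed segment FFTs, with mean-detrending handled as a projection)
and the Pearson-loss gradient (with its centering projection), is verified
against central finite differences in the test suite. Parameters
initialize Xavier-uniform, each from its own seeded stream keyed by
parameter name, which is why ablation variants share every common
parameter bit-for-bit with the baseline.

Problem sizes used by the packaged tests and examples were chosen to keep
a full run comfortable on a single desktop core: the bundled smoke setup
is 18 trials x 1000 samples x 8 channels (72 windows of 400 samples,
preserving the 400/200 windowing geometry), trained for 10 epochs at
batch 16 with a narrow generator (`d_embed = 16`, 2 heads, 1 layer,
`latent_dim = 8`); downstream benchmarks use a 45-trial cohort. The
paper-scale defaults (`d_embed = 256`, 4 heads, 2 layers, `latent_dim =
128`, batch 64, 100 epochs, 62 channels) remain the package defaults and
run unchanged, just longer. At smoke scale a 10-epoch run reliably pulls
the generated spectra toward the real ones (the acceptance suite checks
the median improvement in prior-sample spectral KL over five seeds);
faithful time-domain reconstruction needs far more capacity and epochs
than a smoke run provides, which is expected and not a defect.

# Known limitations

- The EDF implementation covers the package's own exchange needs only
  (no EDF+ annotations, no multi-record streaming).
- Training is CPU-bound R; paper-scale corpora (thousands of 62-channel
  windows, 100 epochs) are hours, not minutes.
- The congruence and augmentation protocols substitute seeds for subjects;
  between-subject variance on real corpora is not represented.
- Conditional controllability (fixed-latent label swaps) is not yet
  quantified; congruence scoring is the only label-specificity probe.
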