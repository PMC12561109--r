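# Desk-scale smoke configuration: 18 trials x 1000 samples x 8 channels
# (72 windows of 400 samples at 200 Hz), a narrow generator and 10 epochs.
# Completes all pipeline stages on one CPU in a few minutes.
seed: 1
out_dir: tcvaegan_smoke
data:
  n_trials: 18
  trial_len: 1000
  n_channels: 8
  fs: 200
  n_classes: 3
  noise_sd: 0.5
  channel_mixing: 0.5
  one_over_f_exponent: 1.0
  win_len: 400
  hop: 200
  write_edf: false
model:
  d_embed: 16
  n_heads: 2
  n_layers: 1
  d_ff: 64
  latent_dim: 8
  dropout: 0.0
  disc_channels: [8, 16, 16]
  disc_fc: 32
  ablation: none
train:
  lr_G: 1.0e-3
  lr_D: 1.0e-4
  batch_size: 16
  epochs: 10
metrics:
  seg_sec: 2.0
  nfft: 1024
downstream:
  ratio: 1
  epochs: 15
  batch_size: 16
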