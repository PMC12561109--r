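# Network building blocks assembled from autograd ops: parameter
# initialization, linear maps, transformer encoder/decoder layers and the
# 1-D convolutional stack shared by discriminator and downstream classifier.

# Deterministic per-parameter seeding: presence or absence of one parameter
# never shifts the draws of another, so ablation variants share all unrelated
# initial weights bit-for-bit with the baseline.
param_seed <- function(seed, name) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% 1000000007
  as.integer((abs(seed) * 131 + h) %% 2147483647L)
}

init_xavier <- function(seed, name, dims, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  old <- .Random.seed_save()
  set.seed(param_seed(seed, name))
  v <- array(stats::runif(prod(dims), -lim, lim), dim = dims)
  .Random.seed_restore(old)
  v
}

init_zeros <- function(dims) array(0, dim = dims)

# Save/restore the global RNG state so parameter init does not perturb user
# simulations that interleave with model construction.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

# Add a linear layer's parameters (W: d_in x d_out, b: d_out) to a param list.
add_linear <- function(params, seed, name, d_in, d_out) {
  params[[paste0(name, "_W")]] <- init_xavier(seed, paste0(name, "_W"), c(d_in, d_out), d_in, d_out)
  params[[paste0(name, "_b")]] <- init_zeros(d_out)
  params
}

add_layernorm <- function(params, name, d) {
  params[[paste0(name, "_g")]] <- rep(1, d)
  params[[paste0(name, "_b")]] <- rep(0, d)
  params
}

add_conv <- function(params, seed, name, k, c_in, c_out) {
  params[[paste0(name, "_W")]] <- init_xavier(seed, paste0(name, "_W"), c(k, c_in, c_out),
                                              k * c_in, k * c_out)
  params[[paste0(name, "_b")]] <- init_zeros(c_out)
  params
}

lin_fwd <- function(pl, name, x) {
  ag_add(ag_matmul(x, pl[[paste0(name, "_W")]]), pl[[paste0(name, "_b")]])
}

ln_fwd <- function(pl, name, x) {
  ag_layernorm(x, pl[[paste0(name, "_g")]], pl[[paste0(name, "_b")]])
}

# Post-norm transformer encoder layer: self-attention and position-wise
# feed-forward, each wrapped in residual + layer normalization.
encoder_layer_fwd <- function(pl, prefix, x, B, T, H, dropout, training) {
  q <- lin_fwd(pl, paste0(prefix, "_Wq"), x)
  k <- lin_fwd(pl, paste0(prefix, "_Wk"), x)
  v <- lin_fwd(pl, paste0(prefix, "_Wv"), x)
  att <- ag_attention(q, k, v, B, T, T, H)
  att <- lin_fwd(pl, paste0(prefix, "_Wo"), att)
  att <- ag_dropout(att, dropout, training)
  x <- ln_fwd(pl, paste0(prefix, "_ln1"), ag_add(x, att))
  h <- ag_relu(lin_fwd(pl, paste0(prefix, "_ff1"), x))
  h <- lin_fwd(pl, paste0(prefix, "_ff2"), h)
  h <- ag_dropout(h, dropout, training)
  ln_fwd(pl, paste0(prefix, "_ln2"), ag_add(x, h))
}

# Transformer decoder layer: target self-attention, source-target attention
# over the memory, feed-forward; residual + layer norm after each block.
decoder_layer_fwd <- function(pl, prefix, tgt, mem, B, Tq, Tk, H, dropout, training) {
  q <- lin_fwd(pl, paste0(prefix, "_sWq"), tgt)
  k <- lin_fwd(pl, paste0(prefix, "_sWk"), tgt)
  v <- lin_fwd(pl, paste0(prefix, "_sWv"), tgt)
  att <- lin_fwd(pl, paste0(prefix, "_sWo"), ag_attention(q, k, v, B, Tq, Tq, H))
  att <- ag_dropout(att, dropout, training)
  tgt <- ln_fwd(pl, paste0(prefix, "_ln1"), ag_add(tgt, att))
  q <- lin_fwd(pl, paste0(prefix, "_cWq"), tgt)
  k <- lin_fwd(pl, paste0(prefix, "_cWk"), mem)
  v <- lin_fwd(pl, paste0(prefix, "_cWv"), mem)
  att <- lin_fwd(pl, paste0(prefix, "_cWo"), ag_attention(q, k, v, B, Tq, Tk, H))
  att <- ag_dropout(att, dropout, training)
  tgt <- ln_fwd(pl, paste0(prefix, "_ln2"), ag_add(tgt, att))
  h <- ag_relu(lin_fwd(pl, paste0(prefix, "_ff1"), tgt))
  h <- lin_fwd(pl, paste0(prefix, "_ff2"), h)
  h <- ag_dropout(h, dropout, training)
  ln_fwd(pl, paste0(prefix, "_ln3"), ag_add(tgt, h))
}

# Stride-2 LeakyReLU convolution stack on [B, C, T]; returns the activation
# after the last convolution, shape [B, c_out_last, ceil(T / 2^n)].
conv_stack_fwd <- function(pl, prefix, x_bct, kernels, slope) {
  h <- x_bct
  for (i in seq_along(kernels)) {
    h <- ag_conv1d(h, pl[[sprintf("%s_c%d_W", prefix, i)]],
                   pl[[sprintf("%s_c%d_b", prefix, i)]], stride = 2L)
    h <- ag_leaky_relu(h, slope)
  }
  h
}
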