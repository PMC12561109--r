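# Model core: transformer encoder, label-conditioned Gaussian latent head,
# transformer conditional decoder, and 1-D convolutional discriminator.
#
# The generator encodes a [B, T, C] window batch into a pooled d_embed vector,
# fuses it with a learned label embedding to infer a conditional Gaussian
# posterior (mu, logvar), samples by reparameterization, and decodes the
# latent code concatenated with the one-hot label back to a [B, T, C] window.
# The discriminator scores windows with a stride-2 convolution stack.

#' Model configuration
#'
#' Hyperparameters of the conditional VAE-GAN. Defaults follow the reference
#' training setup: a 2-layer, 4-head transformer with 256-dimensional
#' embeddings and a 128-dimensional latent space over 400-sample, 62-channel
#' windows with 3 emotion classes.
#'
#' @param T Window length in samples.
#' @param C Number of EEG channels.
#' @param n_class Number of label classes.
#' @param d_embed Embedding width; must be divisible by `n_heads`.
#' @param n_layers Transformer layers in encoder and decoder.
#' @param n_heads Attention heads.
#' @param d_ff Feed-forward width (default `4 * d_embed`).
#' @param dropout Dropout rate used during training.
#' @param latent_dim Latent Gaussian dimension k.
#' @param disc_channels Channel widths of the discriminator's three stride-2
#'   convolutions (kernel sizes 5, 5, 3).
#' @param disc_fc Width of the discriminator's hidden fully connected layer.
#' @param disc_leaky Negative slope of the LeakyReLU activations.
#' @param cnn_channels Channel widths used when the encoder is replaced by a
#'   convolutional stack (`ablation = "cnn_encoder"`).
#' @param logvar_clamp Range to which `logvar` is clamped before
#'   exponentiation (overflow guard).
#' @param ablation One of `"none"`, `"no_cvae"`, `"no_gan"`, `"no_label"`,
#'   `"no_pos"`, `"no_pearson"`, `"no_transformer"`, `"cnn_encoder"`; each
#'   switch removes or replaces exactly the named component.
#' @return An object of class `tcv_model_config`.
#' @export
model_config <- function(T = 400L, C = 62L, n_class = 3L,
                         d_embed = 256L, n_layers = 2L, n_heads = 4L,
                         d_ff = 4L * d_embed, dropout = 0.1,
                         latent_dim = 128L,
                         disc_channels = c(32L, 64L, 64L), disc_fc = 256L,
                         disc_leaky = 0.2,
                         cnn_channels = c(32L, 64L, 64L),
                         logvar_clamp = c(-10, 10),
                         ablation = "none") {
  ablations <- c("none", "no_cvae", "no_gan", "no_label", "no_pos",
                 "no_pearson", "no_transformer", "cnn_encoder")
  if (!ablation %in% ablations)
    stop("unknown ablation '", ablation, "'; must be one of: ",
         paste(ablations, collapse = ", "))
  if (T < 1L || C < 1L || n_class < 2L)
    stop("invalid dimensions: need T >= 1, C >= 1, n_class >= 2")
  if (d_embed %% n_heads != 0L)
    stop("d_embed (", d_embed, ") must be divisible by n_heads (", n_heads, ")")
  if (length(disc_channels) != 3L) stop("disc_channels must have length 3")
  cfg <- list(T = as.integer(T), C = as.integer(C), n_class = as.integer(n_class),
              d_embed = as.integer(d_embed), n_layers = as.integer(n_layers),
              n_heads = as.integer(n_heads), d_ff = as.integer(d_ff),
              dropout = dropout, latent_dim = as.integer(latent_dim),
              disc_channels = as.integer(disc_channels),
              disc_fc = as.integer(disc_fc), disc_leaky = disc_leaky,
              cnn_channels = as.integer(cnn_channels),
              logvar_clamp = logvar_clamp, ablation = ablation)
  class(cfg) <- "tcv_model_config"
  cfg
}

# Temporal length left after the three stride-2 convolutions.
disc_flat_len <- function(T) {
  t1 <- ceiling(T / 2); t2 <- ceiling(t1 / 2); ceiling(t2 / 2)
}

#' Initialize model parameters
#'
#' Creates all trainable arrays for the configured variant. Each parameter is
#' drawn from its own seeded stream, so two variants share the initial values
#' of every component they have in common.
#'
#' @param cfg A [model_config()].
#' @param seed Integer seed for parameter initialization.
#' @return An object of class `tcv_model`: list with `cfg`, `params` (named
#'   list of numeric arrays) and `frozen` (names of non-trainable parameters).
#' @export
model_init <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "tcv_model_config"))
  E <- cfg$d_embed; k <- cfg$latent_dim; nc <- cfg$n_class
  p <- list()
  frozen <- character()
  ab <- cfg$ablation

  # --- encoder ---
  if (ab == "cnn_encoder") {
    ch <- c(cfg$C, cfg$cnn_channels)
    ks <- c(5L, 5L, 3L)
    for (i in 1:3) p <- add_conv(p, seed, sprintf("enccnn_c%d", i), ks[i], ch[i], ch[i + 1L])
    p <- add_linear(p, seed, "enccnn_out", ch[4L], E)
  } else {
    p <- add_linear(p, seed, "enc_proj", cfg$C, E)
    if (ab != "no_transformer") {
      for (l in seq_len(cfg$n_layers)) {
        pre <- sprintf("enc_l%d", l)
        for (nm in c("Wq", "Wk", "Wv", "Wo")) p <- add_linear(p, seed, paste0(pre, "_", nm), E, E)
        p <- add_layernorm(p, paste0(pre, "_ln1"), E)
        p <- add_linear(p, seed, paste0(pre, "_ff1"), E, cfg$d_ff)
        p <- add_linear(p, seed, paste0(pre, "_ff2"), cfg$d_ff, E)
        p <- add_layernorm(p, paste0(pre, "_ln2"), E)
      }
    }
  }

  # --- label embedding ---
  p <- add_linear(p, seed, "lab", nc, E)
  if (ab == "no_label") {
    p$lab_W[] <- 0; p$lab_b[] <- 0
    frozen <- c(frozen, "lab_W", "lab_b")
  }

  # --- latent heads ---
  p <- add_linear(p, seed, "lat_mu", 2L * E, k)
  p <- add_linear(p, seed, "lat_lv", 2L * E, k)

  # --- decoder ---
  p <- add_linear(p, seed, "dec_in", k + nc, E)
  p$dec_pos <- init_xavier(seed, "dec_pos", c(cfg$T, E), cfg$T, E)
  if (ab == "no_pos") {
    p$dec_pos[] <- 0
    frozen <- c(frozen, "dec_pos")
  }
  for (l in seq_len(cfg$n_layers)) {
    pre <- sprintf("dec_l%d", l)
    for (nm in c("sWq", "sWk", "sWv", "sWo", "cWq", "cWk", "cWv", "cWo"))
      p <- add_linear(p, seed, paste0(pre, "_", nm), E, E)
    p <- add_layernorm(p, paste0(pre, "_ln1"), E)
    p <- add_layernorm(p, paste0(pre, "_ln2"), E)
    p <- add_linear(p, seed, paste0(pre, "_ff1"), E, cfg$d_ff)
    p <- add_linear(p, seed, paste0(pre, "_ff2"), cfg$d_ff, E)
    p <- add_layernorm(p, paste0(pre, "_ln3"), E)
  }
  p <- add_linear(p, seed, "dec_out", E, cfg$C)

  # --- discriminator ---
  if (ab != "no_gan") {
    ch <- c(cfg$C, cfg$disc_channels)
    ks <- c(5L, 5L, 3L)
    for (i in 1:3) p <- add_conv(p, seed, sprintf("d_c%d", i), ks[i], ch[i], ch[i + 1L])
    p <- add_linear(p, seed, "d_fc1", cfg$disc_channels[3L] * disc_flat_len(cfg$T), cfg$disc_fc)
    p <- add_linear(p, seed, "d_fc2", cfg$disc_fc, 1L)
  }

  m <- list(cfg = cfg, params = p, frozen = frozen)
  class(m) <- "tcv_model"
  m
}

#' @export
print.tcv_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, integer(1)))
  cat("<tcv_model> ", x$cfg$n_layers, "-layer transformer cVAE-GAN, d_embed=",
      x$cfg$d_embed, ", latent=", x$cfg$latent_dim, ", T=", x$cfg$T,
      ", C=", x$cfg$C, ", ablation=", x$cfg$ablation,
      ", ", format(np, big.mark = ","), " parameters\n", sep = "")
  invisible(x)
}

## ---- layout helpers ----

# Coerce [B,T,C] (or a single [T,C] matrix) to sample-major 2-D layout.
as_btc <- function(x) {
  if (is.matrix(x)) x <- array(x, dim = c(1L, nrow(x), ncol(x)))
  if (length(dim(x)) != 3L) stop("expected a [B, T, C] array or [T, C] matrix")
  x
}

btc_to_2d <- function(x) {
  d <- dim(x)
  m <- aperm(x, c(2L, 1L, 3L))
  dim(m) <- c(d[1L] * d[2L], d[3L])
  m
}

x2d_to_btc <- function(m, B, T) {
  C <- ncol(m)
  dim(m) <- c(T, B, C)
  aperm(m, c(2L, 1L, 3L))
}

make_onehot <- function(y, n_class) {
  y <- as.integer(y)
  if (any(y < 0L | y >= n_class))
    stop("labels must lie in {0, ..., ", n_class - 1L, "}")
  oh <- matrix(0, length(y), n_class)
  oh[cbind(seq_along(y), y + 1L)] <- 1
  oh
}

live_params <- function(model) lapply(model$params, ag_param)
const_params <- function(model) lapply(model$params, ag_const)

## ---- forward passes (autograd) ----

fwd_encode <- function(pl, cfg, x2d, B, training = FALSE) {
  T <- nrow(as_ag(x2d)$val) / B
  ab <- cfg$ablation
  if (ab == "cnn_encoder") {
    h <- ag_to_bct(x2d, B, T)
    h <- conv_stack_fwd(pl, "enccnn", h, c(5L, 5L, 3L), cfg$disc_leaky)
    h <- ag_gap_time(h)
    return(lin_fwd(pl, "enccnn_out", h))
  }
  h <- lin_fwd(pl, "enc_proj", x2d)
  if (ab != "no_transformer") {
    for (l in seq_len(cfg$n_layers))
      h <- encoder_layer_fwd(pl, sprintf("enc_l%d", l), h, B, T, cfg$n_heads,
                             cfg$dropout, training)
  }
  ag_mean_pool_time(h, B, T)
}

fwd_label_embed <- function(pl, cfg, y) {
  oh <- make_onehot(y, cfg$n_class)
  if (cfg$ablation == "no_label") oh[] <- 0
  lin_fwd(pl, "lab", ag_const(oh))
}

fwd_latent <- function(pl, cfg, z_input, e_y) {
  joint <- ag_concat_cols(z_input, e_y)
  list(mu = lin_fwd(pl, "lat_mu", joint), logvar = lin_fwd(pl, "lat_lv", joint))
}

fwd_reparameterize <- function(cfg, mu, logvar, eps) {
  lv <- ag_clamp(logvar, cfg$logvar_clamp[1L], cfg$logvar_clamp[2L])
  sigma <- ag_exp(ag_scale(lv, 0.5))
  ag_add(mu, ag_mul(sigma, ag_const(eps)))
}

fwd_decode <- function(pl, cfg, z, y, B, training = FALSE) {
  oh <- make_onehot(y, cfg$n_class)
  if (cfg$ablation == "no_label") oh[] <- 0
  cond <- ag_concat_cols(z, ag_const(oh))
  mem_row <- lin_fwd(pl, "dec_in", cond)              # B x E
  mem <- ag_repeat_rows(mem_row, cfg$T)               # (B*T) x E, rows replicated
  tgt <- ag_tile_batch(pl$dec_pos, B)                 # zeros + positional encodings
  for (l in seq_len(cfg$n_layers))
    tgt <- decoder_layer_fwd(pl, sprintf("dec_l%d", l), tgt, mem, B, cfg$T, cfg$T,
                             cfg$n_heads, cfg$dropout, training)
  lin_fwd(pl, "dec_out", tgt)                         # (B*T) x C
}

fwd_discriminate <- function(pl, cfg, x2d, B, training = FALSE) {
  if (cfg$ablation == "no_gan") stop("model has no discriminator (ablation = 'no_gan')")
  T <- nrow(as_ag(x2d)$val) / B
  h <- ag_to_bct(x2d, B, T)
  h <- conv_stack_fwd(pl, "d", h, c(5L, 5L, 3L), cfg$disc_leaky)
  h <- ag_flatten_bct(h)
  h <- ag_leaky_relu(lin_fwd(pl, "d_fc1", h), cfg$disc_leaky)
  lin_fwd(pl, "d_fc2", h)                             # B x 1 logits
}

## ---- public numeric interface ----

#' Encode windows into pooled sequence representations
#'
#' Projects channels into the embedding space, applies the transformer
#' encoder stack and mean-pools over time.
#'
#' @param model A [model_init()] object.
#' @param x `[B, T, C]` array (or a single `[T, C]` matrix) of windows.
#' @return `[B, d_embed]` matrix `z_input`.
#' @export
encode <- function(model, x) {
  x <- as_btc(x)
  if (dim(x)[3L] != model$cfg$C)
    stop("channel mismatch: input has ", dim(x)[3L], " channels, model expects ", model$cfg$C)
  if (dim(x)[2L] < 1L) stop("empty time axis")
  fwd_encode(const_params(model), model$cfg, ag_const(btc_to_2d(x)), dim(x)[1L])$val
}

#' Learned label embedding
#'
#' Maps integer class labels (0-based) through the fully connected embedding
#' layer into `d_embed`-dimensional vectors `e_y`.
#'
#' @inheritParams encode
#' @param y Integer labels in `{0, ..., n_class - 1}`.
#' @return `[B, d_embed]` matrix.
#' @export
label_embedding <- function(model, y) {
  fwd_label_embed(const_params(model), model$cfg, y)$val
}

#' Infer the conditional latent Gaussian
#'
#' Concatenates the pooled encoding with the label embedding and applies two
#' independent fully connected heads for the mean and log-variance.
#'
#' @inheritParams encode
#' @param z_input `[B, d_embed]` matrix from [encode()].
#' @param e_y `[B, d_embed]` matrix from [label_embedding()].
#' @return A `latent_gaussian`: list with `mu` and `logvar`, each `[B, k]`.
#' @export
infer_latent <- function(model, z_input, e_y) {
  if (!is.matrix(z_input) || !is.matrix(e_y) || nrow(z_input) != nrow(e_y))
    stop("z_input and e_y must be matrices with matching batch size")
  if (ncol(z_input) != model$cfg$d_embed || ncol(e_y) != model$cfg$d_embed)
    stop("z_input and e_y must have d_embed = ", model$cfg$d_embed, " columns")
  pl <- const_params(model)
  g <- fwd_latent(pl, model$cfg, ag_const(z_input), ag_const(e_y))
  structure(list(mu = g$mu$val, logvar = g$logvar$val), class = "latent_gaussian")
}

#' Reparameterized sampling from a latent Gaussian
#'
#' Draws `z = mu + exp(0.5 * logvar) * eps` with `eps ~ N(0, I)`. `logvar` is
#' clamped to `clamp` before exponentiation as an overflow guard.
#'
#' @param g A `latent_gaussian` (list with `mu`, `logvar`).
#' @param eps Optional `[B, k]` matrix of standard normal draws; when `NULL`,
#'   drawn from R's RNG (seed with [set.seed()] for reproducibility).
#' @param clamp Numeric length-2 clamping range for `logvar`.
#' @return `[B, k]` matrix of latent samples.
#' @export
reparameterize <- function(g, eps = NULL, clamp = c(-10, 10)) {
  mu <- g$mu; lv <- pmin(pmax(g$logvar, clamp[1L]), clamp[2L])
  if (!all(is.finite(mu)) || !all(is.finite(g$logvar)))
    stop("non-finite latent parameters")
  if (is.null(eps)) eps <- matrix(stats::rnorm(length(mu)), nrow(mu), ncol(mu))
  mu + exp(0.5 * lv) * eps
}

#' Decode latent codes into windows
#'
#' Concatenates `z` with the one-hot label, maps it to the embedding space,
#' replicates it T times as decoder memory, and runs the transformer decoder
#' initialized with the learnable positional encodings.
#'
#' @inheritParams encode
#' @param z `[B, k]` latent matrix.
#' @param y Integer labels in `{0, ..., n_class - 1}`.
#' @return `[B, T, C]` array of generated windows.
#' @export
decode <- function(model, z, y) {
  if (!is.matrix(z)) z <- matrix(z, nrow = 1L)
  if (ncol(z) != model$cfg$latent_dim)
    stop("z must have latent_dim = ", model$cfg$latent_dim, " columns")
  if (length(y) != nrow(z)) stop("one label per latent row required")
  out <- fwd_decode(const_params(model), model$cfg, ag_const(z), y, nrow(z))
  x2d_to_btc(out$val, nrow(z), model$cfg$T)
}

#' Discriminator logits
#'
#' Scores windows with the three stride-2 convolutions (kernels 5, 5, 3),
#' flatten, and two fully connected layers. Returns one raw logit per window;
#' apply `plogis()` for a probability.
#'
#' @inheritParams encode
#' @return Numeric vector of length B.
#' @export
discriminate <- function(model, x) {
  x <- as_btc(x)
  if (dim(x)[3L] != model$cfg$C)
    stop("channel mismatch: input has ", dim(x)[3L], " channels, model expects ", model$cfg$C)
  drop(fwd_discriminate(const_params(model), model$cfg, ag_const(btc_to_2d(x)), dim(x)[1L])$val)
}

## ---- checkpoints ----

#' Save / load a model checkpoint
#'
#' Single-file RDS container with a format tag and version, holding the
#' configuration, all parameter arrays, frozen-parameter names and optional
#' optimizer state / metadata.
#'
#' @param model A `tcv_model`.
#' @param path File path.
#' @param optimizer_state Optional optimizer state to resume training.
#' @param meta Optional named list of metadata.
#' @return `load_checkpoint()` returns the `tcv_model` with attribute
#'   `"optimizer_state"` and `"meta"` attached when present.
#' @export
save_checkpoint <- function(model, path, optimizer_state = NULL, meta = NULL) {
  stopifnot(inherits(model, "tcv_model"))
  obj <- list(format = "tcvaegan-checkpoint", version = 1L,
              cfg = model$cfg, params = model$params, frozen = model$frozen,
              optimizer_state = optimizer_state, meta = meta)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "tcvaegan-checkpoint"))
    stop("not a tcvaegan checkpoint: ", path)
  m <- list(cfg = obj$cfg, params = obj$params, frozen = obj$frozen)
  class(m) <- "tcv_model"
  attr(m, "optimizer_state") <- obj$optimizer_state
  attr(m, "meta") <- obj$meta
  m
}
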