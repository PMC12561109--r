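# Alternating adversarial training: one discriminator update followed by two
# generator updates per iteration, Adam for both, no learning-rate schedule.
# All six generator loss terms are recombined every batch with dynamic
# weights; ablation switches drop or bypass exactly one component.

#' Training configuration
#'
#' Defaults follow the reference setup: generator lr 1e-3, discriminator lr
#' 1e-4, Adam betas (0.9, 0.999), batch size 64, 100 epochs, one
#' discriminator then two generator updates per iteration.
#'
#' @param lr_G,lr_D Learning rates of generator and discriminator.
#' @param betas Adam `(beta1, beta2)`.
#' @param batch_size Windows per batch (>= 2).
#' @param epochs Training epochs.
#' @param g_steps_per_iter,d_steps_per_iter Updates per iteration.
#' @param seed Seed for all stochastic components (shuffling, latent draws,
#'   dropout).
#' @param ablation Optional override of the model's ablation switch.
#' @return A `train_config`.
#' @export
train_config <- function(lr_G = 1e-3, lr_D = 1e-4, betas = c(0.9, 0.999),
                         batch_size = 64L, epochs = 100L,
                         g_steps_per_iter = 2L, d_steps_per_iter = 1L,
                         seed = 1L, ablation = NULL) {
  if (lr_G <= 0 || lr_D <= 0) stop("learning rates must be positive")
  if (batch_size < 2L) stop("batch_size must be at least 2")
  if (epochs < 0L) stop("epochs must be non-negative")
  structure(list(lr_G = lr_G, lr_D = lr_D, betas = betas,
                 batch_size = as.integer(batch_size), epochs = as.integer(epochs),
                 g_steps_per_iter = as.integer(g_steps_per_iter),
                 d_steps_per_iter = as.integer(d_steps_per_iter),
                 seed = as.integer(seed), ablation = ablation),
            class = "train_config")
}

active_loss_terms <- function(ablation) {
  terms <- loss_term_names
  if (ablation == "no_cvae") terms <- setdiff(terms, "kl")
  if (ablation == "no_gan") terms <- setdiff(terms, "adv")
  if (ablation == "no_pearson") terms <- setdiff(terms, "corr")
  terms
}

## ---- Adam ----

adam_init <- function() list(m = list(), v = list(), t = 0L)

adam_step <- function(pl, state, names, lr, betas, frozen = character(), eps = 1e-8) {
  state$t <- state$t + 1L
  b1 <- betas[1L]; b2 <- betas[2L]
  corr1 <- 1 - b1^state$t; corr2 <- 1 - b2^state$t
  for (nm in names) {
    if (nm %in% frozen) next
    g <- pl[[nm]]$grad
    if (is.null(g)) next
    m <- state$m[[nm]]; v <- state$v[[nm]]
    if (is.null(m)) { m <- g * 0; v <- g * 0 }
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g^2
    state$m[[nm]] <- m; state$v[[nm]] <- v
    pl[[nm]]$val <- pl[[nm]]$val - lr * (m / corr1) / (sqrt(v / corr2) + eps)
  }
  state
}

## ---- training state ----

# Internal environment bundling model config, live parameters, optimizer
# states and update counters.
new_train_state <- function(model, tcfg) {
  st <- new.env(parent = emptyenv())
  st$cfg <- model$cfg
  st$tcfg <- tcfg
  st$frozen <- model$frozen
  st$pl <- live_params(model)
  nm <- names(st$pl)
  st$g_names <- nm[!startsWith(nm, "d_")]
  st$d_names <- nm[startsWith(nm, "d_")]
  st$opt_g <- adam_init()
  st$opt_d <- adam_init()
  st$n_updates_d <- 0L
  st$n_updates_g <- 0L
  st
}

# One full generator forward on a batch, returning the loss nodes of the
# active terms plus the reconstruction x_hat node.
generator_forward <- function(st, x2d, yb, B, training = TRUE, with_losses = TRUE) {
  cfg <- st$cfg
  pl <- st$pl
  zi <- fwd_encode(pl, cfg, ag_const(x2d), B, training = training)
  ey <- fwd_label_embed(pl, cfg, yb)
  lat <- fwd_latent(pl, cfg, zi, ey)
  if (cfg$ablation == "no_cvae") {
    z <- lat$mu                               # deterministic latent head
  } else {
    eps <- matrix(stats::rnorm(B * cfg$latent_dim), B, cfg$latent_dim)
    z <- fwd_reparameterize(cfg, lat$mu, lat$logvar, eps)
  }
  xh <- fwd_decode(pl, cfg, z, yb, B, training = training)
  if (!with_losses) return(list(losses = NULL, xh = xh))
  losses <- list(recon = ag_recon_loss(xh, x2d))
  if (cfg$ablation != "no_cvae")
    losses$kl <- ag_kl_loss(lat$mu, lat$logvar, B)
  if (cfg$ablation != "no_gan") {
    lg <- fwd_discriminate(pl, cfg, xh, B, training = training)
    losses$adv <- ag_adv_gen_loss(lg)
  }
  if (cfg$ablation != "no_pearson")
    losses$corr <- ag_pearson_loss(xh, x2d, B, cfg$T)
  losses$smooth <- ag_smooth_loss(xh, B, cfg$T)
  # 1.0 s Hann segments, capped at the window length for short windows
  losses$spec <- ag_spectrum_loss(xh, x2d, B, cfg$T, st$fs,
                                  seg_len = min(as.integer(round(st$fs)), cfg$T))
  list(losses = losses, xh = xh)
}

#' One adversarial training iteration
#'
#' Runs `d_steps_per_iter` discriminator updates (real vs freshly generated
#' windows, binary cross-entropy) followed by `g_steps_per_iter` generator
#' updates on the dynamically weighted multi-term objective.
#'
#' @param st Training state created by [fit_tcvaegan()] (internal).
#' @param xb `[B, T, C]` batch array.
#' @param yb Integer labels of the batch.
#' @return List with the last generator `loss_bundle` and the discriminator
#'   loss (`NA` under `no_gan`).
#' @keywords internal
train_step <- function(st, xb, yb) {
  cfg <- st$cfg; tcfg <- st$tcfg
  B <- dim(xb)[1L]
  x2d <- btc_to_2d(xb)
  d_loss_val <- NA_real_
  if (cfg$ablation != "no_gan") {
    for (i in seq_len(tcfg$d_steps_per_iter)) {
      fake <- generator_forward(st, x2d, yb, B, training = TRUE, with_losses = FALSE)$xh$val
      lr_real <- fwd_discriminate(st$pl, cfg, ag_const(x2d), B, training = TRUE)
      lr_fake <- fwd_discriminate(st$pl, cfg, ag_const(fake), B, training = TRUE)
      dl <- ag_disc_loss(lr_real, lr_fake)
      d_loss_val <- dl$val
      if (!is.finite(d_loss_val)) stop("non-finite discriminator loss")
      ag_backward(dl)
      st$opt_d <- adam_step(st$pl, st$opt_d, st$d_names, tcfg$lr_D, tcfg$betas, st$frozen)
      ag_zero_grad(st$pl)
      st$n_updates_d <- st$n_updates_d + 1L
    }
  }
  bundle <- NULL
  for (i in seq_len(tcfg$g_steps_per_iter)) {
    gf <- generator_forward(st, x2d, yb, B, training = TRUE)
    vals <- vapply(gf$losses, function(n) n$val, numeric(1))
    alpha <- dynamic_weights(vals)            # no-grad, non-trainable
    tot <- ag_wsum(unname(gf$losses), alpha)
    if (!is.finite(tot$val))
      stop("non-finite generator loss (terms: ",
           paste(sprintf("%s=%.3g", names(vals), vals), collapse = ", "), ")")
    ag_backward(tot)
    st$opt_g <- adam_step(st$pl, st$opt_g, st$g_names, tcfg$lr_G, tcfg$betas, st$frozen)
    ag_zero_grad(st$pl)
    st$n_updates_g <- st$n_updates_g + 1L
    bundle <- generator_loss(vals, alpha)
  }
  list(bundle = bundle, d_loss = d_loss_val)
}

#' Train the conditional VAE-GAN
#'
#' End-to-end alternating optimization on a window batch. All randomness
#' (shuffling, reparameterization draws, dropout) flows from `train_cfg$seed`,
#' so identical configurations reproduce identical loss trajectories.
#'
#' @param windows An [window_batch()] of training windows.
#' @param model_cfg A [model_config()]; its `T`/`C` must match the windows.
#' @param train_cfg A [train_config()].
#' @param model Optional pre-initialized `tcv_model` to continue training.
#' @param log_csv Optional path; per-epoch means of every loss term, its
#'   weight and the discriminator loss are appended as CSV.
#' @param verbose Print per-epoch summaries.
#' @return The trained `tcv_model` with attributes `training_log`
#'   (data frame) and `update_counts` (named vector, D and G).
#' @export
fit_tcvaegan <- function(windows, model_cfg = model_config(),
                         train_cfg = train_config(), model = NULL,
                         log_csv = NULL, verbose = FALSE) {
  stopifnot(inherits(windows, "eeg_window_batch"))
  d <- dim(windows$data)
  if (!is.null(train_cfg$ablation)) {
    args <- unclass(model_cfg)
    args$ablation <- train_cfg$ablation
    model_cfg <- do.call(model_config, args)
  }
  if (d[2L] != model_cfg$T || d[3L] != model_cfg$C)
    stop("window shape [", d[2L], " x ", d[3L], "] does not match model (T=",
         model_cfg$T, ", C=", model_cfg$C, ")")
  if (is.null(model)) model <- model_init(model_cfg, seed = train_cfg$seed)
  set.seed(train_cfg$seed)
  st <- new_train_state(model, train_cfg)
  st$fs <- windows$fs
  n <- d[1L]
  log_rows <- vector("list", train_cfg$epochs)
  terms <- active_loss_terms(model_cfg$ablation)
  for (ep in seq_len(train_cfg$epochs)) {
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / train_cfg$batch_size))
    acc <- NULL; accw <- NULL; accd <- c()
    for (bi in batches) {
      res <- train_step(st, windows$data[bi, , , drop = FALSE], windows$labels[bi])
      acc <- rbind(acc, res$bundle$terms)
      accw <- rbind(accw, res$bundle$alpha)
      accd <- c(accd, res$d_loss)
    }
    row <- data.frame(epoch = ep)
    for (tn in terms) {
      row[[paste0("L_", tn)]] <- mean(acc[, tn])
      row[[paste0("alpha_", tn)]] <- mean(accw[, tn])
    }
    row$d_loss <- if (all(is.na(accd))) NA_real_ else mean(accd, na.rm = TRUE)
    row$L_gen <- mean(rowSums(acc * accw))
    log_rows[[ep]] <- row
    if (verbose)
      message(sprintf("epoch %3d | L_gen %.4f | D %.4f", ep, row$L_gen,
                      ifelse(is.na(row$d_loss), NaN, row$d_loss)))
  }
  log <- if (train_cfg$epochs > 0L) do.call(rbind, log_rows) else NULL
  if (!is.null(log_csv) && !is.null(log))
    utils::write.csv(log, log_csv, row.names = FALSE)
  for (nm in names(st$pl)) model$params[[nm]] <- st$pl[[nm]]$val
  attr(model, "training_log") <- log
  attr(model, "update_counts") <- c(D = st$n_updates_d, G = st$n_updates_g)
  model
}

#' Generate windows from a trained model
#'
#' `mode = "prior"` draws latent codes from N(0, I) and decodes them with
#' the requested labels (used for distributional metrics and augmentation);
#' `mode = "reconstruction"` encodes real windows and decodes their inferred
#' latents, yielding generated windows paired index-to-index with the input
#' (used for the paired correlation metrics).
#'
#' @param model A trained `tcv_model`.
#' @param labels Integer labels for prior sampling (ignored in
#'   reconstruction mode, where labels come from `x`).
#' @param mode `"prior"` or `"reconstruction"`.
#' @param x An [window_batch()] of real windows (reconstruction mode).
#' @param fs Sampling rate attached to the generated batch (taken from `x`
#'   when given).
#' @param seed Optional seed for the latent draws.
#' @return An [window_batch()] of generated windows.
#' @export
sample_windows <- function(model, labels = NULL,
                           mode = c("prior", "reconstruction"),
                           x = NULL, fs = 200, seed = NULL) {
  mode <- match.arg(mode)
  cfg <- model$cfg
  if (!is.null(seed)) set.seed(seed)
  if (mode == "prior") {
    if (is.null(labels)) stop("prior mode requires labels")
    labels <- as.integer(labels)
    if (any(labels < 0L | labels >= cfg$n_class))
      stop("labels must lie in {0, ..., ", cfg$n_class - 1L, "}")
    B <- length(labels)
    z <- matrix(stats::rnorm(B * cfg$latent_dim), B, cfg$latent_dim)
    out <- decode(model, z, labels)
    return(window_batch(out, labels, fs,
                        data.frame(trial_id = rep("prior", B), start = rep(NA_integer_, B))))
  }
  if (is.null(x)) stop("reconstruction mode requires real windows x")
  stopifnot(inherits(x, "eeg_window_batch"))
  labels <- x$labels
  B <- dim(x$data)[1L]
  zi <- encode(model, x$data)
  ey <- label_embedding(model, labels)
  g <- infer_latent(model, zi, ey)
  z <- if (cfg$ablation == "no_cvae") g$mu else
    reparameterize(g, clamp = cfg$logvar_clamp)
  out <- decode(model, z, labels)
  window_batch(out, labels, x$fs,
               data.frame(trial_id = paste0("recon:", x$provenance$trial_id),
                          start = x$provenance$start))
}
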