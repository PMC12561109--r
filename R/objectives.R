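# The six generator loss terms, the discriminator objective and the
# batch-wise dynamic weighting scheme.
#
# Weighting: the six scalar losses are z-scored within the batch, passed
# through a softmax, clipped to [0.1, 0.4] and renormalized to sum to one.
# With six terms the post-clipping bounds imply a maximum per-term
# contribution of 0.4 / (0.4 + 5 * 0.1) = 0.444... and a minimum of
# 0.1 / 0.9 = 0.111... The weights carry no gradient and are not trainable.

loss_term_names <- c("recon", "kl", "adv", "corr", "smooth", "spec")

## ---- public numeric interface ----

#' Reconstruction loss (MSE)
#'
#' Mean squared error over all samples, time steps and channels.
#'
#' @param x_hat,x Arrays of identical shape (`[B, T, C]`, `[T, C]` or vector).
#' @return Non-negative scalar.
#' @export
recon_loss <- function(x_hat, x) {
  if (!identical(dim(x_hat) %||% length(x_hat), dim(x) %||% length(x)))
    stop("x_hat and x must have identical shapes")
  mean((x_hat - x)^2)
}

#' KL divergence of the latent posterior from N(0, I)
#'
#' `-0.5 * sum_j (1 + logvar_j - mu_j^2 - exp(logvar_j))`, averaged over the
#' batch.
#'
#' @param g A `latent_gaussian` (list with matrices `mu`, `logvar`).
#' @return Non-negative scalar.
#' @export
kl_loss <- function(g) {
  mu <- as.matrix(g$mu); lv <- as.matrix(g$logvar)
  stopifnot(all(dim(mu) == dim(lv)), all(is.finite(mu)), all(is.finite(lv)))
  mean(-0.5 * rowSums(1 + lv - mu^2 - exp(lv)))
}

#' Adversarial losses
#'
#' `adv_loss_generator()` is the non-saturating generator term
#' `E[-log D(x_hat)]`; `disc_loss()` is binary cross-entropy with targets 1
#' (real) and 0 (fake). Both operate on raw logits for numerical stability.
#'
#' @param logits_fake,logits_real Numeric vectors of discriminator logits.
#' @return Scalar loss.
#' @export
adv_loss_generator <- function(logits_fake) {
  stopifnot(all(is.finite(logits_fake)))
  mean(log1p(exp(-abs(logits_fake))) + pmax(-logits_fake, 0))
}

#' @rdname adv_loss_generator
#' @export
disc_loss <- function(logits_real, logits_fake) {
  stopifnot(all(is.finite(logits_real)), all(is.finite(logits_fake)))
  softplus <- function(z) log1p(exp(-abs(z))) + pmax(z, 0)
  mean(softplus(-logits_real)) + mean(softplus(logits_fake))
}

#' Pearson correlation loss
#'
#' One minus the mean over samples and channels of the per-channel Pearson
#' correlation along time between generated and real windows. A channel pair
#' with zero variance contributes correlation 0 (with a warning), penalizing
#' degenerate flat generations without interrupting training.
#'
#' @param x_hat,x `[B, T, C]` arrays (or `[T, C]` matrices) of matching shape.
#' @return Scalar in `[0, 2]`.
#' @export
pearson_loss <- function(x_hat, x) {
  x_hat <- as_btc(x_hat); x <- as_btc(x)
  if (!identical(dim(x_hat), dim(x))) stop("x_hat and x must have identical shapes")
  d <- dim(x_hat)
  node <- ag_pearson_loss(ag_const(btc_to_2d(x_hat)), btc_to_2d(x), d[1L], d[2L])
  node$val
}

#' Temporal smoothness loss
#'
#' Mean over the batch of `1/(T-1) * sum_t ||x_t - x_{t+1}||^2` (squared
#' norm over channels), penalizing large variations between adjacent steps.
#'
#' @param x_hat `[B, T, C]` array or `[T, C]` matrix with `T >= 2`.
#' @return Non-negative scalar.
#' @export
smooth_loss <- function(x_hat) {
  x_hat <- as_btc(x_hat)
  if (dim(x_hat)[2L] < 2L) stop("smooth_loss requires T >= 2")
  d <- dim(x_hat)
  ag_smooth_loss(ag_const(btc_to_2d(x_hat)), d[1L], d[2L])$val
}

#' Power-spectrum consistency loss
#'
#' Welch PSDs (1.0 s Hann segments, 50% overlap, full band up to fs/2) of
#' generated and real windows, compared by mean squared error over frequency
#' bins, channels and the batch. Differentiable in `x_hat` along the
#' training path.
#'
#' @inheritParams pearson_loss
#' @param fs Sampling rate in Hz.
#' @param seg_sec Welch segment length in seconds (default 1.0).
#' @param overlap Fractional segment overlap (default 0.5).
#' @return Non-negative scalar.
#' @export
spectrum_loss <- function(x_hat, x, fs, seg_sec = 1.0, overlap = 0.5) {
  x_hat <- as_btc(x_hat); x <- as_btc(x)
  if (!identical(dim(x_hat), dim(x))) stop("x_hat and x must have identical shapes")
  d <- dim(x_hat)
  seg_len <- as.integer(round(seg_sec * fs))
  if (d[2L] < seg_len)
    stop("T = ", d[2L], " too short for one Welch segment of ", seg_len, " samples")
  ag_spectrum_loss(ag_const(btc_to_2d(x_hat)), btc_to_2d(x), d[1L], d[2L],
                   fs, seg_len, overlap)$val
}

#' Dynamic loss weights
#'
#' z-scores the loss values (epsilon = 1e-8 in the denominator), applies a
#' softmax, clips each weight to `clip` and renormalizes to sum to one. The
#' weights are computed outside gradient flow and are not trainable.
#'
#' @param losses Numeric vector of finite scalar loss values.
#' @param clip Length-2 clipping range (default `c(0.1, 0.4)`).
#' @param eps Stabilizer added to the standard deviation.
#' @return Weight vector of the same length summing to one.
#' @export
dynamic_weights <- function(losses, clip = c(0.1, 0.4), eps = 1e-8) {
  losses <- as.numeric(losses)
  bad <- which(!is.finite(losses))
  if (length(bad)) {
    nm <- if (!is.null(names(losses))) names(losses)[bad] else
      if (length(losses) == 6L) loss_term_names[bad] else as.character(bad)
    stop("non-finite loss term(s): ", paste(nm, collapse = ", "))
  }
  z <- (losses - mean(losses)) / (stats::sd(losses) + eps)
  if (any(!is.finite(z))) z <- rep(0, length(losses))
  e <- exp(z - max(z))
  w <- e / sum(e)
  w <- pmin(pmax(w, clip[1L]), clip[2L])
  w / sum(w)
}

#' Assemble the total generator loss
#'
#' Combines the six loss terms with their dynamic weights into
#' `L_gen = sum_i alpha_i * L_i`.
#'
#' @param terms Named numeric vector of loss values (names
#'   `recon, kl, adv, corr, smooth, spec`, or any subset under ablation).
#' @param alpha Optional weights; computed by [dynamic_weights()] when `NULL`.
#' @return A `loss_bundle`: list with `terms`, `alpha`, `total`.
#' @export
generator_loss <- function(terms, alpha = NULL) {
  terms <- unlist(terms)
  if (is.null(names(terms)) && length(terms) == 6L) names(terms) <- loss_term_names
  if (is.null(alpha)) alpha <- dynamic_weights(terms)
  stopifnot(length(alpha) == length(terms))
  structure(list(terms = terms, alpha = stats::setNames(as.numeric(alpha), names(terms)),
                 total = sum(alpha * terms)),
            class = "loss_bundle")
}

#' @export
print.loss_bundle <- function(x, ...) {
  cat("<loss_bundle> L_gen =", format(x$total, digits = 6), "\n")
  df <- data.frame(term = names(x$terms), loss = as.numeric(x$terms),
                   alpha = as.numeric(x$alpha))
  print(df, row.names = FALSE)
  invisible(x)
}

## ---- autograd loss ops (training path) ----

ag_recon_loss <- function(x_hat, x) ag_mean(ag_square(ag_sub(x_hat, as_ag(x))))

ag_kl_loss <- function(mu, logvar, B) {
  inner <- ag_sub(ag_sub(ag_add(logvar, 1), ag_square(mu)), ag_exp(logvar))
  ag_scale(ag_sum(inner), -0.5 / B)
}

ag_adv_gen_loss <- function(logits) ag_mean(ag_softplus(ag_neg(logits)))

ag_disc_loss <- function(logits_real, logits_fake) {
  ag_add(ag_mean(ag_softplus(ag_neg(logits_real))),
         ag_mean(ag_softplus(logits_fake)))
}

# 1 - mean_{b,c} corr_t(x_hat, x); custom op with analytic gradient in x_hat.
ag_pearson_loss <- function(x_hat, x, B, T, var_tol = 1e-12) {
  x_hat <- as_ag(x_hat)
  xv <- if (is_ag(x)) x$val else x
  C <- ncol(x_hat$val)
  a <- x_hat$val; dim(a) <- c(T, B * C)
  b <- xv; dim(b) <- c(T, B * C)
  ac <- sweep(a, 2L, colMeans(a), "-")
  bc <- sweep(b, 2L, colMeans(b), "-")
  sa2 <- colSums(ac^2); sb2 <- colSums(bc^2)
  ok <- sa2 > var_tol & sb2 > var_tol
  if (!all(ok))
    warning(sum(!ok), " zero-variance channel series; correlation set to 0")
  r <- numeric(B * C)
  denom <- sqrt(sa2[ok] * sb2[ok])
  r[ok] <- colSums(ac[, ok, drop = FALSE] * bc[, ok, drop = FALSE]) / denom
  val <- 1 - mean(r)
  ag_op(val, list(x_hat), function(g) {
    gr <- matrix(0, T, B * C)
    if (any(ok)) {
      scale <- -g / (B * C)
      dr <- sweep(bc[, ok, drop = FALSE], 2L, denom, "/") -
        sweep(ac[, ok, drop = FALSE], 2L, r[ok] / sa2[ok], "*")
      dr <- sweep(dr, 2L, colMeans(dr), "-")   # centering projection
      gr[, ok] <- scale * dr
    }
    dim(gr) <- c(T * B, C)
    list(gr)
  })
}

# mean_b 1/(T-1) sum_t sum_c (x[t+1] - x[t])^2; custom op.
ag_smooth_loss <- function(x_hat, B, T) {
  x_hat <- as_ag(x_hat)
  C <- ncol(x_hat$val)
  a <- x_hat$val; dim(a) <- c(T, B, C)
  d <- a[-1L, , , drop = FALSE] - a[-T, , , drop = FALSE]
  val <- sum(d^2) / ((T - 1) * B)
  ag_op(val, list(x_hat), function(g) {
    gd <- 2 * g * d / ((T - 1) * B)
    gx <- array(0, dim = c(T, B, C))
    gx[-1L, , ] <- gd
    gx[-T, , ] <- gx[-T, , , drop = FALSE] - gd
    dim(gx) <- c(T * B, C)
    list(gx)
  })
}

# MSE between Welch PSDs of x_hat and x; gradient in x_hat flows through the
# windowed FFTs of every segment (detrending handled as a projection).
ag_spectrum_loss <- function(x_hat, x, B, T, fs, seg_len, overlap = 0.5) {
  x_hat <- as_ag(x_hat)
  xv <- if (is_ag(x)) x$val else x
  C <- ncol(x_hat$val)
  M <- B * C
  a <- x_hat$val; dim(a) <- c(T, M)
  b <- xv; dim(b) <- c(T, M)
  wa <- welch_psd_mat(a, fs, seg_len, overlap, window = "hann", keep_fft = TRUE)
  wb <- welch_psd_mat(b, fs, seg_len, overlap, window = "hann")
  diff <- wa$psd - wb$psd
  nb <- nrow(diff)
  val <- mean(diff^2)
  ag_op(val, list(x_hat), function(g) {
    gP <- 2 * g * diff / (nb * M)              # nb x M
    N <- wa$nfft
    # map the one-sided gradient onto the full spectrum (mirror bins share it)
    gx <- matrix(0, T, M)
    for (s in seq_len(wa$nseg)) {
      X <- wa$ffts[[s]]
      H <- matrix(0 + 0i, N, M)
      H[seq_len(nb), ] <- gP
      if (N %% 2L == 0L) {
        if (nb > 2L) H[N:(nb + 1L), ] <- gP[2:(nb - 1L), , drop = FALSE]
      } else {
        H[N:(nb + 1L), ] <- gP[2:nb, , drop = FALSE]
      }
      Y <- stats::mvfft(H * Conj(X))
      du <- 2 * Re(Y[seq_len(wa$seg_len), , drop = FALSE]) * wa$w / (fs * wa$U * wa$nseg)
      du <- sweep(du, 2L, colMeans(du), "-")   # mean-detrend projection
      idx <- ((s - 1L) * wa$hop + 1L):((s - 1L) * wa$hop + wa$seg_len)
      gx[idx, ] <- gx[idx, ] + du
    }
    dim(gx) <- c(T * B, C)
    list(gx)
  })
}
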