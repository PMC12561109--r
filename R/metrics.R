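# Evaluation suite: paired channel-wise Pearson / Spearman correlation,
# spectral KL divergence, feature-space Frechet distance (FID), normalized
# PSD mean squared error and spectral earth mover's distance, with
# channel-wise and aggregate reporting.

#' Channel-wise Pearson correlation
#'
#' Product-moment correlation along time, per channel, between paired
#' signals. Zero-variance channels are reported as `NA` with a warning.
#'
#' @param x,y `[T, C]` matrices (real and generated).
#' @return Numeric vector of length C.
#' @export
pearson_channels <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  stopifnot(identical(dim(x), dim(y)))
  xc <- sweep(x, 2L, colMeans(x), "-")
  yc <- sweep(y, 2L, colMeans(y), "-")
  sx <- colSums(xc^2); sy <- colSums(yc^2)
  ok <- sx > 1e-24 & sy > 1e-24
  r <- rep(NA_real_, ncol(x))
  if (any(!ok)) warning(sum(!ok), " zero-variance channel(s); correlation undefined")
  r[ok] <- colSums(xc[, ok, drop = FALSE] * yc[, ok, drop = FALSE]) /
    sqrt(sx[ok] * sy[ok])
  r
}

#' Channel-wise Spearman rank correlation
#'
#' Average ranks are used for ties. Without ties this equals
#' `1 - 6 * sum(d_i^2) / (n (n^2 - 1))` on the rank differences; with ties
#' it is the Pearson correlation of the rank vectors.
#'
#' @inheritParams pearson_channels
#' @return Numeric vector of length C.
#' @export
spearman_channels <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  stopifnot(identical(dim(x), dim(y)))
  n <- nrow(x)
  vapply(seq_len(ncol(x)), function(j) {
    if (stats::sd(x[, j]) < 1e-12 || stats::sd(y[, j]) < 1e-12) {
      warning("constant channel ", j, "; rank correlation undefined")
      return(NA_real_)
    }
    rx <- rank(x[, j], ties.method = "average")
    ry <- rank(y[, j], ties.method = "average")
    ties <- anyDuplicated(rx) > 0L || anyDuplicated(ry) > 0L
    if (!ties) 1 - 6 * sum((rx - ry)^2) / (n * (n^2 - 1))
    else stats::cor(rx, ry)
  }, numeric(1))
}

band_psd <- function(x, fs, spec) {
  seg_len <- as.integer(round(spec$seg_sec * fs))
  nfft <- max(spec$nfft, seg_len)
  w <- welch_psd(x, fs, seg_len, overlap = spec$overlap,
                 window = spec$window, nfft = nfft)
  welch_band(w$freq, w$psd, spec$band)
}

#' Spectral KL divergence per channel
#'
#' Band-limited Welch PSDs of the real (`P`) and generated (`Q`) signal,
#' each normalized to sum to one over the retained bins, compared by
#' `sum(P * log(P / Q))` (natural log; `Q` floored at 1e-12).
#'
#' @param x,y `[T, C]` matrices: real and generated signals.
#' @param fs Sampling rate in Hz.
#' @param spec A [welch_spec()].
#' @return Numeric vector of length C.
#' @export
spectral_kl <- function(x, y, fs, spec = welch_spec()) {
  x <- as.matrix(x); y <- as.matrix(y)
  stopifnot(ncol(x) == ncol(y))
  vapply(seq_len(ncol(x)), function(j) {
    P <- band_psd(x[, j], fs, spec)$psd
    Q <- band_psd(y[, j], fs, spec)$psd
    if (sum(P) <= 0 || sum(Q) <= 0) stop("all-zero PSD in channel ", j)
    kl_discrete(P / sum(P), Q / sum(Q))
  }, numeric(1))
}

# KL divergence between two discrete distributions (natural log, floor on Q).
kl_discrete <- function(P, Q, eps = 1e-12) {
  Q <- pmax(Q, eps)
  sum(ifelse(P > 0, P * log(P / Q), 0))
}

# Area between the CDFs of two spectral densities sampled on grid f.
# The densities are treated as piecewise linear between Welch bins (so their
# CDFs are piecewise quadratic and exact under the trapezoidal rule); the
# grid is refined before integrating |F_x - F_y|, which otherwise loses
# accuracy wherever the CDF difference changes sign inside a bin.
emd_cdf_area <- function(f, px, py, refine = 1024L) {
  px <- px / pracma::trapz(f, px)
  py <- py / pracma::trapz(f, py)
  if (refine > 1L && length(f) > 1L) {
    fg <- unique(as.numeric(vapply(seq_len(length(f) - 1L), function(i)
      seq(f[i], f[i + 1L], length.out = refine + 1L), numeric(refine + 1L))))
    px <- stats::approx(f, px, fg)$y
    py <- stats::approx(f, py, fg)$y
    f <- fg
  }
  Fx <- pracma::cumtrapz(f, px)
  Fy <- pracma::cumtrapz(f, py)
  pracma::trapz(f, abs(Fx - Fy))
}

#' Normalized PSD mean squared error per channel
#'
#' Welch PSDs are band-limited to the spec's band and L1-normalized over it
#' (probability-like spectral envelopes); the metric is the discrete mean
#' squared error between the envelopes on the Welch frequency grid.
#'
#' @inheritParams spectral_kl
#' @return Numeric vector of length C.
#' @export
psd_mse <- function(x, y, fs, spec = welch_spec()) {
  x <- as.matrix(x); y <- as.matrix(y)
  stopifnot(ncol(x) == ncol(y))
  vapply(seq_len(ncol(x)), function(j) {
    bx <- band_psd(x[, j], fs, spec)
    by <- band_psd(y[, j], fs, spec)
    Px <- bx$psd / pracma::trapz(bx$freq, bx$psd)
    Py <- by$psd / pracma::trapz(by$freq, by$psd)
    mean((Px - Py)^2)
  }, numeric(1))
}

#' Spectral earth mover's distance per channel (Hz)
#'
#' Band-limited Welch PSDs are normalized to probability densities over
#' frequency; the EMD is the area between their cumulative distribution
#' functions over the band, integrated by the trapezoidal rule on the Welch
#' grid.
#'
#' @inheritParams spectral_kl
#' @return Numeric vector of length C, in Hz.
#' @export
spectral_emd <- function(x, y, fs, spec = welch_spec()) {
  x <- as.matrix(x); y <- as.matrix(y)
  stopifnot(ncol(x) == ncol(y))
  vapply(seq_len(ncol(x)), function(j) {
    bx <- band_psd(x[, j], fs, spec)
    by <- band_psd(y[, j], fs, spec)
    emd_cdf_area(bx$freq, bx$psd, by$psd)
  }, numeric(1))
}

#' FID feature-extraction settings
#'
#' @param win_sec,hop_sec Short-window length and hop in seconds.
#' @param nfft FFT length of the per-window periodogram.
#' @param ar_order Autoregressive model order (Yule-Walker).
#' @param shrink Diagonal loading factor for the covariance matrices,
#'   relative to the mean diagonal.
#' @return A `fid_spec` list.
#' @export
fid_spec <- function(win_sec = 0.30, hop_sec = 0.15, nfft = 256L,
                     ar_order = 4L, shrink = 1e-6) {
  structure(list(win_sec = win_sec, hop_sec = hop_sec, nfft = as.integer(nfft),
                 ar_order = as.integer(ar_order), shrink = shrink,
                 band = c(0.5, 45)), class = "fid_spec")
}

#' Spectral-temporal features for the Frechet distance
#'
#' Per 0.30 s window (0.15 s hop): five log band-energy integrals (delta,
#' theta, alpha, beta, gamma), spectral centroid and spectral entropy of the
#' band-normalized periodogram, time-domain RMS, and AR(4) coefficients
#' estimated by Yule-Walker - a 12-dimensional embedding per window.
#'
#' @param x Numeric vector (one channel).
#' @param fs Sampling rate in Hz.
#' @param spec A [fid_spec()].
#' @return `[n_windows, 12]` feature matrix.
#' @export
fid_features <- function(x, fs, spec = fid_spec()) {
  win <- as.integer(round(spec$win_sec * fs))
  hop <- max(1L, as.integer(round(spec$hop_sec * fs)))
  n <- length(x)
  if (n < win) stop("signal shorter than one ", spec$win_sec, " s feature window")
  if (win <= spec$ar_order + 1L) stop("window too short for AR(", spec$ar_order, ")")
  starts <- seq(1L, n - win + 1L, by = hop)
  feats <- matrix(NA_real_, length(starts), 5L + 3L + spec$ar_order)
  colnames(feats) <- c(paste0("logE_", names(eeg_bands)), "centroid", "entropy",
                       "rms", paste0("ar", seq_len(spec$ar_order)))
  for (i in seq_along(starts)) {
    seg <- x[starts[i]:(starts[i] + win - 1L)]
    w <- welch_psd(seg, fs, seg_len = win, overlap = 0, window = "hamming",
                   nfft = max(spec$nfft, win))
    bw <- welch_band(w$freq, w$psd, spec$band)
    f <- bw$freq; p <- bw$psd
    bp <- vapply(eeg_bands, function(b) {
      sel <- f >= b[1] & f < b[2]
      if (!any(sel)) return(0)
      sum(p[sel]) * (f[2] - f[1])
    }, numeric(1))
    pn <- p / sum(p)
    centroid <- sum(f * pn)
    entropy <- -sum(ifelse(pn > 0, pn * log(pn), 0))
    rms <- sqrt(mean(seg^2))
    ar <- yule_walker(seg, spec$ar_order)
    feats[i, ] <- c(log(pmax(bp, 1e-12)), centroid, entropy, rms, ar)
  }
  feats
}

#' Yule-Walker autoregressive coefficients
#'
#' Solves the Toeplitz system `R a = r` built from the biased sample
#' autocovariances of the demeaned series (the classical Yule-Walker
#' estimator). A (near-)constant series returns zero coefficients.
#'
#' @param x Numeric vector.
#' @param order AR order.
#' @return Coefficient vector of length `order`.
#' @export
yule_walker <- function(x, order = 4L) {
  n <- length(x)
  if (n <= order + 1L) stop("series too short for AR(", order, ")")
  xc <- x - mean(x)
  r <- vapply(0:order, function(k) sum(xc[seq_len(n - k)] * xc[(k + 1L):n]) / n,
              numeric(1))
  if (r[1L] < 1e-24) return(rep(0, order))
  R <- stats::toeplitz(r[seq_len(order)])
  as.numeric(solve(R, r[2:(order + 1L)]))
}

# Trace of sqrtm(C1 %*% C2) for symmetric PSD C1, C2, computed entirely by
# SVD: sqrt(C1) from the SVD of C1, then the SVD of the symmetrized product
# sqrt(C1) C2 sqrt(C1), whose singular values are the eigenvalues of C1 C2.
tr_sqrt_product <- function(C1, C2) {
  s1 <- svd(C1)
  sq1 <- s1$u %*% (sqrt(pmax(s1$d, 0)) * t(s1$u))
  M <- sq1 %*% C2 %*% sq1
  M <- (M + t(M)) / 2
  sum(sqrt(pmax(svd(M)$d, 0)))
}

#' Frechet distance between two feature sets
#'
#' Features from both sides are pooled and z-normalized feature-wise, split
#' back, and summarized by their means and covariances; covariances are
#' symmetrized and diagonally loaded. The distance is
#' `||mu1 - mu2||^2 + Tr(C1 + C2 - 2 (C1 C2)^{1/2})` with an SVD-based
#' matrix square root; tiny negative residue is clamped to zero.
#'
#' @param feat_real,feat_gen `[n, d]` feature matrices (e.g. from
#'   [fid_features()]).
#' @param shrink Diagonal loading factor relative to the mean diagonal.
#' @param normalize Pool and z-normalize the features first (the evaluation
#'   protocol); set `FALSE` to evaluate the Gaussian Frechet formula on the
#'   features as given.
#' @return Non-negative scalar.
#' @export
fid_distance <- function(feat_real, feat_gen, shrink = 1e-6, normalize = TRUE) {
  stopifnot(ncol(feat_real) == ncol(feat_gen),
            nrow(feat_real) >= 2L, nrow(feat_gen) >= 2L)
  pooled <- rbind(feat_real, feat_gen)
  if (normalize) {
    mu <- colMeans(pooled)
    sd_ <- apply(pooled, 2L, stats::sd)
    sd_[sd_ < 1e-12] <- 1
    z <- sweep(sweep(pooled, 2L, mu, "-"), 2L, sd_, "/")
  } else z <- pooled
  n1 <- nrow(feat_real)
  z1 <- z[seq_len(n1), , drop = FALSE]
  z2 <- z[-seq_len(n1), , drop = FALSE]
  mu1 <- colMeans(z1); mu2 <- colMeans(z2)
  C1 <- stats::cov(z1); C2 <- stats::cov(z2)
  C1 <- (C1 + t(C1)) / 2; C2 <- (C2 + t(C2)) / 2
  C1 <- C1 + diag(shrink * mean(diag(C1)) + 1e-12, ncol(C1))
  C2 <- C2 + diag(shrink * mean(diag(C2)) + 1e-12, ncol(C2))
  val <- sum((mu1 - mu2)^2) + sum(diag(C1)) + sum(diag(C2)) -
    2 * tr_sqrt_product(C1, C2)
  max(val, 0)
}

#' Evaluate generated windows against real windows
#'
#' Paired mode computes Pearson and Spearman correlations per window pair
#' and channel (averaged over windows); unpaired mode skips them with a
#' notice. The spectral metrics (KL, PSD-MSE, EMD) and the FID operate on
#' per-channel series built by concatenating all windows of each side, so
#' one value per channel is reported, and FID features are extracted from
#' short windows of those series.
#'
#' @param real,generated [window_batch()] objects with equal channel counts
#'   (and equal window counts in paired mode).
#' @param paired Whether windows are index-aligned (reconstruction mode).
#' @param spec A [welch_spec()] for the spectral metrics.
#' @param fspec A [fid_spec()] for the Frechet distance features.
#' @return A `metric_report`: list with `per_channel` (data frame),
#'   `aggregate` (mean and SD per metric) and `meta`.
#' @export
evaluate_generation <- function(real, generated, paired = TRUE,
                                spec = welch_spec(), fspec = fid_spec()) {
  stopifnot(inherits(real, "eeg_window_batch"), inherits(generated, "eeg_window_batch"))
  dr <- dim(real$data); dg <- dim(generated$data)
  if (dr[3L] != dg[3L]) stop("channel-count mismatch: ", dr[3L], " vs ", dg[3L])
  C <- dr[3L]; fs <- real$fs
  pearson <- spearman <- rep(NA_real_, C)
  if (paired) {
    if (dr[1L] != dg[1L]) stop("paired evaluation requires equal window counts")
    pe <- matrix(NA_real_, dr[1L], C); sp <- matrix(NA_real_, dr[1L], C)
    for (i in seq_len(dr[1L])) {
      xw <- matrix(real$data[i, , ], dr[2L], C)
      yw <- matrix(generated$data[i, , ], dg[2L], C)
      pe[i, ] <- pearson_channels(xw, yw)
      sp[i, ] <- spearman_channels(xw, yw)
    }
    pearson <- colMeans(pe, na.rm = TRUE)
    spearman <- colMeans(sp, na.rm = TRUE)
  } else {
    message("unpaired evaluation: Pearson/Spearman skipped")
  }
  # channel series: concatenate windows (one long series per channel, per side)
  xs <- apply(real$data, 3L, function(m) as.numeric(t(m)))
  ys <- apply(generated$data, 3L, function(m) as.numeric(t(m)))
  kl <- spectral_kl(xs, ys, fs, spec)
  pm <- psd_mse(xs, ys, fs, spec)
  emd <- spectral_emd(xs, ys, fs, spec)
  fid <- vapply(seq_len(C), function(j)
    fid_distance(fid_features(xs[, j], fs, fspec),
                 fid_features(ys[, j], fs, fspec), shrink = fspec$shrink),
    numeric(1))
  per_channel <- data.frame(channel = seq_len(C), pearson = pearson,
                            spearman = spearman, kl = kl, fid = fid,
                            psd_mse = pm, emd = emd)
  agg <- do.call(rbind, lapply(c("pearson", "spearman", "kl", "fid", "psd_mse", "emd"),
    function(mn) data.frame(metric = mn,
                            mean = mean(per_channel[[mn]], na.rm = TRUE),
                            sd = stats::sd(per_channel[[mn]], na.rm = TRUE))))
  structure(list(per_channel = per_channel, aggregate = agg,
                 meta = list(paired = paired, n_real = dr[1L], n_gen = dg[1L],
                             fs = fs, kl_log = "natural",
                             welch = unclass(spec), fid = unclass(fspec))),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("<metric_report> ", x$meta$n_real, " real vs ", x$meta$n_gen,
      " generated windows (", if (x$meta$paired) "paired" else "unpaired", ")\n", sep = "")
  agg <- x$aggregate
  for (i in seq_len(nrow(agg)))
    cat(sprintf("  %-8s %8.4f +/- %.4f\n", agg$metric[i], agg$mean[i], agg$sd[i]))
  invisible(x)
}

#' Write a metric report as JSON
#'
#' @param report A `metric_report`.
#' @param path Output path.
#' @export
write_metric_report <- function(report, path) {
  jsonlite::write_json(list(per_channel = report$per_channel,
                            aggregate = report$aggregate,
                            meta = report$meta),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
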