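# Welch power spectral density estimation (periodogram averaging over
# overlapping, windowed, mean-detrended segments; one-sided density scaling).

#' Welch estimator settings for the evaluation metrics
#'
#' Defaults follow the evaluation protocol: 2.0 s Hamming segments, 50%
#' overlap, 1024-point FFT, band-limited to 0.5-45 Hz.
#'
#' @param seg_sec Segment length in seconds.
#' @param window `"hamming"` or `"hann"`.
#' @param overlap Fractional overlap between consecutive segments.
#' @param nfft FFT length (zero-padded when longer than the segment).
#' @param band Frequency band `[lo, hi]` in Hz retained for the metrics.
#' @return A `welch_spec` list.
#' @export
welch_spec <- function(seg_sec = 2.0, window = "hamming", overlap = 0.5,
                       nfft = 1024L, band = c(0.5, 45)) {
  stopifnot(seg_sec > 0, overlap >= 0, overlap < 1, band[1] < band[2])
  structure(list(seg_sec = seg_sec, window = window, overlap = overlap,
                 nfft = as.integer(nfft), band = band), class = "welch_spec")
}

# Periodic window of length n (scipy convention).
welch_window <- function(n, type = c("hamming", "hann")) {
  type <- match.arg(type)
  i <- seq_len(n) - 1L
  switch(type,
         hamming = 0.54 - 0.46 * cos(2 * pi * i / n),
         hann = 0.5 - 0.5 * cos(2 * pi * i / n))
}

#' Welch power spectral density
#'
#' Averages one-sided periodograms of overlapping, windowed, mean-detrended
#' segments; density scaling (units x^2 / Hz).
#'
#' @param x Numeric vector (one channel).
#' @param fs Sampling rate in Hz.
#' @param seg_len Segment length in samples.
#' @param overlap Fractional overlap.
#' @param window `"hamming"` or `"hann"`.
#' @param nfft FFT length; defaults to `seg_len`.
#' @param detrend Remove each segment's mean before windowing.
#' @return List with `freq` (Hz) and `psd`.
#' @export
welch_psd <- function(x, fs, seg_len, overlap = 0.5,
                      window = c("hamming", "hann"), nfft = NULL,
                      detrend = TRUE) {
  window <- match.arg(window)
  n <- length(x)
  seg_len <- as.integer(seg_len)
  if (n < seg_len)
    stop("signal of length ", n, " shorter than one Welch segment (", seg_len, ")")
  res <- welch_psd_mat(matrix(x, ncol = 1L), fs, seg_len, overlap, window,
                       nfft = nfft, detrend = detrend)
  list(freq = res$freq, psd = drop(res$psd))
}

# Vectorized Welch over columns of a matrix; optionally returns the cached
# per-segment FFTs needed for the spectrum-loss gradient.
welch_psd_mat <- function(xm, fs, seg_len, overlap = 0.5, window = "hamming",
                          nfft = NULL, detrend = TRUE, keep_fft = FALSE) {
  n <- nrow(xm); m <- ncol(xm)
  hop <- max(1L, as.integer(round(seg_len * (1 - overlap))))
  nseg <- (n - seg_len) %/% hop + 1L
  if (is.null(nfft)) nfft <- seg_len
  nfft <- as.integer(nfft)
  stopifnot(nfft >= seg_len)
  w <- welch_window(seg_len, window)
  U <- sum(w^2)
  nb <- nfft %/% 2L + 1L
  sk <- rep(2, nb); sk[1L] <- 1
  if (nfft %% 2L == 0L) sk[nb] <- 1
  psd <- matrix(0, nb, m)
  ffts <- if (keep_fft) vector("list", nseg)
  for (s in seq_len(nseg)) {
    idx <- ((s - 1L) * hop + 1L):((s - 1L) * hop + seg_len)
    seg <- xm[idx, , drop = FALSE]
    if (detrend) seg <- sweep(seg, 2L, colMeans(seg), "-")
    seg <- seg * w
    if (nfft > seg_len) seg <- rbind(seg, matrix(0, nfft - seg_len, m))
    X <- stats::mvfft(seg)
    psd <- psd + sk * (Mod(X[seq_len(nb), , drop = FALSE])^2) / (fs * U)
    if (keep_fft) ffts[[s]] <- X
  }
  psd <- psd / nseg
  list(freq = (seq_len(nb) - 1L) * fs / nfft, psd = psd,
       ffts = ffts, w = w, U = U, hop = hop, nseg = nseg, nfft = nfft,
       seg_len = seg_len)
}

# Restrict a Welch result to a band; errors if no bins remain.
welch_band <- function(freq, psd, band) {
  keep <- freq >= band[1] & freq <= band[2]
  if (!any(keep)) stop("no frequency bins inside the band [",
                       band[1], ", ", band[2], "] Hz")
  list(freq = freq[keep], psd = if (is.matrix(psd)) psd[keep, , drop = FALSE] else psd[keep])
}
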