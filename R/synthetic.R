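# Synthetic EEG-like cohorts: band-limited stochastic oscillators with
# class-dependent band power over a 1/f background, linearly mixed across
# channels and per-channel z-scored. Emulates preprocessed (down-sampled,
# 0-45 Hz band-limited, z-scored) emotion-trial recordings so the whole
# pipeline is testable without external data.

#' Canonical EEG frequency bands
#'
#' delta 0.5-4, theta 4-8, alpha 8-13, beta 13-30, gamma 30-45 Hz.
#' @export
eeg_bands <- list(delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 13),
                  beta = c(13, 30), gamma = c(30, 45))

default_band_weights <- function(n_classes) {
  # Relative log-power per band; classes differ mainly in alpha/beta balance
  # (negative / neutral / positive emulation). Extra classes interpolate.
  base <- list(
    c(delta = 0.8, theta = 0.4, alpha = -0.2, beta = -0.4, gamma = -1.2),
    c(delta = 0.6, theta = 0.2, alpha = 0.8, beta = -0.8, gamma = -1.4),
    c(delta = 0.6, theta = 0.3, alpha = 0.2, beta = 0.4, gamma = -0.9))
  lapply(seq_len(n_classes), function(k) base[[(k - 1L) %% 3L + 1L]])
}

#' Synthetic cohort configuration
#'
#' @param n_trials Number of trials in the cohort.
#' @param trial_len Trial length in samples.
#' @param n_channels Number of channels.
#' @param fs Sampling rate in Hz (default 200).
#' @param n_classes Number of label classes (default 3).
#' @param band_weights List of length `n_classes`; each element a named
#'   numeric vector over exactly `delta, theta, alpha, beta, gamma` giving
#'   the relative log-power of that band (`-Inf` disables a band).
#' @param one_over_f_exponent Spectral slope of the background noise.
#' @param channel_mixing Mixing strength in `[0, 1]`: 0 keeps channels
#'   independent, 1 fully mixes through a random orthogonal matrix.
#' @param noise_sd Standard deviation of the 1/f background component.
#' @param seed Cohort seed; every trial derives its own stream from it.
#' @return A `synthetic_cohort_config`.
#' @export
synthetic_cohort_config <- function(n_trials = 90L, trial_len = 2000L,
                                    n_channels = 8L, fs = 200,
                                    n_classes = 3L, band_weights = NULL,
                                    one_over_f_exponent = 1.0,
                                    channel_mixing = 0.5, noise_sd = 0.5,
                                    seed = 1L) {
  if (fs <= 0) stop("fs must be positive")
  if (n_trials < 1L || trial_len < 1L || n_channels < 1L)
    stop("n_trials, trial_len and n_channels must be positive")
  if (n_classes < 2L) stop("n_classes must be at least 2")
  if (channel_mixing < 0 || channel_mixing > 1) stop("channel_mixing must be in [0, 1]")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (is.null(band_weights)) band_weights <- default_band_weights(n_classes)
  if (length(band_weights) != n_classes)
    stop("band_weights must have one element per class")
  for (w in band_weights) {
    if (!setequal(names(w), names(eeg_bands)))
      stop("band_weights names must be exactly: ", paste(names(eeg_bands), collapse = ", "))
  }
  cfg <- list(n_trials = as.integer(n_trials), trial_len = as.integer(trial_len),
              n_channels = as.integer(n_channels), fs = fs,
              n_classes = as.integer(n_classes), band_weights = band_weights,
              one_over_f_exponent = one_over_f_exponent,
              channel_mixing = channel_mixing, noise_sd = noise_sd,
              seed = as.integer(seed))
  class(cfg) <- "synthetic_cohort_config"
  cfg
}

trial_stream_seed <- function(cohort_seed, trial_seed, label) {
  as.integer((abs(cohort_seed) * 1000003 + abs(trial_seed) * 97 + label) %% 2147483647)
}

# Fixed per-cohort mixing matrix: convex blend of identity and a random
# orthogonal matrix (QR of a Gaussian draw).
mixing_matrix <- function(cfg) {
  C <- cfg$n_channels
  if (C == 1L) return(matrix(1, 1, 1))
  old <- .Random.seed_save()
  set.seed(trial_stream_seed(cfg$seed, 0L, 0L))
  Q <- qr.Q(qr(matrix(stats::rnorm(C * C), C, C)))
  .Random.seed_restore(old)
  (1 - cfg$channel_mixing) * diag(C) + cfg$channel_mixing * Q
}

# 1/f^a-shaped background, low-passed above the gamma edge, scaled to unit SD.
one_over_f_noise <- function(n, fs, expo) {
  wn <- stats::rnorm(n)
  X <- stats::fft(wn)
  f <- (seq_len(n) - 1L) * fs / n
  f <- pmin(f, fs - f)                      # two-sided frequency magnitude
  mag <- pmax(f, 0.5)^(-expo / 2)
  mag[1L] <- 0                              # kill DC
  hi <- f > 45
  mag[hi] <- mag[hi] * exp(-(f[hi] - 45) / 1.5)
  x <- Re(stats::fft(X * mag, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s > 0) x / s else x
}

# White noise band-passed with a zero-phase 4th-order Butterworth filter,
# rescaled to an exact target SD.
band_oscillator <- function(n, fs, band, target_sd) {
  if (!is.finite(target_sd) || target_sd <= 0) return(numeric(n))
  wn <- stats::rnorm(n)
  ny <- fs / 2
  bf <- signal::butter(4, c(band[1], band[2]) / ny, type = "pass")
  x <- signal::filtfilt(bf, wn)
  s <- stats::sd(x)
  if (s == 0) return(numeric(n))
  x / s * target_sd
}

#' Generate one synthetic trial
#'
#' Each channel source is a sum of five band-limited stochastic oscillators
#' (per-band SD `exp(0.5 * band_weights[[label + 1]])`) plus a 1/f
#' background of SD `noise_sd`; sources are mixed across channels by the
#' cohort's fixed mixing matrix and each channel is z-scored. Deterministic
#' given `(cfg$seed, trial_seed, label)`.
#'
#' @param cfg A [synthetic_cohort_config()].
#' @param label Integer class label in `{0, ..., n_classes - 1}`.
#' @param trial_seed Integer stream index of the trial.
#' @return An `eeg_trial` (see [eeg_trial()]).
#' @export
generate_trial <- function(cfg, label, trial_seed) {
  stopifnot(inherits(cfg, "synthetic_cohort_config"))
  label <- as.integer(label)
  if (label < 0L || label >= cfg$n_classes)
    stop("label ", label, " outside {0, ..., ", cfg$n_classes - 1L, "}")
  A <- mixing_matrix(cfg)
  w <- cfg$band_weights[[label + 1L]]
  old <- .Random.seed_save()
  set.seed(trial_stream_seed(cfg$seed, trial_seed, label + 1L))
  n <- cfg$trial_len
  S <- matrix(0, n, cfg$n_channels)
  for (ch in seq_len(cfg$n_channels)) {
    x <- if (cfg$noise_sd > 0) cfg$noise_sd * one_over_f_noise(n, cfg$fs, cfg$one_over_f_exponent) else numeric(n)
    for (bn in names(eeg_bands))
      x <- x + band_oscillator(n, cfg$fs, eeg_bands[[bn]], exp(0.5 * w[[bn]]))
    S[, ch] <- x
  }
  .Random.seed_restore(old)
  X <- S %*% t(A)
  X <- scale(X)                             # per-channel z-score
  attr(X, "scaled:center") <- NULL
  attr(X, "scaled:scale") <- NULL
  eeg_trial(X, fs = cfg$fs, label = label,
            subject = "sim", session = "1")
}

#' Generate a class-balanced synthetic cohort
#'
#' Class counts differ by at most one (extra trials go to the lower class
#' indices when `n_trials` is not divisible by `n_classes`); trials are
#' independently seeded from the cohort seed.
#'
#' @param cfg A [synthetic_cohort_config()].
#' @return List of `eeg_trial` objects with attribute `"config"`.
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_cohort_config"))
  K <- cfg$n_classes
  base <- cfg$n_trials %/% K
  counts <- rep(base, K) + as.integer(seq_len(K) <= cfg$n_trials %% K)
  labels <- rep(seq_len(K) - 1L, times = counts)
  trials <- lapply(seq_along(labels), function(i)
    generate_trial(cfg, labels[i], trial_seed = i))
  attr(trials, "config") <- cfg
  trials
}

#' Write a cohort to disk as EDF files plus a manifest
#'
#' One EDF per trial, with `label=<k> subject=<id> session=<id>` stored in
#' the recording-id header field, and a tab-separated `trials.tsv` manifest
#' (columns `file`, `label`, `subject`, `session`).
#'
#' @param cohort List of `eeg_trial` objects (e.g. from [generate_cohort()]).
#' @param dir Output directory (created if missing).
#' @return Path of the manifest, invisibly.
#' @export
write_cohort_edf <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- vector("list", length(cohort))
  for (i in seq_along(cohort)) {
    tr <- cohort[[i]]
    fn <- sprintf("trial%03d.edf", i)
    rid <- sprintf("label=%d subject=%s session=%s", tr$label, tr$subject, tr$session)
    write_edf(tr$signal, tr$fs, file.path(dir, fn), recording_id = rid)
    rows[[i]] <- data.frame(file = fn, label = tr$label, subject = tr$subject,
                            session = tr$session, stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  mp <- file.path(dir, "trials.tsv")
  utils::write.table(manifest, mp, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(mp)
}
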