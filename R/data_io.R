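# Trials, window batches, preprocessing (per-channel z-scoring, sliding
# windows with label inheritance) and on-disk exchange (EDF cohorts with a
# TSV manifest; RDS window archives).

#' EEG trial container
#'
#' @param signal `[time, channels]` numeric matrix (z-units after
#'   preprocessing).
#' @param fs Sampling rate in Hz.
#' @param label Integer class label (0-based).
#' @param subject,session Identifier strings.
#' @return An `eeg_trial` list.
#' @export
eeg_trial <- function(signal, fs, label, subject = "", session = "") {
  if (!is.matrix(signal) || nrow(signal) < 1L || ncol(signal) < 1L)
    stop("signal must be a [time, channels] matrix with at least one sample and channel")
  if (fs <= 0) stop("fs must be positive")
  structure(list(signal = signal, fs = fs, label = as.integer(label),
                 subject = as.character(subject), session = as.character(session)),
            class = "eeg_trial")
}

#' @export
print.eeg_trial <- function(x, ...) {
  cat("<eeg_trial> ", nrow(x$signal), " samples x ", ncol(x$signal),
      " channels @ ", x$fs, " Hz, label ", x$label, "\n", sep = "")
  invisible(x)
}

#' Per-channel z-score normalization
#'
#' Standardizes each channel within the trial to mean 0, SD 1. Applied at
#' trial level, before windowing; windows are not re-normalized.
#'
#' @param trial An [eeg_trial()].
#' @param constant Policy for a zero-variance channel: `"error"` (default;
#'   silent zeros can hide dead electrodes) or `"zero"` (output zeros with a
#'   warning).
#' @return The z-scored `eeg_trial`.
#' @export
zscore_per_channel <- function(trial, constant = c("error", "zero")) {
  constant <- match.arg(constant)
  x <- trial$signal
  s <- apply(x, 2L, stats::sd)
  flat <- s < 1e-12
  if (any(flat)) {
    if (constant == "error")
      stop("constant channel(s): ", paste(which(flat), collapse = ", "),
           "; set constant = \"zero\" to zero them instead")
    warning("constant channel(s) ", paste(which(flat), collapse = ", "),
            " set to zero")
    s[flat] <- 1
  }
  z <- sweep(sweep(x, 2L, colMeans(x), "-"), 2L, s, "/")
  z[, flat] <- 0
  trial$signal <- z
  trial
}

#' Window batch container
#'
#' @param data `[B, T, C]` array of windows.
#' @param labels Integer vector of length B (0-based class indices).
#' @param fs Sampling rate in Hz.
#' @param provenance Optional data frame with one row per window
#'   (`trial_id`, `start`).
#' @return An `eeg_window_batch`.
#' @export
window_batch <- function(data, labels, fs, provenance = NULL) {
  if (length(dim(data)) != 3L) stop("data must be a [B, T, C] array")
  if (dim(data)[1L] != length(labels)) stop("one label per window required")
  if (is.null(provenance))
    provenance <- data.frame(trial_id = rep(NA_character_, length(labels)),
                             start = rep(NA_integer_, length(labels)))
  structure(list(data = data, labels = as.integer(labels), fs = fs,
                 provenance = provenance),
            class = "eeg_window_batch")
}

#' @export
print.eeg_window_batch <- function(x, ...) {
  d <- dim(x$data)
  cat("<eeg_window_batch> ", d[1L], " windows of [", d[2L], " x ", d[3L],
      "] @ ", x$fs, " Hz; labels: ",
      paste(sprintf("%d:%d", sort(unique(x$labels)),
                    tabulate(x$labels + 1L, max(x$labels) + 1L)[sort(unique(x$labels)) + 1L]),
            collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Sliding-window segmentation with label inheritance
#'
#' Windows start at offsets `0, hop, 2*hop, ...`; the count is
#' `floor((N - win_len) / hop) + 1`. Every window inherits the label of its
#' parent trial. A trial shorter than `win_len` yields an empty batch with a
#' warning (not an error), so ragged cohorts survive.
#'
#' @param trial An [eeg_trial()].
#' @param win_len Window length in samples (default 400).
#' @param hop Step size in samples (default 200).
#' @param trial_id Identifier recorded in the provenance table.
#' @return An [window_batch()].
#' @export
segment_windows <- function(trial, win_len = 400L, hop = 200L, trial_id = "trial") {
  stopifnot(hop >= 1L, win_len >= 1L)
  N <- nrow(trial$signal); C <- ncol(trial$signal)
  if (N < win_len) {
    warning("trial of ", N, " samples shorter than window (", win_len,
            "); returning empty batch")
    return(window_batch(array(0, dim = c(0L, win_len, C)), integer(0), trial$fs,
                        data.frame(trial_id = character(0), start = integer(0))))
  }
  n_win <- (N - win_len) %/% hop + 1L
  starts <- (seq_len(n_win) - 1L) * hop
  data <- array(0, dim = c(n_win, win_len, C))
  for (i in seq_len(n_win))
    data[i, , ] <- trial$signal[(starts[i] + 1L):(starts[i] + win_len), ]
  window_batch(data, rep(trial$label, n_win), trial$fs,
               data.frame(trial_id = rep(trial_id, n_win), start = starts))
}

#' Segment every trial of a cohort into one window batch
#'
#' @param trials List of [eeg_trial()] objects.
#' @inheritParams segment_windows
#' @return An [window_batch()] combining all windows.
#' @export
segment_cohort <- function(trials, win_len = 400L, hop = 200L) {
  batches <- lapply(seq_along(trials), function(i)
    segment_windows(trials[[i]], win_len, hop, trial_id = sprintf("trial%03d", i)))
  batches <- Filter(function(b) dim(b$data)[1L] > 0L, batches)
  if (!length(batches)) stop("no trial long enough for one window")
  C <- dim(batches[[1L]]$data)[3L]
  for (b in batches) if (dim(b$data)[3L] != C)
    stop("channel-count mismatch across trials: ", dim(b$data)[3L], " vs ", C)
  n <- sum(vapply(batches, function(b) dim(b$data)[1L], integer(1)))
  data <- array(0, dim = c(n, win_len, C))
  labels <- integer(n); prov <- vector("list", length(batches))
  at <- 0L
  for (j in seq_along(batches)) {
    b <- batches[[j]]; nb <- dim(b$data)[1L]
    data[(at + 1L):(at + nb), , ] <- b$data
    labels[(at + 1L):(at + nb)] <- b$labels
    prov[[j]] <- b$provenance
    at <- at + nb
  }
  window_batch(data, labels, batches[[1L]]$fs, do.call(rbind, prov))
}

#' Save / load a window-batch archive
#'
#' Single-file container holding the named arrays `data`, `labels`, `fs`
#' and the `provenance` table; the round-trip is bitwise exact.
#'
#' @param batch An [window_batch()].
#' @param path Archive file path (RDS).
#' @return `load_window_batch()` returns the `eeg_window_batch`.
#' @export
save_window_batch <- function(batch, path) {
  stopifnot(inherits(batch, "eeg_window_batch"))
  saveRDS(list(format = "tcvaegan-windows", version = 1L,
               data = batch$data, labels = batch$labels, fs = batch$fs,
               provenance = batch$provenance), path)
  invisible(path)
}

#' @rdname save_window_batch
#' @export
load_window_batch <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "tcvaegan-windows"))
    stop("not a window archive: ", path)
  window_batch(obj$data, obj$labels, obj$fs, obj$provenance)
}

#' Load a cohort from a manifest of EDF files
#'
#' Reads the tab-separated manifest (columns `file`, `label`, `subject`,
#' `session`), loads each EDF and maps labels to 0-based class indices.
#' String labels require an explicit `label_map` (e.g.
#' `c(negative = 0, neutral = 1, positive = 2)`); guessing is refused.
#'
#' @param manifest Path to `trials.tsv`.
#' @param label_map Optional named integer vector mapping label strings to
#'   class indices.
#' @param orientation `"time_by_channel"` (default) or `"channel_by_time"`;
#'   stored trial matrices are transposed to `[time, channels]` when needed.
#' @return List of [eeg_trial()] objects.
#' @export
load_cohort <- function(manifest, label_map = NULL,
                        orientation = c("time_by_channel", "channel_by_time")) {
  orientation <- match.arg(orientation)
  if (!file.exists(manifest)) stop("manifest not found: ", manifest)
  tab <- utils::read.delim(manifest, stringsAsFactors = FALSE)
  need <- c("file", "label", "subject", "session")
  if (!all(need %in% names(tab)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  base <- dirname(manifest)
  trials <- vector("list", nrow(tab))
  n_ch <- NULL
  for (i in seq_len(nrow(tab))) {
    fp <- file.path(base, tab$file[i])
    if (!file.exists(fp))
      stop("manifest row ", i, ": file not found: ", tab$file[i])
    lab <- tab$label[i]
    if (!is.null(label_map)) {
      if (!as.character(lab) %in% names(label_map))
        stop("manifest row ", i, ": label '", lab, "' not in label_map")
      lab <- label_map[[as.character(lab)]]
    } else if (is.na(suppressWarnings(as.integer(lab)))) {
      stop("manifest row ", i, ": string label '", lab,
           "' requires an explicit label_map")
    } else lab <- as.integer(lab)
    if (lab < 0L) stop("manifest row ", i, ": negative label index")
    e <- read_edf(fp)
    sig <- e$signal
    if (orientation == "channel_by_time") sig <- t(sig)
    if (is.null(n_ch)) n_ch <- ncol(sig)
    else if (ncol(sig) != n_ch)
      stop("manifest row ", i, ": channel-count mismatch (", ncol(sig),
           " vs ", n_ch, ")")
    trials[[i]] <- eeg_trial(sig, e$fs, lab, tab$subject[i], tab$session[i])
  }
  trials
}
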