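# End-to-end pipeline: simulate -> preprocess -> train -> sample ->
# evaluate -> downstream, driven by a YAML config with blocks `data:`,
# `model:`, `objectives:`, `train:`, `metrics:`, `downstream:`. Every run
# writes a frozen copy of its resolved configuration and line-delimited
# JSON stage logs into the run directory.

pipeline_blocks <- list(
  data = c("n_trials", "trial_len", "n_channels", "fs", "n_classes",
           "noise_sd", "channel_mixing", "one_over_f_exponent",
           "win_len", "hop", "write_edf", "manifest", "label_map"),
  model = c("d_embed", "n_heads", "n_layers", "d_ff", "latent_dim", "dropout",
            "disc_channels", "disc_fc", "disc_leaky", "cnn_channels", "ablation"),
  objectives = c("seg_sec", "overlap", "clip_lo", "clip_hi"),
  train = c("lr_G", "lr_D", "beta1", "beta2", "batch_size", "epochs",
            "g_steps_per_iter", "d_steps_per_iter"),
  metrics = c("seg_sec", "window", "overlap", "nfft", "band_lo", "band_hi"),
  downstream = c("ratio", "epochs", "batch_size", "channels"))

#' Read and validate a pipeline configuration
#'
#' Unknown keys are rejected with the offending name; omitted keys fall
#' back to package defaults.
#'
#' @param path YAML file path.
#' @return Validated config list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  top_allowed <- c("seed", "out_dir", names(pipeline_blocks))
  bad <- setdiff(names(cfg), top_allowed)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  for (blk in names(pipeline_blocks)) {
    if (is.null(cfg[[blk]])) next
    bad <- setdiff(names(cfg[[blk]]), pipeline_blocks[[blk]])
    if (length(bad))
      stop("unknown key(s) in '", blk, "': ", paste(bad, collapse = ", "))
  }
  if (!is.null(cfg$train$lr_G) && cfg$train$lr_G <= 0) stop("train$lr_G must be positive")
  if (!is.null(cfg$train$lr_D) && cfg$train$lr_D <= 0) stop("train$lr_D must be positive")
  class(cfg) <- c("run_config", class(cfg))
  cfg
}

cfg_get <- function(cfg, blk, key, default) {
  v <- cfg[[blk]][[key]]
  if (is.null(v)) default else v
}

jsonl_log <- function(path, stage, ...) {
  rec <- c(list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), stage = stage),
           list(...))
  cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n", file = path, append = TRUE)
}

#' Run the full pipeline
#'
#' @param config Path to a YAML config or a list from [read_run_config()].
#' @param out_dir Output directory (overrides the config's `out_dir`).
#' @param seed Global seed (overrides the config's `seed`).
#' @return Invisibly, a list with the run directory and the main artifacts
#'   (checkpoint, metric reports, downstream scores).
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = NULL) {
  cfg <- if (is.character(config)) read_run_config(config) else config
  seed <- as.integer(seed %||% cfg$seed %||% 1L)
  out_dir <- out_dir %||% cfg$out_dir %||% "tcvaegan_run"
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.jsonl")
  resolved <- unclass(cfg); resolved$seed <- seed; resolved$out_dir <- out_dir
  yaml::write_yaml(resolved, file.path(out_dir, "config.resolved.yaml"))

  # -- simulate / load --
  win_len <- as.integer(cfg_get(cfg, "data", "win_len", 400L))
  hop <- as.integer(cfg_get(cfg, "data", "hop", 200L))
  manifest <- cfg_get(cfg, "data", "manifest", NULL)
  if (is.null(manifest)) {
    scfg <- synthetic_cohort_config(
      n_trials = as.integer(cfg_get(cfg, "data", "n_trials", 18L)),
      trial_len = as.integer(cfg_get(cfg, "data", "trial_len", 1000L)),
      n_channels = as.integer(cfg_get(cfg, "data", "n_channels", 8L)),
      fs = cfg_get(cfg, "data", "fs", 200),
      n_classes = as.integer(cfg_get(cfg, "data", "n_classes", 3L)),
      noise_sd = cfg_get(cfg, "data", "noise_sd", 0.5),
      channel_mixing = cfg_get(cfg, "data", "channel_mixing", 0.5),
      one_over_f_exponent = cfg_get(cfg, "data", "one_over_f_exponent", 1.0),
      seed = seed)
    trials <- generate_cohort(scfg)
    if (isTRUE(cfg_get(cfg, "data", "write_edf", FALSE)))
      write_cohort_edf(trials, file.path(out_dir, "cohort"))
    jsonl_log(log_path, "simulate", n_trials = length(trials))
  } else {
    lm <- cfg_get(cfg, "data", "label_map", NULL)
    if (!is.null(lm)) lm <- unlist(lm)
    trials <- load_cohort(manifest, label_map = lm)
    jsonl_log(log_path, "load", n_trials = length(trials))
  }

  # -- preprocess --
  trials <- lapply(trials, zscore_per_channel)
  windows <- segment_cohort(trials, win_len, hop)
  jsonl_log(log_path, "preprocess", n_windows = dim(windows$data)[1L])

  # -- train --
  d <- dim(windows$data)
  mcfg <- model_config(
    T = d[2L], C = d[3L],
    n_class = length(unique(windows$labels)),
    d_embed = as.integer(cfg_get(cfg, "model", "d_embed", 256L)),
    n_heads = as.integer(cfg_get(cfg, "model", "n_heads", 4L)),
    n_layers = as.integer(cfg_get(cfg, "model", "n_layers", 2L)),
    d_ff = as.integer(cfg_get(cfg, "model", "d_ff",
                              4L * as.integer(cfg_get(cfg, "model", "d_embed", 256L)))),
    latent_dim = as.integer(cfg_get(cfg, "model", "latent_dim", 128L)),
    dropout = cfg_get(cfg, "model", "dropout", 0.1),
    disc_channels = as.integer(unlist(cfg_get(cfg, "model", "disc_channels", c(32L, 64L, 64L)))),
    disc_fc = as.integer(cfg_get(cfg, "model", "disc_fc", 256L)),
    ablation = cfg_get(cfg, "model", "ablation", "none"))
  tcfg <- train_config(
    lr_G = cfg_get(cfg, "train", "lr_G", 1e-3),
    lr_D = cfg_get(cfg, "train", "lr_D", 1e-4),
    betas = c(cfg_get(cfg, "train", "beta1", 0.9), cfg_get(cfg, "train", "beta2", 0.999)),
    batch_size = as.integer(cfg_get(cfg, "train", "batch_size", 64L)),
    epochs = as.integer(cfg_get(cfg, "train", "epochs", 100L)),
    g_steps_per_iter = as.integer(cfg_get(cfg, "train", "g_steps_per_iter", 2L)),
    d_steps_per_iter = as.integer(cfg_get(cfg, "train", "d_steps_per_iter", 1L)),
    seed = seed)
  model <- fit_tcvaegan(windows, mcfg, tcfg,
                        log_csv = file.path(out_dir, "training_log.csv"))
  ckpt <- file.path(out_dir, "checkpoint.rds")
  save_checkpoint(model, ckpt, meta = list(seed = seed))
  uc <- attr(model, "update_counts")
  jsonl_log(log_path, "train", epochs = tcfg$epochs, d_updates = uc[["D"]],
            g_updates = uc[["G"]])

  # -- sample --
  recon <- sample_windows(model, mode = "reconstruction", x = windows, seed = seed)
  prior <- sample_windows(model, labels = windows$labels, mode = "prior",
                          fs = windows$fs, seed = seed)
  save_window_batch(recon, file.path(out_dir, "generated_recon.rds"))
  save_window_batch(prior, file.path(out_dir, "generated_prior.rds"))
  jsonl_log(log_path, "sample", n_recon = dim(recon$data)[1L],
            n_prior = dim(prior$data)[1L])

  # -- evaluate --
  wspec <- welch_spec(seg_sec = cfg_get(cfg, "metrics", "seg_sec", 2.0),
                      window = cfg_get(cfg, "metrics", "window", "hamming"),
                      overlap = cfg_get(cfg, "metrics", "overlap", 0.5),
                      nfft = as.integer(cfg_get(cfg, "metrics", "nfft", 1024L)),
                      band = c(cfg_get(cfg, "metrics", "band_lo", 0.5),
                               cfg_get(cfg, "metrics", "band_hi", 45)))
  rep_paired <- evaluate_generation(windows, recon, paired = TRUE, spec = wspec)
  rep_prior <- evaluate_generation(windows, prior, paired = FALSE, spec = wspec)
  write_metric_report(rep_paired, file.path(out_dir, "metrics_reconstruction.json"))
  write_metric_report(rep_prior, file.path(out_dir, "metrics_prior.json"))
  jsonl_log(log_path, "evaluate",
            pearson = rep_paired$aggregate$mean[rep_paired$aggregate$metric == "pearson"],
            kl_prior = rep_prior$aggregate$mean[rep_prior$aggregate$metric == "kl"])

  # -- downstream --
  ds <- augmentation_study(trials, model,
                           ratio = cfg_get(cfg, "downstream", "ratio", 1),
                           seed = seed, win_len = win_len, hop = hop,
                           epochs = as.integer(cfg_get(cfg, "downstream", "epochs", 20L)),
                           batch_size = as.integer(cfg_get(cfg, "downstream", "batch_size", 16L)))
  plan <- ds$split
  wins_all <- segment_cohort(trials, win_len, hop)
  te <- subset_windows(wins_all, plan, "test")
  tr <- subset_windows(wins_all, plan, "train")
  va <- subset_windows(wins_all, plan, "validation")
  clf <- train_classifier(tr, va, n_class = length(unique(plan$label)),
                          epochs = as.integer(cfg_get(cfg, "downstream", "epochs", 20L)),
                          batch_size = as.integer(cfg_get(cfg, "downstream", "batch_size", 16L)),
                          seed = seed)
  gen_te <- sample_windows(model, labels = te$labels, mode = "prior",
                           fs = windows$fs, seed = seed + 2L)
  cong <- congruence(clf, gen_te)
  scores <- list(real_only = unclass(ds$real_only),
                 generated_to_real = unclass(cong),
                 augmented = unclass(ds$augmented))
  jsonlite::write_json(scores, file.path(out_dir, "downstream_scores.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonl_log(log_path, "downstream",
            real_acc = ds$real_only$accuracy, congruence_acc = cong$accuracy,
            augmented_acc = ds$augmented$accuracy)

  invisible(list(out_dir = out_dir, checkpoint = ckpt,
                 metrics_reconstruction = rep_paired, metrics_prior = rep_prior,
                 downstream = scores))
}
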