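# Downstream protocols: trial-level stratified splits with window
# inheritance, a small 1-D CNN reference classifier trained on real windows
# only, frozen-classifier congruence scoring of generated windows, and the
# augmentation study (real + class-balanced generated training windows,
# validation/test kept real-only).

#' Trial-level stratified split
#'
#' Assigns whole trials to train/validation/test (default 80/10/10),
#' stratified by label; every window inherits its parent trial's split, so
#' no window of a validation or test trial can reach the training set.
#'
#' @param trials List of [eeg_trial()] objects.
#' @param fractions Length-3 fractions for train/validation/test.
#' @param seed Split seed.
#' @return A `split_plan` data frame with columns `trial_id`, `label`,
#'   `split`.
#' @export
make_split <- function(trials, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  stopifnot(abs(sum(fractions) - 1) < 1e-9)
  labels <- vapply(trials, function(t) t$label, integer(1))
  plan <- data.frame(trial_id = sprintf("trial%03d", seq_along(trials)),
                     label = labels, split = NA_character_,
                     stringsAsFactors = FALSE)
  old <- .Random.seed_save()
  set.seed(as.integer(seed))
  for (lab in sort(unique(labels))) {
    idx <- which(labels == lab)
    n <- length(idx)
    n_test <- max(1L, round(fractions[3L] * n))
    n_val <- max(1L, round(fractions[2L] * n))
    if (n - n_test - n_val < 1L)
      stop("class ", lab, " has too few trials (", n,
           ") for a stratified train/validation/test split")
    idx <- sample(idx)
    plan$split[idx[seq_len(n_test)]] <- "test"
    plan$split[idx[n_test + seq_len(n_val)]] <- "validation"
    plan$split[idx[(n_test + n_val + 1L):n]] <- "train"
  }
  .Random.seed_restore(old)
  class(plan) <- c("split_plan", class(plan))
  plan
}

#' Select the windows belonging to one split
#'
#' @param batch An [window_batch()] whose provenance `trial_id`s follow
#'   [segment_cohort()] naming.
#' @param plan A [make_split()] plan.
#' @param split `"train"`, `"validation"` or `"test"`.
#' @return An [window_batch()] subset.
#' @export
subset_windows <- function(batch, plan, split) {
  ids <- plan$trial_id[plan$split == split]
  keep <- batch$provenance$trial_id %in% ids
  window_batch(batch$data[keep, , , drop = FALSE], batch$labels[keep],
               batch$fs, batch$provenance[keep, , drop = FALSE])
}

## ---- reference CNN classifier ----

classifier_param_list <- function(C, n_class, channels, seed) {
  p <- list()
  ch <- c(C, channels)
  ks <- c(5L, 5L, 3L)
  for (i in 1:3) p <- add_conv(p, seed, sprintf("clf_c%d", i), ks[i], ch[i], ch[i + 1L])
  p <- add_linear(p, seed, "clf_out", channels[3L], n_class)
  p
}

clf_forward <- function(pl, ccfg, x2d, B) {
  T <- nrow(as_ag(x2d)$val) / B
  h <- ag_to_bct(x2d, B, T)
  h <- conv_stack_fwd(pl, "clf", h, c(5L, 5L, 3L), 0.2)
  h <- ag_gap_time(h)
  lin_fwd(pl, "clf_out", h)
}

# Softmax cross-entropy with integer targets; custom op.
ag_cross_entropy <- function(logits, y, n_class) {
  logits <- as_ag(logits)
  oh <- make_onehot(y, n_class)
  z <- logits$val
  z <- z - apply(z, 1L, max)
  ez <- exp(z)
  sm <- ez / rowSums(ez)
  B <- nrow(z)
  val <- -mean(rowSums(oh * (z - log(rowSums(ez)))))
  ag_op(val, list(logits), function(g) list(g * (sm - oh) / B))
}

#' Train the reference CNN emotion classifier on real windows
#'
#' Three stride-2 1-D convolutions (kernels 5, 5, 3) with LeakyReLU, global
#' average pooling and a linear head, trained with Adam and cross-entropy.
#' The epoch with the best validation accuracy is kept and the returned
#' classifier is frozen (scoring never changes its parameters).
#'
#' @param train_windows,val_windows [window_batch()] objects.
#' @param n_class Number of classes.
#' @param channels Convolution channel widths.
#' @param epochs,batch_size,lr Optimization settings.
#' @param seed Seed for initialization and shuffling.
#' @return An `eeg_classifier`: list with `params`, `cfg`, `history`.
#' @export
train_classifier <- function(train_windows, val_windows, n_class = 3L,
                             channels = c(16L, 32L, 32L), epochs = 30L,
                             batch_size = 16L, lr = 1e-3, seed = 1L) {
  stopifnot(inherits(train_windows, "eeg_window_batch"))
  d <- dim(train_windows$data)
  present <- sort(unique(train_windows$labels))
  missing_cls <- setdiff(seq_len(n_class) - 1L, present)
  if (length(missing_cls))
    stop("class(es) ", paste(missing_cls, collapse = ", "),
         " absent from the training set")
  ccfg <- list(C = d[3L], n_class = as.integer(n_class), channels = channels)
  set.seed(as.integer(seed))
  pl <- lapply(classifier_param_list(d[3L], n_class, channels, seed), ag_param)
  opt <- adam_init()
  n <- d[1L]
  best_acc <- -1; best_params <- NULL
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0), val_acc = numeric(0))
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / batch_size))
    eploss <- 0
    for (bi in batches) {
      xb <- btc_to_2d(train_windows$data[bi, , , drop = FALSE])
      lg <- clf_forward(pl, ccfg, ag_const(xb), length(bi))
      loss <- ag_cross_entropy(lg, train_windows$labels[bi], n_class)
      ag_backward(loss)
      opt <- adam_step(pl, opt, names(pl), lr, c(0.9, 0.999))
      ag_zero_grad(pl)
      eploss <- eploss + loss$val * length(bi)
    }
    params_now <- lapply(pl, function(p) p$val)
    clf_now <- structure(list(params = params_now, cfg = ccfg), class = "eeg_classifier")
    va <- mean(predict_classifier(clf_now, val_windows)$class == val_windows$labels)
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = eploss / n, val_acc = va))
    if (va > best_acc) { best_acc <- va; best_params <- params_now }
  }
  structure(list(params = best_params, cfg = ccfg, history = hist),
            class = "eeg_classifier")
}

#' Classifier predictions
#'
#' @param clf An `eeg_classifier`.
#' @param windows An [window_batch()].
#' @return List with `probs` (`[B, n_class]` softmax matrix) and `class`
#'   (0-based predicted labels).
#' @export
predict_classifier <- function(clf, windows) {
  d <- dim(windows$data)
  if (d[3L] != clf$cfg$C)
    stop("channel mismatch: windows have ", d[3L], ", classifier expects ", clf$cfg$C)
  pl <- lapply(clf$params, ag_const)
  lg <- clf_forward(pl, clf$cfg, ag_const(btc_to_2d(windows$data)), d[1L])$val
  z <- lg - apply(lg, 1L, max)
  ez <- exp(z)
  probs <- ez / rowSums(ez)
  list(probs = probs, class = max.col(probs) - 1L)
}

#' Macro-averaged classification scores
#'
#' Accuracy, macro precision/recall/F1 (classes with empty denominators
#' contribute 0) and macro one-vs-rest AUC computed from the rank statistic.
#'
#' @param y_true Integer true labels (0-based).
#' @param probs `[B, n_class]` probability matrix.
#' @param regime Label attached to the score set (`"real_only"`,
#'   `"generated_to_real"`, `"augmented"`).
#' @return A `classifier_scores` named list: accuracy, precision, recall,
#'   f1, auc.
#' @export
classifier_scores <- function(y_true, probs, regime = "real_only") {
  y_true <- as.integer(y_true)
  K <- ncol(probs)
  pred <- max.col(probs) - 1L
  acc <- mean(pred == y_true)
  prec <- rec <- f1 <- auc <- numeric(K)
  for (k in seq_len(K) - 1L) {
    tp <- sum(pred == k & y_true == k)
    fp <- sum(pred == k & y_true != k)
    fn <- sum(pred != k & y_true == k)
    prec[k + 1L] <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec[k + 1L] <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1[k + 1L] <- if (prec[k + 1L] + rec[k + 1L] > 0)
      2 * prec[k + 1L] * rec[k + 1L] / (prec[k + 1L] + rec[k + 1L]) else 0
    pos <- y_true == k
    n1 <- sum(pos); n0 <- sum(!pos)
    auc[k + 1L] <- if (n1 > 0 && n0 > 0) {
      r <- rank(probs[, k + 1L])
      (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    } else NA_real_
  }
  structure(list(accuracy = acc, precision = mean(prec), recall = mean(rec),
                 f1 = mean(f1), auc = mean(auc, na.rm = TRUE), regime = regime),
            class = "classifier_scores")
}

#' @export
print.classifier_scores <- function(x, ...) {
  cat(sprintf("<classifier_scores: %s> acc %.3f | prec %.3f | rec %.3f | f1 %.3f | auc %.3f\n",
              x$regime, x$accuracy, x$precision, x$recall, x$f1, x$auc))
  invisible(x)
}

#' Frozen-classifier congruence
#'
#' Scores generated windows against their conditioning labels with a
#' classifier trained only on real data. High congruence means the
#' generator preserves label-relevant structure.
#'
#' @param clf A frozen `eeg_classifier`.
#' @param generated An [window_batch()] of generated windows carrying the
#'   conditioning labels.
#' @return A `classifier_scores` with regime `"generated_to_real"`.
#' @export
congruence <- function(clf, generated) {
  if (any(generated$labels < 0L | generated$labels >= clf$cfg$n_class))
    stop("generated labels outside the classifier's class set")
  pr <- predict_classifier(clf, generated)
  classifier_scores(generated$labels, pr$probs, regime = "generated_to_real")
}

#' Augmentation study
#'
#' Trains the reference classifier on real training windows, then again on
#' real plus class-balanced generated windows (prior mode, `ratio` generated
#' windows per real training window), with identical hyperparameters and
#' seed; both are evaluated on the untouched real test split.
#'
#' @param trials Real cohort (list of [eeg_trial()]).
#' @param model Trained generator (`tcv_model`).
#' @param ratio Generated-to-real ratio (default 1).
#' @param seed Seed for split, classifier and sampling.
#' @param win_len,hop Windowing geometry.
#' @param epochs,batch_size Classifier training settings.
#' @return List with `real_only` and `augmented` `classifier_scores`, plus
#'   the `split_plan`.
#' @export
augmentation_study <- function(trials, model, ratio = 1, seed = 1L,
                               win_len = 400L, hop = 200L,
                               epochs = 20L, batch_size = 16L) {
  plan <- make_split(trials, seed = seed)
  wins <- segment_cohort(trials, win_len, hop)
  tr <- subset_windows(wins, plan, "train")
  va <- subset_windows(wins, plan, "validation")
  te <- subset_windows(wins, plan, "test")
  n_class <- length(unique(plan$label))
  clf_real <- train_classifier(tr, va, n_class = n_class, epochs = epochs,
                               batch_size = batch_size, seed = seed)
  sc_real <- classifier_scores(te$labels, predict_classifier(clf_real, te)$probs,
                               regime = "real_only")
  if (ratio > 0) {
    n_gen <- round(ratio * dim(tr$data)[1L])
    gl <- rep(seq_len(n_class) - 1L, length.out = n_gen)  # class-balanced
    gen <- sample_windows(model, labels = gl, mode = "prior", fs = wins$fs,
                          seed = seed + 1L)
    aug <- window_batch(
      abind3(tr$data, gen$data),
      c(tr$labels, gen$labels), tr$fs,
      rbind(tr$provenance, gen$provenance))
    clf_aug <- train_classifier(aug, va, n_class = n_class, epochs = epochs,
                                batch_size = batch_size, seed = seed)
  } else {
    clf_aug <- clf_real
  }
  sc_aug <- classifier_scores(te$labels, predict_classifier(clf_aug, te)$probs,
                              regime = "augmented")
  list(real_only = sc_real, augmented = sc_aug, split = plan)
}

# Bind two [B, T, C] arrays along the first axis.
abind3 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  stopifnot(all(da[-1L] == db[-1L]))
  out <- array(0, dim = c(da[1L] + db[1L], da[2L], da[3L]))
  if (da[1L] > 0) out[seq_len(da[1L]), , ] <- a
  if (db[1L] > 0) out[da[1L] + seq_len(db[1L]), , ] <- b
  out
}
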