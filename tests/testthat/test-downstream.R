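# Downstream protocols: stratified trial-level splits, leakage audits, the
# reference classifier, score oracles, congruence and augmentation.

test_that("stratified split assigns 8/1/1 trials per class for 30 trials", {
  coh <- generate_cohort(synthetic_cohort_config(n_trials = 30L, trial_len = 64L,
                                                 n_channels = 1L, seed = 41L))
  plan <- make_split(coh, seed = 1L)
  tab <- table(plan$split, plan$label)
  expect_true(all(tab["train", ] == 8L))
  expect_true(all(tab["validation", ] == 1L))
  expect_true(all(tab["test", ] == 1L))
  # determinism and seed sensitivity
  expect_identical(plan, make_split(coh, seed = 1L))
  expect_false(identical(plan$split, make_split(coh, seed = 2L)$split))
  expect_error(make_split(coh[c(1, 11, 21)], seed = 1L), "too few trials")
})

test_that("all windows of a trial share its split (inheritance)", {
  coh <- smoke_cohort()
  wins <- smoke_windows()
  plan <- make_split(coh, seed = 3L)
  for (sp in c("train", "validation", "test")) {
    sub <- subset_windows(wins, plan, sp)
    expect_true(all(sub$provenance$trial_id %in% plan$trial_id[plan$split == sp]))
  }
})

test_that("no validation/test window ever reaches the training set (audit)", {
  coh <- smoke_cohort()
  wins <- smoke_windows()
  for (s in 1:25) {
    plan <- make_split(coh, seed = s)
    tr <- subset_windows(wins, plan, "train")
    held <- plan$trial_id[plan$split != "train"]
    expect_length(intersect(tr$provenance$trial_id, held), 0L)
    n_total <- dim(subset_windows(wins, plan, "validation")$data)[1] +
      dim(subset_windows(wins, plan, "test")$data)[1] + dim(tr$data)[1]
    expect_equal(n_total, dim(wins$data)[1])
  }
})

test_that("macro scores match a brute-force confusion-matrix oracle", {
  set.seed(42)
  y <- sample(0:2, 60, replace = TRUE)
  probs <- matrix(runif(180), 60, 3)
  probs <- probs / rowSums(probs)
  sc <- classifier_scores(y, probs)
  pred <- max.col(probs) - 1L
  # oracle: per-class confusion counts
  oprec <- orec <- of1 <- numeric(3)
  for (k in 0:2) {
    tp <- sum(pred == k & y == k); fp <- sum(pred == k & y != k)
    fn <- sum(pred != k & y == k)
    oprec[k + 1] <- if (tp + fp) tp / (tp + fp) else 0
    orec[k + 1] <- if (tp + fn) tp / (tp + fn) else 0
    of1[k + 1] <- if (oprec[k + 1] + orec[k + 1])
      2 * oprec[k + 1] * orec[k + 1] / (oprec[k + 1] + orec[k + 1]) else 0
  }
  expect_equal(sc$accuracy, mean(pred == y))
  expect_equal(sc$precision, mean(oprec))
  expect_equal(sc$recall, mean(orec))
  expect_equal(sc$f1, mean(of1))
  expect_true(all(unlist(sc[c("accuracy", "precision", "recall", "f1", "auc")]) >= 0 &
                    unlist(sc[c("accuracy", "precision", "recall", "f1", "auc")]) <= 1))
})

test_that("macro one-vs-rest AUC matches the pROC oracle", {
  skip_if_not_installed("pROC")
  set.seed(43)
  y <- sample(0:2, 80, replace = TRUE)
  probs <- matrix(runif(240), 80, 3)
  probs <- probs / rowSums(probs)
  sc <- classifier_scores(y, probs)
  oracle <- mean(vapply(0:2, function(k)
    as.numeric(pROC::auc(pROC::roc(as.integer(y == k), probs[, k + 1],
                                   quiet = TRUE, direction = "<"))),
    numeric(1)))
  expect_equal(sc$auc, oracle, tolerance = 1e-12)
})

test_that("classifier learns the class-specific band structure well above chance", {
  coh <- bench_cohort()
  wins <- bench_windows()
  plan <- make_split(coh, seed = 5L)
  tr <- subset_windows(wins, plan, "train")
  va <- subset_windows(wins, plan, "validation")
  te <- subset_windows(wins, plan, "test")
  clf <- train_classifier(tr, va, epochs = 30L, seed = 5L)
  sc <- classifier_scores(te$labels, predict_classifier(clf, te)$probs)
  expect_gt(sc$accuracy, 1 / 3 + 0.2)
  .fixtures$bench_clf <- clf
  .fixtures$bench_te <- te
  .fixtures$bench_real_scores <- sc
})

test_that("scoring a frozen classifier never changes its parameters", {
  clf <- .fixtures$bench_clf
  before <- serialize(clf$params, NULL)
  invisible(predict_classifier(clf, .fixtures$bench_te))
  invisible(congruence(clf, .fixtures$bench_te))
  expect_identical(serialize(clf$params, NULL), before)
})

test_that("congruence on identical real windows reproduces the real-only scores", {
  clf <- .fixtures$bench_clf
  te <- .fixtures$bench_te
  sc <- congruence(clf, te)
  real <- .fixtures$bench_real_scores
  for (f in c("accuracy", "precision", "recall", "f1", "auc"))
    expect_identical(sc[[f]], real[[f]])
  expect_equal(sc$regime, "generated_to_real")
  bad <- window_batch(te$data, rep(7L, length(te$labels)), te$fs)
  expect_error(congruence(clf, bad), "class set")
})

test_that("label-shuffled congruence collapses to chance accuracy", {
  clf <- .fixtures$bench_clf
  wins <- bench_windows()
  set.seed(44)
  accs <- vapply(1:20, function(i) {
    shuf <- window_batch(wins$data, sample(wins$labels), wins$fs)
    congruence(clf, shuf)$accuracy
  }, numeric(1))
  expect_lt(abs(mean(accs) - 1 / 3), 0.05)
})

test_that("classifier training fails when a class is absent", {
  wins <- bench_windows()
  keep <- wins$labels != 2L
  sub <- window_batch(wins$data[keep, , , drop = FALSE], wins$labels[keep], wins$fs)
  expect_error(train_classifier(sub, sub, n_class = 3L, epochs = 1L), "absent")
})

test_that("augmentation with ratio 0 reproduces the real-only scores", {
  coh <- smoke_cohort()
  m <- model_init(smoke_model_config(), seed = 6L)
  res <- augmentation_study(coh, m, ratio = 0, seed = 6L, epochs = 5L)
  expect_equal(res$real_only$accuracy, res$augmented$accuracy)
  expect_equal(res$real_only$f1, res$augmented$f1)
})

test_that("augmentation adds class-balanced generated windows", {
  m <- model_init(smoke_model_config(), seed = 7L)
  gl <- rep(0:2, length.out = 50L)
  gen <- sample_windows(m, labels = gl, mode = "prior", seed = 7L)
  counts <- tabulate(gen$labels + 1L, 3L)
  expect_lte(max(counts) - min(counts), 1L)
})
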