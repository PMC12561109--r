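# Evaluation metrics against closed forms, hand evaluations and independent
# oracles (brute-force Welch, eigendecomposition FID square root, dense-grid
# EMD, stats::ar.yw for Yule-Walker).

test_that("Welch PSD matches a brute-force periodogram-averaging oracle", {
  oracle <- function(x, fs, seg, hop, nfft, wtype) {
    i <- seq_len(seg) - 1
    w <- if (wtype == "hamming") 0.54 - 0.46 * cos(2 * pi * i / seg)
         else 0.5 - 0.5 * cos(2 * pi * i / seg)
    U <- sum(w^2); nb <- nfft %/% 2 + 1
    acc <- numeric(nb); ns <- 0; s <- 1
    while (s + seg - 1 <= length(x)) {
      v <- x[s:(s + seg - 1)]
      v <- (v - mean(v)) * w
      X <- fft(c(v, rep(0, nfft - seg)))[1:nb]
      p <- Mod(X)^2 / (fs * U)
      p[2:(nb - 1)] <- 2 * p[2:(nb - 1)]
      acc <- acc + p; ns <- ns + 1; s <- s + hop
    }
    acc / ns
  }
  set.seed(10)
  x <- rnorm(1000)
  for (wtype in c("hamming", "hann")) {
    got <- welch_psd(x, fs = 200, seg_len = 256, overlap = 0.5,
                     window = wtype, nfft = 512)
    expect_equal(got$psd, oracle(x, 200, 256, 128, 512, wtype), tolerance = 1e-9)
    expect_equal(got$freq, (0:256) * 200 / 512)
  }
  expect_error(welch_psd(rnorm(100), 200, seg_len = 256), "shorter")
})

test_that("Pearson metric matches Eq.-style brute force on toy vectors", {
  x <- c(1, 2, 3, 4); y <- c(2, 1, 4, 3)
  brute <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  got <- pearson_channels(matrix(x), matrix(y))
  expect_equal(got, brute, tolerance = 1e-12)
  expect_equal(pearson_channels(matrix(x), matrix(x)), 1)
  expect_equal(pearson_channels(matrix(x), matrix(-x)), -1)
  expect_warning(r <- pearson_channels(matrix(rep(1, 4)), matrix(y)), "zero-variance")
  expect_true(is.na(r))
})

test_that("Spearman metric: monotone invariance, reversal, ties vs rank-Pearson", {
  set.seed(11)
  x <- rnorm(30)
  expect_equal(spearman_channels(matrix(x), matrix(exp(x))), 1)
  expect_equal(spearman_channels(matrix(x), matrix(-x)), -1)
  # no ties: closed form 1 - 6 sum d^2 / (n(n^2-1)) equals cor(method = "spearman")
  y <- rnorm(30)
  expect_equal(spearman_channels(matrix(x), matrix(y)),
               cor(x, y, method = "spearman"), tolerance = 1e-12)
  # ties: equals Pearson on average ranks (stats::cor as oracle)
  xt <- c(1, 2, 2, 3, 4, 4, 4, 5)
  yt <- c(2, 1, 3, 3, 5, 4, 6, 6)
  expect_equal(spearman_channels(matrix(xt), matrix(yt)),
               cor(xt, yt, method = "spearman"), tolerance = 1e-12)
})

test_that("spectral KL: identity zero, Gibbs non-negativity, two-bin hand value", {
  kl <- tcvaegan:::kl_discrete
  expect_equal(kl(c(0.5, 0.5), c(0.25, 0.75)),
               0.5 * log(0.5 / 0.25) + 0.5 * log(0.5 / 0.75), tolerance = 1e-12)
  set.seed(12)
  x <- matrix(rnorm(1200), ncol = 2)
  expect_equal(spectral_kl(x, x, fs = 200, welch_spec(seg_sec = 1)), c(0, 0))
  for (i in 1:10) {
    p <- runif(8); p <- p / sum(p)
    q <- runif(8); q <- q / sum(q)
    expect_gte(kl(p, q), 0)
  }
})

test_that("PSD-MSE: identity, amplitude invariance, 5-bin hand evaluation", {
  set.seed(13)
  x <- matrix(rnorm(1600), ncol = 2)
  spec <- welch_spec(seg_sec = 1)
  expect_equal(psd_mse(x, x, 200, spec), c(0, 0))
  expect_equal(psd_mse(x, 10 * x, 200, spec), c(0, 0), tolerance = 1e-20)
  # hand evaluation of the normalized-envelope MSE on a 5-bin grid
  f <- 1:5
  px <- c(1, 2, 3, 2, 1); py <- c(3, 1, 1, 1, 3)
  nx <- px / pracma::trapz(f, px); ny <- py / pracma::trapz(f, py)
  # trapz(px) = 8, trapz(py) = 6; mean of squared envelope differences:
  hand <- (2 * (1 / 8 - 1 / 2)^2 + (1 / 4 - 1 / 6)^2 +
             (3 / 8 - 1 / 6)^2 + (1 / 4 - 1 / 6)^2) / 5
  expect_equal(mean((nx - ny)^2), hand, tolerance = 1e-12)
})

test_that("spectral EMD: identity, tone transport, dense-grid oracle, triangle", {
  fs <- 200
  tone <- function(f0) sin(2 * pi * f0 * (0:4095) / fs)
  d <- spectral_emd(matrix(tone(10)), matrix(tone(15)), fs,
                    welch_spec(seg_sec = 2, nfft = 2048))
  expect_lt(abs(d - 5), 0.5)
  expect_equal(spectral_emd(matrix(tone(10)), matrix(tone(10)), fs), 0)
  # dense-grid CDF-area oracle on random densities
  set.seed(14)
  f <- seq(0.5, 45, length.out = 90)
  oracle_emd <- function(f, px, py) {
    fg <- seq(min(f), max(f), length.out = 200000)
    pxg <- approx(f, px, fg)$y; pyg <- approx(f, py, fg)$y
    pxg <- pxg / pracma::trapz(fg, pxg); pyg <- pyg / pracma::trapz(fg, pyg)
    pracma::trapz(fg, abs(pracma::cumtrapz(fg, pxg) - pracma::cumtrapz(fg, pyg)))
  }
  for (i in 1:5) {
    px <- runif(90) + 0.1; py <- runif(90) + 0.1
    expect_equal(tcvaegan:::emd_cdf_area(f, px, py), oracle_emd(f, px, py),
                 tolerance = 1e-6)
  }
  # triangle inequality (1-D Wasserstein)
  for (i in 1:10) {
    pa <- runif(90) + 0.05; pb <- runif(90) + 0.05; pc <- runif(90) + 0.05
    ab <- tcvaegan:::emd_cdf_area(f, pa, pb)
    bc <- tcvaegan:::emd_cdf_area(f, pb, pc)
    ac <- tcvaegan:::emd_cdf_area(f, pa, pc)
    expect_lte(ac, ab + bc + 1e-9)
  }
})

test_that("FID: identity zero, mean-shift closed form, swap symmetry", {
  set.seed(15)
  fr <- matrix(rnorm(200 * 5), 200, 5)
  expect_lt(fid_distance(fr, fr), 1e-8)
  # equal covariances, mean shift d: FID = ||d||^2 on the raw features
  d <- c(0.5, -1, 2, 0, 0.3)
  fg <- sweep(fr, 2, -d)
  expect_equal(fid_distance(fr, fg, normalize = FALSE), sum(d^2), tolerance = 1e-8)
  # symmetric under swapping real/generated with pooled z-normalization
  fg2 <- matrix(rnorm(150 * 5), 150, 5) + 0.4
  expect_equal(fid_distance(fr, fg2), fid_distance(fg2, fr), tolerance = 1e-10)
})

test_that("SVD-based matrix square-root trace matches the eigendecomposition oracle", {
  set.seed(16)
  for (i in 1:20) {
    A <- crossprod(matrix(rnorm(64), 8, 8)) + diag(0.1, 8)
    B <- crossprod(matrix(rnorm(64), 8, 8)) + diag(0.1, 8)
    got <- tcvaegan:::tr_sqrt_product(A, B)
    oracle <- sum(sqrt(pmax(Re(eigen(A %*% B, only.values = TRUE)$values), 0)))
    expect_equal(got, oracle, tolerance = 1e-6)
  }
})

test_that("Yule-Walker recovers AR(4) coefficients and matches stats::ar.yw", {
  set.seed(17)
  phi <- c(0.5, -0.3, 0.2, -0.1)
  n <- 1e4
  x <- as.numeric(arima.sim(list(ar = phi), n))
  got <- yule_walker(x, 4L)
  expect_lt(max(abs(got - phi)), 0.1)
  oracle <- stats::ar.yw(x, aic = FALSE, order.max = 4L, demean = TRUE)$ar
  expect_equal(got, as.numeric(oracle), tolerance = 1e-6)
  expect_equal(yule_walker(rep(1, 100), 4L), rep(0, 4))
})

test_that("FID features capture tone, noise and AR structure", {
  fs <- 200
  tone <- sin(2 * pi * 10 * (0:1999) / fs)
  ft <- fid_features(tone, fs)
  expect_equal(ncol(ft), 12L)
  # centroid within the alpha band, alpha log-energy maximal
  expect_true(all(ft[, "centroid"] > 8 & ft[, "centroid"] < 13))
  expect_true(all(max.col(ft[, 1:5]) == 3L))
  # white noise: spectral entropy near log(bin count)
  set.seed(18)
  fw <- fid_features(rnorm(4000), fs)
  nb <- sum((0:128) * fs / 256 >= 0.5 & (0:128) * fs / 256 <= 45)
  expect_gt(mean(fw[, "entropy"]), 0.9 * log(nb))
})

test_that("evaluate_generation: degenerate perfect generator and mismatch detection", {
  wins <- smoke_windows()
  sub <- window_batch(wins$data[1:24, , , drop = FALSE], wins$labels[1:24],
                      wins$fs, wins$provenance[1:24, ])
  rep <- evaluate_generation(sub, sub, paired = TRUE)
  pc <- rep$per_channel
  expect_true(all(abs(pc$pearson - 1) < 1e-8))
  expect_true(all(abs(pc$spearman - 1) < 1e-8))
  expect_true(all(abs(pc$kl) < 1e-8))
  expect_true(all(abs(pc$psd_mse) < 1e-8))
  expect_true(all(abs(pc$emd) < 1e-8))
  expect_true(all(abs(pc$fid) < 1e-6))
  # aggregates recompute from the channel arrays
  expect_equal(rep$aggregate$mean[rep$aggregate$metric == "kl"], mean(pc$kl))
  expect_equal(rep$aggregate$sd[rep$aggregate$metric == "fid"], sd(pc$fid))
  # white-noise generated vs structured real: spectral metrics strictly positive
  set.seed(19)
  wn <- window_batch(array(rnorm(length(sub$data)), dim(sub$data)),
                     sub$labels, sub$fs)
  rep2 <- evaluate_generation(sub, wn, paired = TRUE)
  expect_true(all(rep2$per_channel$kl > 0))
  expect_true(all(rep2$per_channel$emd > 0))
  expect_true(all(rep2$per_channel$psd_mse > 0))
})

test_that("metrics are invariant to consistent channel reordering", {
  wins <- smoke_windows()
  sub <- window_batch(wins$data[1:8, , , drop = FALSE], wins$labels[1:8], wins$fs)
  set.seed(20)
  gen <- window_batch(sub$data + array(rnorm(length(sub$data), sd = 0.3), dim(sub$data)),
                      sub$labels, sub$fs)
  perm <- c(3, 1, 4, 2, 8, 6, 5, 7)
  subp <- window_batch(sub$data[, , perm, drop = FALSE], sub$labels, sub$fs)
  genp <- window_batch(gen$data[, , perm, drop = FALSE], gen$labels, gen$fs)
  r1 <- evaluate_generation(sub, gen, paired = TRUE)
  r2 <- evaluate_generation(subp, genp, paired = TRUE)
  for (mn in c("pearson", "spearman", "kl", "fid", "psd_mse", "emd"))
    expect_equal(r2$per_channel[[mn]], r1$per_channel[[mn]][perm],
                 tolerance = 1e-10, info = mn)
})

test_that("unpaired evaluation skips correlations with a notice", {
  wins <- smoke_windows()
  a <- window_batch(wins$data[1:6, , , drop = FALSE], wins$labels[1:6], wins$fs)
  b <- window_batch(wins$data[7:14, , , drop = FALSE], wins$labels[7:14], wins$fs)
  expect_message(rep <- evaluate_generation(a, b, paired = FALSE), "unpaired")
  expect_true(all(is.na(rep$per_channel$pearson)))
  expect_true(all(is.finite(rep$per_channel$kl)))
  expect_error(evaluate_generation(a, window_batch(b$data[, , 1:3, drop = FALSE],
                                                   b$labels, b$fs)),
               "channel-count mismatch")
})
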