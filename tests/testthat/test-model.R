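# Model core: shape contracts of the four blocks, the reparameterization
# trick, architectural isolation, ablation parameter diffs and checkpointing.

test_that("encoder maps [B, T, C] windows to [B, d_embed] at paper scale", {
  m <- model_init(model_config(T = 400L, C = 62L), seed = 1L)
  x <- array(rnorm(4 * 400 * 62), c(4, 400, 62))
  z <- encode(m, x)
  expect_equal(dim(z), c(4L, 256L))
  # identical windows give identical rows
  x[2, , ] <- x[1, , ]
  z <- encode(m, x)
  expect_equal(z[1, ], z[2, ], tolerance = 1e-12)
})

test_that("mean pooling equals the explicit sum over a 3-step toy sequence", {
  pool <- tcvaegan:::ag_mean_pool_time
  x <- matrix(rnorm(3 * 2), 3, 2)  # B = 1, T = 3
  got <- pool(tcvaegan:::ag_const(x), 1L, 3L)$val
  expect_equal(drop(got), colSums(x) / 3, tolerance = 1e-12)
})

test_that("latent heads are independent maps to [B, 128]", {
  cfg <- model_config(T = 64L, C = 4L)
  m <- model_init(cfg, seed = 2L)
  zi <- matrix(rnorm(8 * 256), 8, 256)
  ey <- matrix(rnorm(8 * 256), 8, 256)
  g <- infer_latent(m, zi, ey)
  expect_equal(dim(g$mu), c(8L, 128L))
  expect_equal(dim(g$logvar), c(8L, 128L))
  # zeroed weights give zero outputs
  m0 <- m
  m0$params$lat_mu_W[] <- 0; m0$params$lat_mu_b[] <- 0
  m0$params$lat_lv_W[] <- 0; m0$params$lat_lv_b[] <- 0
  g0 <- infer_latent(m0, zi, ey)
  expect_true(all(g0$mu == 0) && all(g0$logvar == 0))
  # perturbing the mu head leaves logvar unchanged
  m1 <- m
  m1$params$lat_mu_W <- m1$params$lat_mu_W + 1
  g1 <- infer_latent(m1, zi, ey)
  expect_identical(g1$logvar, g$logvar)
  expect_false(identical(g1$mu, g$mu))
})

test_that("reparameterization is mu + exp(0.5 logvar) * eps", {
  g <- list(mu = matrix(1:6 / 2, 2, 3), logvar = matrix(0.4, 2, 3))
  eps <- matrix(rnorm(6), 2, 3)
  z <- reparameterize(g, eps = eps)
  expect_equal(z, g$mu + exp(0.2) * eps, tolerance = 1e-12)
  # clamp floor: variance collapses, z ~= mu
  g$logvar[] <- -1e6
  z0 <- reparameterize(g, eps = eps)
  expect_lt(max(abs(z0 - g$mu)), exp(-5) * max(abs(eps)) + 1e-12)
  # fixed seed reproduces draws
  set.seed(123); z1 <- reparameterize(g)
  set.seed(123); z2 <- reparameterize(g)
  expect_identical(z1, z2)
})

test_that("1e5 standard-normal reparameterized draws match N(0,1) moments", {
  g <- list(mu = matrix(0, 1e5, 2), logvar = matrix(0, 1e5, 2))
  set.seed(55)
  z <- reparameterize(g)
  expect_true(all(abs(colMeans(z)) < 0.02))
  expect_true(all(abs(apply(z, 2, sd) - 1) < 0.02))
})

test_that("decoder produces [B, T, C] with replicated memory rows", {
  cfg <- model_config(T = 400L, C = 62L)
  m <- model_init(cfg, seed = 3L)
  z <- matrix(rnorm(8 * 128), 8, 128)
  out <- decode(m, z, rep(0:2, length.out = 8))
  expect_equal(dim(out), c(8L, 400L, 62L))
  # memory replication: repeated rows are identical across the T axis
  rr <- tcvaegan:::ag_repeat_rows(tcvaegan:::ag_const(matrix(1:4, 2, 2)), 3L)$val
  expect_equal(rr, matrix(c(1, 1, 1, 2, 2, 2, 3, 3, 3, 4, 4, 4), 6, 2))
})

test_that("discriminator emits one logit per window with stride-2 length arithmetic", {
  cfg <- smoke_model_config()
  m <- model_init(cfg, seed = 4L)
  expect_equal(tcvaegan:::disc_flat_len(400L), 50)
  x <- array(rnorm(5 * 400 * 8), c(5, 400, 8))
  lg <- discriminate(m, x)
  expect_length(lg, 5L)
  # batch permutation equivariance
  perm <- c(3, 1, 5, 2, 4)
  lg2 <- discriminate(m, x[perm, , , drop = FALSE])
  expect_equal(lg2, lg[perm], tolerance = 1e-10)
})

test_that("encode -> latent -> reparameterize -> decode closes the loop for several shapes", {
  for (geom in list(c(64L, 3L), c(128L, 5L))) {
    cfg <- model_config(T = geom[1], C = geom[2], d_embed = 8L, n_heads = 2L,
                        n_layers = 1L, d_ff = 16L, latent_dim = 4L,
                        disc_channels = c(4L, 4L, 4L), disc_fc = 8L, dropout = 0)
    m <- model_init(cfg, seed = 5L)
    x <- array(rnorm(3 * geom[1] * geom[2]), c(3, geom[1], geom[2]))
    y <- c(0L, 1L, 2L)
    zi <- encode(m, x)
    g <- infer_latent(m, zi, label_embedding(m, y))
    set.seed(1)
    xh <- decode(m, reparameterize(g), y)
    expect_equal(dim(xh), dim(x))
    expect_true(all(is.finite(xh)))
  }
})

test_that("each ablation switch alters exactly its component at initialization", {
  base <- model_init(smoke_model_config("none"), seed = 7L)
  bn <- names(base$params)

  nl <- model_init(smoke_model_config("no_label"), seed = 7L)
  expect_true(all(nl$params$lab_W == 0) && all(nl$params$lab_b == 0))
  expect_setequal(nl$frozen, c("lab_W", "lab_b"))
  same <- setdiff(bn, c("lab_W", "lab_b"))
  expect_identical(base$params[same], nl$params[same])

  np <- model_init(smoke_model_config("no_pos"), seed = 7L)
  expect_true(all(np$params$dec_pos == 0))
  expect_identical(np$frozen, "dec_pos")
  same <- setdiff(bn, "dec_pos")
  expect_identical(base$params[same], np$params[same])

  ng <- model_init(smoke_model_config("no_gan"), seed = 7L)
  expect_length(grep("^d_", names(ng$params)), 0L)
  same <- setdiff(bn, grep("^d_", bn, value = TRUE))
  expect_identical(base$params[same], ng$params[same])

  nt <- model_init(smoke_model_config("no_transformer"), seed = 7L)
  expect_length(grep("^enc_l", names(nt$params)), 0L)
  same <- setdiff(bn, grep("^enc_l", bn, value = TRUE))
  expect_identical(base$params[same], nt$params[same])

  ce <- model_init(smoke_model_config("cnn_encoder"), seed = 7L)
  expect_gt(length(grep("^enccnn", names(ce$params))), 0L)
  expect_length(grep("^enc_l|^enc_proj", names(ce$params)), 0L)
  same <- setdiff(bn, grep("^enc_", bn, value = TRUE))
  expect_identical(base$params[same], ce$params[same])

  nc <- model_init(smoke_model_config("no_cvae"), seed = 7L)
  expect_identical(base$params, nc$params)   # same nets; sampling/KL change only
  npr <- model_init(smoke_model_config("no_pearson"), seed = 7L)
  expect_identical(base$params, npr$params)  # loss-term-only ablation
})

test_that("ablated encoders still produce [B, d_embed] encodings", {
  x <- array(rnorm(2 * 400 * 8), c(2, 400, 8))
  for (ab in c("no_transformer", "cnn_encoder", "no_pos", "no_label")) {
    m <- model_init(smoke_model_config(ab), seed = 8L)
    expect_equal(dim(encode(m, x)), c(2L, 16L), info = ab)
  }
  # zero-label ablation: embeddings are all zero
  m <- model_init(smoke_model_config("no_label"), seed = 8L)
  expect_true(all(label_embedding(m, c(0L, 2L)) == 0))
})

test_that("checkpoints round-trip forward outputs bitwise", {
  m <- model_init(smoke_model_config(), seed = 9L)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(m, path, meta = list(note = "test"))
  m2 <- load_checkpoint(path)
  x <- array(rnorm(2 * 400 * 8), c(2, 400, 8))
  expect_identical(encode(m, x), encode(m2, x))
  expect_identical(discriminate(m, x), discriminate(m2, x))
  expect_identical(attr(m2, "meta")$note, "test")
  saveRDS(list(a = 1), path)
  expect_error(load_checkpoint(path), "not a tcvaegan checkpoint")
})

test_that("shape and label violations raise descriptive errors", {
  m <- model_init(smoke_model_config(), seed = 1L)
  expect_error(encode(m, array(rnorm(2 * 400 * 5), c(2, 400, 5))), "channel mismatch")
  expect_error(decode(m, matrix(rnorm(2 * 8), 2, 8), c(0L, 3L)), "labels")
  expect_error(decode(m, matrix(rnorm(2 * 5), 2, 5), c(0L, 1L)), "latent_dim")
  expect_error(model_config(d_embed = 30L, n_heads = 4L), "divisible")
  expect_error(model_config(ablation = "bogus"), "unknown ablation")
  mg <- model_init(smoke_model_config("no_gan"), seed = 1L)
  expect_error(discriminate(mg, array(rnorm(400 * 8), c(1, 400, 8))), "no discriminator")
})
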