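# Reverse-mode gradients of every tensor op are checked against central
# finite differences on random inputs.

ag <- function(name) getFromNamespace(name, "tcvaegan")

gradcheck <- function(fn, x, tol = 1e-5) {
  p <- ag_param(x)
  out <- fn(p)
  ag_backward(out)
  ng <- num_grad(function(v) fn(ag_const(v))$val, x)
  expect_lt(max(abs(p$grad - ng)), tol)
}

test_that("elementwise, linear and normalization ops backpropagate correctly", {
  set.seed(42)
  x <- matrix(rnorm(12), 3, 4)
  M <- matrix(rnorm(8), 4, 2)
  bvec <- rnorm(4); gmv <- rnorm(4); btv <- rnorm(4)
  cases <- list(
    matmul    = function(p) ag_sum(ag("ag_matmul")(p, ag_const(M))),
    add_bias  = function(p) ag_sum(ag_square(ag("ag_add")(p, ag_const(bvec)))),
    sub       = function(p) ag_sum(ag_square(ag("ag_sub")(p, ag_const(x * 0.5)))),
    mul       = function(p) ag_sum(ag("ag_mul")(p, ag_const(x + 1))),
    exp       = function(p) ag_sum(ag("ag_exp")(p)),
    softplus  = function(p) ag_sum(ag("ag_softplus")(p)),
    sigmoid   = function(p) ag_sum(ag_square(ag("ag_sigmoid")(p))),
    relu      = function(p) ag_sum(ag_square(ag("ag_relu")(p))),
    leaky     = function(p) ag_sum(ag_square(ag("ag_leaky_relu")(p, 0.2))),
    clamp     = function(p) ag_sum(ag_square(ag("ag_clamp")(p, -0.5, 0.5))),
    softmax   = function(p) ag_sum(ag_square(ag("ag_softmax_rows")(p))),
    layernorm = function(p) ag_sum(ag_square(ag("ag_layernorm")(p, ag_const(gmv), ag_const(btv)))),
    concat    = function(p) ag_sum(ag_square(ag("ag_concat_cols")(p, ag_const(x * 2))))
  )
  for (nm in names(cases)) gradcheck(cases[[nm]], x)
})

test_that("layernorm gain/bias gradients are correct", {
  set.seed(7)
  x <- matrix(rnorm(20), 5, 4)
  gmv <- rnorm(4); btv <- rnorm(4)
  gradcheck(function(p) ag_sum(ag_square(ag("ag_layernorm")(ag_const(x), p, ag_const(btv)))), gmv)
  gradcheck(function(p) ag_sum(ag_square(ag("ag_layernorm")(ag_const(x), ag_const(gmv), p))), btv)
})

test_that("pooling, tiling and reshape ops backpropagate correctly", {
  set.seed(8)
  x <- matrix(rnorm(12 * 4), 12, 4)    # B = 2, T = 6
  s <- matrix(rnorm(8), 2, 4)
  xc <- array(rnorm(2 * 3 * 10), c(2, 3, 10))
  gradcheck(function(p) ag_sum(ag_square(ag("ag_mean_pool_time")(p, 2, 6))), x)
  gradcheck(function(p) ag_sum(ag_square(ag("ag_repeat_rows")(p, 3))), s)
  gradcheck(function(p) ag_sum(ag_square(ag("ag_tile_batch")(p, 3))), s)
  gradcheck(function(p) ag_sum(ag_square(ag("ag_to_bct")(p, 2, 6))), x)
  gradcheck(function(p) ag_sum(ag_square(ag("ag_gap_time")(p))), xc)
  gradcheck(function(p) ag_sum(ag_square(ag("ag_flatten_bct")(p))), xc)
})

test_that("compiled attention matches finite differences in q, k and v", {
  set.seed(9)
  B <- 2L; Tq <- 3L; Tk <- 4L; H <- 2L; E <- 4L
  q <- matrix(rnorm(B * Tq * E), B * Tq, E)
  k <- matrix(rnorm(B * Tk * E), B * Tk, E)
  v <- matrix(rnorm(B * Tk * E), B * Tk, E)
  attn <- ag("ag_attention")
  gradcheck(function(p) ag_sum(ag_square(attn(p, ag_const(k), ag_const(v), B, Tq, Tk, H))), q)
  gradcheck(function(p) ag_sum(ag_square(attn(ag_const(q), p, ag_const(v), B, Tq, Tk, H))), k)
  gradcheck(function(p) ag_sum(ag_square(attn(ag_const(q), ag_const(k), p, B, Tq, Tk, H))), v)
})

test_that("compiled strided convolution matches finite differences", {
  set.seed(10)
  xc <- array(rnorm(2 * 3 * 11), c(2, 3, 11))
  W <- array(rnorm(5 * 3 * 4), c(5, 3, 4))
  bb <- rnorm(4)
  conv <- ag("ag_conv1d")
  gradcheck(function(p) ag_sum(ag_square(conv(p, ag_const(W), ag_const(bb)))), xc, tol = 1e-4)
  gradcheck(function(p) ag_sum(ag_square(conv(ag_const(xc), p, ag_const(bb)))), W, tol = 1e-4)
  gradcheck(function(p) ag_sum(ag_square(conv(ag_const(xc), ag_const(W), p))), bb, tol = 1e-4)
})

test_that("stride-2 convolution halves the temporal axis (ceil)", {
  conv <- ag("ag_conv1d")
  for (T in c(400L, 401L, 50L, 7L)) {
    x <- array(rnorm(2 * 2 * T), c(2, 2, T))
    W <- array(rnorm(5 * 2 * 3), c(5, 2, 3))
    out <- conv(ag_const(x), ag_const(W), ag_const(rnorm(3)))
    expect_equal(dim(out$val)[3], ceiling(T / 2))
  }
})

test_that("custom loss ops match finite differences", {
  set.seed(11)
  B <- 2L; T <- 40L; C <- 3L
  xh <- matrix(rnorm(B * T * C), B * T, C)
  xr <- matrix(rnorm(B * T * C), B * T, C)
  gradcheck(function(p) ag("ag_pearson_loss")(p, xr, B, T), xh)
  gradcheck(function(p) ag("ag_smooth_loss")(p, B, T), xh)
  gradcheck(function(p) ag("ag_spectrum_loss")(p, xr, B, T, fs = 20, seg_len = 16), xh, tol = 1e-4)
  mu <- matrix(rnorm(6), 2, 3); lv <- matrix(rnorm(6), 2, 3)
  gradcheck(function(p) ag("ag_kl_loss")(p, ag_const(lv), 2), mu)
  gradcheck(function(p) ag("ag_kl_loss")(ag_const(mu), p, 2), lv)
  lg <- matrix(rnorm(5)); lr <- matrix(rnorm(5))
  gradcheck(function(p) ag("ag_adv_gen_loss")(p), lg)
  gradcheck(function(p) ag("ag_disc_loss")(p, ag_const(lg)), lr)
  gradcheck(function(p) ag("ag_disc_loss")(ag_const(lr), p), lg)
})

test_that("gradients accumulate across shared sub-expressions", {
  p <- ag_param(matrix(c(1, 2, 3, 4), 2, 2))
  # f = sum(p^2) + 2 * sum(p)  => df/dp = 2p + 2
  out <- ag("ag_add")(ag_sum(ag_square(p)), ag("ag_scale")(ag_sum(p), 2))
  ag_backward(out)
  expect_equal(p$grad, 2 * p$val + 2)
})
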