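# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# Small cohort: 18 trials x 1000 samples x 8 channels -> 72 windows of 400.
smoke_cohort <- function() fixture("smoke_cohort", function() {
  generate_cohort(synthetic_cohort_config(n_trials = 18L, trial_len = 1000L,
                                          n_channels = 8L, seed = 11L))
})

smoke_windows <- function() fixture("smoke_windows", function() {
  segment_cohort(smoke_cohort())
})

# Mid-size cohort for downstream benchmarks: 45 trials -> 180 windows.
bench_cohort <- function() fixture("bench_cohort", function() {
  generate_cohort(synthetic_cohort_config(n_trials = 45L, trial_len = 1000L,
                                          n_channels = 8L, seed = 21L))
})

bench_windows <- function() fixture("bench_windows", function() {
  segment_cohort(bench_cohort())
})

# Narrow model configuration matching the smoke windows.
smoke_model_config <- function(ablation = "none") {
  model_config(T = 400L, C = 8L, n_class = 3L, d_embed = 16L, n_heads = 2L,
               n_layers = 1L, d_ff = 64L, latent_dim = 8L, dropout = 0,
               disc_channels = c(8L, 16L, 16L), disc_fc = 32L,
               ablation = ablation)
}

# Tiny windows (T = 128) for fast trainer mechanics tests.
tiny_windows <- function() fixture("tiny_windows", function() {
  coh <- generate_cohort(synthetic_cohort_config(n_trials = 6L, trial_len = 320L,
                                                 n_channels = 3L, seed = 31L))
  segment_cohort(coh, win_len = 128L, hop = 96L)
})

tiny_model_config <- function(ablation = "none") {
  model_config(T = 128L, C = 3L, n_class = 3L, d_embed = 8L, n_heads = 2L,
               n_layers = 1L, d_ff = 32L, latent_dim = 4L, dropout = 0,
               disc_channels = c(4L, 8L, 8L), disc_fc = 16L,
               ablation = ablation)
}

# Central finite-difference gradient of a scalar-valued function.
num_grad <- function(fn, x, eps = 1e-6) {
  g <- array(0, dim = dim(x) %||% length(x))
  for (i in seq_along(x)) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + eps; xm[i] <- xm[i] - eps
    g[i] <- (fn(xp) - fn(xm)) / (2 * eps)
  }
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

ag_param <- tcvaegan:::ag_param
ag_const <- tcvaegan:::ag_const
ag_backward <- tcvaegan:::ag_backward
ag_sum <- tcvaegan:::ag_sum
ag_square <- tcvaegan:::ag_square
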