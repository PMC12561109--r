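# Minimal reverse-mode automatic differentiation on plain R arrays.
#
# Activations are 2-D matrices in "sample-major" layout: row r = (b - 1) * T + t
# for batch element b and time step t, so dim(x) <- c(T, B, C) recovers the
# [time, batch, channel] view without copying. Scalars are length-1 numerics.
# Every node is an environment holding its value, accumulated gradient, parent
# nodes and a backward closure; topological order is recovered from a global
# creation counter (parents are always created before children).

.ag <- new.env(parent = emptyenv())
.ag$counter <- 0L

ag_next_id <- function() {
  .ag$counter <- .ag$counter + 1L
  .ag$counter
}

#' Create an autograd leaf
#'
#' `ag_param()` makes a trainable leaf (gradients are accumulated into it),
#' `ag_const()` a non-tracked constant. Both wrap a numeric array unchanged.
#'
#' @param val Numeric vector, matrix or array.
#' @return An `ag_tensor` environment with fields `val`, `grad`, `track`.
#' @keywords internal
ag_param <- function(val) {
  e <- new.env(parent = emptyenv())
  e$val <- val
  e$grad <- NULL
  e$parents <- list()
  e$bfun <- NULL
  e$track <- TRUE
  e$idx <- ag_next_id()
  class(e) <- "ag_tensor"
  e
}

#' @rdname ag_param
#' @keywords internal
ag_const <- function(val) {
  e <- new.env(parent = emptyenv())
  e$val <- val
  e$grad <- NULL
  e$parents <- list()
  e$bfun <- NULL
  e$track <- FALSE
  e$idx <- ag_next_id()
  class(e) <- "ag_tensor"
  e
}

is_ag <- function(x) inherits(x, "ag_tensor")

as_ag <- function(x) if (is_ag(x)) x else ag_const(x)

# Generic op constructor. `bfun(g)` must return a list of gradients, one per
# parent (NULL allowed for untracked parents).
ag_op <- function(val, parents, bfun) {
  track <- FALSE
  for (p in parents) if (p$track) { track <- TRUE; break }
  e <- new.env(parent = emptyenv())
  e$val <- val
  e$grad <- NULL
  e$track <- track
  if (track) {
    e$parents <- parents
    e$bfun <- bfun
  } else {
    e$parents <- list()
    e$bfun <- NULL
  }
  e$idx <- ag_next_id()
  class(e) <- "ag_tensor"
  e
}

#' Backpropagate through the tape
#'
#' Accumulates gradients of `root` (typically a scalar loss node) into every
#' tracked ancestor's `grad` field.
#'
#' @param root An `ag_tensor`.
#' @param grad Seed gradient; defaults to 1 for scalar roots.
#' @keywords internal
ag_backward <- function(root, grad = 1) {
  if (!root$track) return(invisible(NULL))
  # Collect tracked subgraph, keyed by creation index.
  nodes <- new.env(parent = emptyenv())
  stack <- list(root)
  while (length(stack)) {
    n <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- as.character(n$idx)
    if (!is.null(nodes[[key]])) next
    nodes[[key]] <- n
    for (p in n$parents) if (p$track) stack[[length(stack) + 1L]] <- p
  }
  ord <- sort(as.integer(ls(nodes)), decreasing = TRUE)
  root$grad <- ag_acc(root$grad, grad, root$val)
  for (i in ord) {
    n <- nodes[[as.character(i)]]
    if (is.null(n$bfun) || is.null(n$grad)) next
    gs <- n$bfun(n$grad)
    for (j in seq_along(n$parents)) {
      p <- n$parents[[j]]
      if (p$track && !is.null(gs[[j]])) p$grad <- ag_acc(p$grad, gs[[j]], p$val)
    }
  }
  invisible(NULL)
}

# Accumulate gradient g into slot cur, coercing to the shape of val.
ag_acc <- function(cur, g, val) {
  if (length(g) == 1L && length(val) > 1L) g <- array(g, dim = dim(val) %||% length(val))
  if (is.null(cur)) g else cur + g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

ag_zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

## ---- elementwise and linear-algebra ops ----

ag_matmul <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  ag_op(a$val %*% b$val, list(a, b), function(g) {
    list(g %*% t(b$val), crossprod(a$val, g))
  })
}

# a + b; b may be a row-broadcast bias vector (length == ncol(a)).
ag_add <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  av <- a$val; bv <- b$val
  if (is.matrix(av) && !is.matrix(bv) && length(bv) == ncol(av)) {
    val <- sweep(av, 2L, bv, "+")
    ag_op(val, list(a, b), function(g) list(g, colSums(g)))
  } else if (length(bv) == 1L && length(av) > 1L) {
    ag_op(av + bv, list(a, b), function(g) list(g, sum(g)))
  } else if (length(av) == 1L && length(bv) > 1L) {
    ag_op(av + bv, list(a, b), function(g) list(sum(g), g))
  } else {
    ag_op(av + bv, list(a, b), function(g) list(g, g))
  }
}

ag_sub <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  stopifnot(length(a$val) == length(b$val) || length(a$val) == 1L || length(b$val) == 1L)
  ag_op(a$val - b$val, list(a, b), function(g) {
    ga <- if (length(a$val) == 1L && length(b$val) > 1L) sum(g) else g
    gb <- if (length(b$val) == 1L && length(a$val) > 1L) -sum(g) else -g
    list(ga, gb)
  })
}

ag_mul <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  ag_op(a$val * b$val, list(a, b), function(g) {
    ga <- g * b$val; gb <- g * a$val
    if (length(a$val) == 1L && length(b$val) > 1L) ga <- sum(ga)
    if (length(b$val) == 1L && length(a$val) > 1L) gb <- sum(gb)
    list(ga, gb)
  })
}

ag_scale <- function(a, s) {
  a <- as_ag(a)
  ag_op(a$val * s, list(a), function(g) list(g * s))
}

ag_neg <- function(a) ag_scale(a, -1)

ag_exp <- function(a) {
  a <- as_ag(a)
  v <- exp(a$val)
  ag_op(v, list(a), function(g) list(g * v))
}

ag_log <- function(a) {
  a <- as_ag(a)
  ag_op(log(a$val), list(a), function(g) list(g / a$val))
}

ag_square <- function(a) {
  a <- as_ag(a)
  ag_op(a$val^2, list(a), function(g) list(2 * g * a$val))
}

ag_relu <- function(a) {
  a <- as_ag(a)
  m <- a$val > 0
  ag_op(a$val * m, list(a), function(g) list(g * m))
}

ag_leaky_relu <- function(a, slope = 0.2) {
  a <- as_ag(a)
  m <- ifelse(a$val > 0, 1, slope)
  ag_op(a$val * m, list(a), function(g) list(g * m))
}

ag_sigmoid <- function(a) {
  a <- as_ag(a)
  v <- 1 / (1 + exp(-a$val))
  ag_op(v, list(a), function(g) list(g * v * (1 - v)))
}

ag_tanh <- function(a) {
  a <- as_ag(a)
  v <- tanh(a$val)
  ag_op(v, list(a), function(g) list(g * (1 - v^2)))
}

# Numerically stable softplus log(1 + exp(x)); gradient is sigmoid(x).
ag_softplus <- function(a) {
  a <- as_ag(a)
  v <- pmax(a$val, 0) + log1p(exp(-abs(a$val)))
  ag_op(v, list(a), function(g) list(g / (1 + exp(-a$val))))
}

ag_sum <- function(a) {
  a <- as_ag(a)
  ag_op(sum(a$val), list(a), function(g) {
    list(array(g, dim = dim(a$val) %||% length(a$val)))
  })
}

ag_mean <- function(a) {
  a <- as_ag(a)
  n <- length(a$val)
  ag_op(sum(a$val) / n, list(a), function(g) {
    list(array(g / n, dim = dim(a$val) %||% length(a$val)))
  })
}

# Row-wise softmax of a matrix.
ag_softmax_rows <- function(a) {
  a <- as_ag(a)
  v <- a$val
  v <- v - apply(v, 1L, max)
  v <- exp(v)
  v <- v / rowSums(v)
  ag_op(v, list(a), function(g) {
    list((g - rowSums(g * v)) * v)
  })
}

# Concatenate matrices column-wise.
ag_concat_cols <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  na <- ncol(a$val)
  ag_op(cbind(a$val, b$val), list(a, b), function(g) {
    list(g[, seq_len(na), drop = FALSE], g[, -seq_len(na), drop = FALSE])
  })
}

# Layer normalization over the columns of each row (feature axis), with
# learnable gain/bias vectors.
ag_layernorm <- function(x, gamma, beta, eps = 1e-5) {
  x <- as_ag(x); gamma <- as_ag(gamma); beta <- as_ag(beta)
  v <- x$val
  n <- ncol(v)
  mu <- rowMeans(v)
  xc <- v - mu
  var <- rowMeans(xc^2)
  inv <- 1 / sqrt(var + eps)
  xn <- xc * inv
  out <- sweep(sweep(xn, 2L, gamma$val, "*"), 2L, beta$val, "+")
  ag_op(out, list(x, gamma, beta), function(g) {
    gg <- colSums(g * xn)
    gb <- colSums(g)
    gxn <- sweep(g, 2L, gamma$val, "*")
    # d/dx of (x - mu) * inv with mu, inv functions of the row
    gx <- inv * (gxn - rowMeans(gxn) - xn * rowMeans(gxn * xn))
    list(gx, gg, gb)
  })
}

# Mean over the time axis: (B*T) x E -> B x E, rows sample-major.
ag_mean_pool_time <- function(x, B, T) {
  x <- as_ag(x)
  v <- x$val
  E <- ncol(v)
  grp <- rep(seq_len(B), each = T)
  out <- rowsum(v, grp, reorder = FALSE) / T
  dimnames(out) <- NULL
  ag_op(out, list(x), function(g) {
    list(g[grp, , drop = FALSE] / T)
  })
}

# Replicate each row T times: B x E -> (B*T) x E, rows sample-major.
ag_repeat_rows <- function(x, T) {
  x <- as_ag(x)
  v <- x$val
  B <- nrow(v)
  idx <- rep(seq_len(B), each = T)
  ag_op(v[idx, , drop = FALSE], list(x), function(g) {
    gs <- rowsum(g, idx, reorder = FALSE)
    dimnames(gs) <- NULL
    list(gs)
  })
}

# Tile a T x E matrix across a batch: -> (B*T) x E (used for positional encodings).
ag_tile_batch <- function(x, B) {
  x <- as_ag(x)
  v <- x$val
  T <- nrow(v)
  idx <- rep(seq_len(T), B)
  ag_op(v[idx, , drop = FALSE], list(x), function(g) {
    gs <- rowsum(g, idx, reorder = FALSE)
    dimnames(gs) <- NULL
    list(gs)
  })
}

# Inverted dropout; identity when p == 0 or mask is NULL.
ag_dropout <- function(x, p, training) {
  if (!training || p <= 0) return(as_ag(x))
  x <- as_ag(x)
  keep <- (array(stats::runif(length(x$val)), dim = dim(x$val) %||% length(x$val)) >= p) / (1 - p)
  ag_op(x$val * keep, list(x), function(g) list(g * keep))
}

# Scaled dot-product multi-head attention on sample-major 2-D activations.
# q: (B*Tq) x E, k/v: (B*Tk) x E, H heads. Returns (B*Tq) x E. The per-head
# softmax matrices are computed in compiled code and cached for the backward
# pass.
ag_attention <- function(q, k, v, B, Tq, Tk, H) {
  q <- as_ag(q); k <- as_ag(k); v <- as_ag(v)
  E <- ncol(q$val)
  stopifnot(E %% H == 0L)
  fw <- attn_forward_cpp(q$val, k$val, v$val, B, Tq, Tk, H)
  ag_op(fw$out, list(q, k, v), function(g) {
    bw <- attn_backward_cpp(g, q$val, k$val, v$val, fw$A, B, Tq, Tk, H)
    list(bw$gq, bw$gk, bw$gv)
  })
}

# 1-D convolution with stride and symmetric "same"-style zero padding, via
# im2col in compiled code. x: array [B, Cin, T]; W: array [K, Cin, Cout];
# b: length Cout. Output: array [B, Cout, Tout] with Tout = ceil(T / stride).
ag_conv1d <- function(x, W, b, stride = 2L, pad = NULL) {
  x <- as_ag(x); W <- as_ag(W); b <- as_ag(b)
  xv <- x$val
  stopifnot(length(dim(xv)) == 3L)
  B <- dim(xv)[1L]; Cin <- dim(xv)[2L]; T <- dim(xv)[3L]
  K <- dim(W$val)[1L]; Cout <- dim(W$val)[3L]
  stopifnot(dim(W$val)[2L] == Cin)
  Tout <- as.integer(ceiling(T / stride))
  if (is.null(pad)) {
    # total padding so that the last window fits: (Tout-1)*stride + K - T
    ptot <- max(0L, (Tout - 1L) * stride + K - T)
    pl <- ptot %/% 2L
  } else pl <- as.integer(pad)
  if (T + pl < K) stop("input length ", T, " too short for kernel ", K, "; increase T")
  fw <- conv1d_forward_cpp(xv, W$val, as.numeric(b$val), as.integer(stride), pl)
  ag_op(fw$out, list(x, W, b), function(g) {
    bw <- conv1d_backward_cpp(g, fw$Xcol, W$val, B, Cin, T, as.integer(stride), pl)
    list(bw$gx, bw$gW, as.numeric(bw$gb))
  })
}

# [B, C, Tout] -> B x (C*Tout) flatten (row-major over channels then time).
ag_flatten_bct <- function(x) {
  x <- as_ag(x)
  d <- dim(x$val)
  B <- d[1L]
  out <- matrix(x$val, nrow = B)  # columns ordered (c, t) column-major: c fastest
  ag_op(out, list(x), function(g) {
    list(array(g, dim = d))
  })
}

# Global average pool over time: [B, C, T] -> B x C.
ag_gap_time <- function(x) {
  x <- as_ag(x)
  d <- dim(x$val)
  out <- rowMeans(matrix(x$val, d[1L] * d[2L], d[3L]))
  dim(out) <- d[1:2]
  ag_op(out, list(x), function(g) {
    list(array(rep(g / d[3L], d[3L]), dim = d))
  })
}

# Weighted sum of scalar nodes with constant (no-grad) weights.
ag_wsum <- function(nodes, w) {
  stopifnot(length(nodes) == length(w))
  val <- 0
  for (i in seq_along(nodes)) val <- val + w[i] * nodes[[i]]$val
  ag_op(val, nodes, function(g) as.list(g * w))
}

# Clamp with straight-through gradient inside the range.
ag_clamp <- function(a, lo, hi) {
  a <- as_ag(a)
  m <- a$val >= lo & a$val <= hi
  ag_op(pmin(pmax(a$val, lo), hi), list(a), function(g) list(g * m))
}

# Sample-major (B*T) x C activations -> [B, C, T] array (discriminator input).
ag_to_bct <- function(x, B, T) {
  x <- as_ag(x)
  C <- ncol(x$val)
  v <- x$val
  dim(v) <- c(T, B, C)
  out <- aperm(v, c(2L, 3L, 1L))
  ag_op(out, list(x), function(g) {
    gg <- aperm(g, c(3L, 1L, 2L))
    dim(gg) <- c(T * B, C)
    list(gg)
  })
}
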