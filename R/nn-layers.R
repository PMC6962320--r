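# Layer primitives of the CNN engine. Each layer is a mutable environment
# holding its parameters, gradients, Adam state and forward cache; tensors are
# column-major R arrays with the batch as the last dimension:
#   2D activations (H, W, C, N); 3D activations (H, W, D, C, N);
#   dense activations (features, N).
# Backward passes implement the exact analytic gradients; the test suite pins
# them against finite differences.

new_layer <- function(type, params = list(), decay = character(), extra = list()) {
  l <- new.env(parent = emptyenv())
  l$type <- type
  l$params <- params
  l$grads <- list()
  l$decay <- decay         # names of params subject to L2 weight decay
  l$opt <- list()
  for (nm in names(extra)) assign(nm, extra[[nm]], envir = l)
  class(l) <- c(paste0("lt_", type), "lt_layer")
  l
}

he_uniform <- function(dims, fan_in) {
  lim <- sqrt(6 / fan_in)
  array(runif(prod(dims), -lim, lim), dim = dims)
}

layer_conv2d <- function(c_in, c_out) {
  new_layer("conv2d",
            params = list(W = he_uniform(c(3, 3, c_in, c_out), 9 * c_in),
                          b = numeric(c_out)),
            decay = "W")
}

layer_conv3d <- function(c_in, c_out) {
  new_layer("conv3d",
            params = list(W = he_uniform(c(3, 3, 3, c_in, c_out), 27 * c_in),
                          b = numeric(c_out)),
            decay = "W")
}

layer_dense <- function(n_in, n_out) {
  new_layer("dense",
            params = list(W = he_uniform(c(n_out, n_in), n_in),
                          b = numeric(n_out)),
            decay = "W")
}

layer_relu <- function() new_layer("relu")
layer_pool <- function() new_layer("pool")     # 2x2 stride-2 max over (H, W)
layer_flatten <- function() new_layer("flatten")
layer_gap <- function() new_layer("gap")       # global average pool -> (C, N)
layer_dropout <- function(p = 0.5) new_layer("dropout", extra = list(p = p))

layer_bn <- function(c_ch, momentum = 0.9, eps = 1e-5) {
  new_layer("bn",
            params = list(gamma = rep(1, c_ch), beta = numeric(c_ch)),
            extra = list(momentum = momentum, eps = eps,
                         run_mean = numeric(c_ch), run_var = rep(1, c_ch)))
}

# Per-channel moments for an array with channel as the second-to-last dim.
channel_stats <- function(x) {
  d <- dim(x)
  nd <- length(d)
  C <- d[nd - 1L]
  S <- prod(d[seq_len(nd - 2L)])
  m <- matrix(x, nrow = S)
  cm <- matrix(colMeans(m), nrow = C)          # C x N
  cm2 <- matrix(colMeans(m * m), nrow = C)
  mu <- rowMeans(cm)
  list(mu = mu, var = rowMeans(cm2) - mu^2, S = S, C = C,
       M = S * (length(x) / (S * C)))
}

channel_sum <- function(x, S, C) {
  m <- matrix(x, nrow = S)
  rowSums(matrix(colSums(m), nrow = C))
}

layer_fwd <- function(l, x, training = FALSE) {
  switch(l$type,
    conv2d = {
      l$x <- x
      cpp_conv2d_fwd(x, l$params$W, l$params$b)
    },
    conv3d = {
      l$x <- x
      cpp_conv3d_fwd(x, l$params$W, l$params$b)
    },
    dense = {
      l$x <- x
      l$params$W %*% x + l$params$b
    },
    relu = {
      y <- x * (x > 0)
      l$y <- y
      y
    },
    pool = {
      l$xdim <- dim(x)
      r <- cpp_maxpool_hw_fwd(x)
      l$idx <- r$idx
      r$y
    },
    flatten = {
      d <- dim(x)
      l$xdim <- d
      dim(x) <- c(prod(d[-length(d)]), d[length(d)])
      x
    },
    gap = {
      d <- dim(x)
      l$xdim <- d
      C <- d[length(d) - 1L]
      S <- prod(d[seq_len(length(d) - 2L)])
      matrix(colMeans(matrix(x, nrow = S)), nrow = C)
    },
    dropout = {
      if (training && l$p > 0) {
        mask <- (runif(length(x)) >= l$p) / (1 - l$p)
        l$mask <- mask
        x * mask
      } else {
        l$mask <- NULL
        x
      }
    },
    bn = {
      d <- dim(x)
      S <- prod(d[seq_len(length(d) - 2L)])
      l$train_mode <- training
      if (training) {
        st <- channel_stats(x)
        l$mu <- st$mu; l$var <- st$var; l$S <- S; l$M <- st$M
        l$run_mean <- l$momentum * l$run_mean + (1 - l$momentum) * st$mu
        l$run_var <- l$momentum * l$run_var + (1 - l$momentum) * st$var
        invstd <- 1 / sqrt(st$var + l$eps)
      } else {
        l$mu <- l$run_mean; l$var <- l$run_var; l$S <- S
        invstd <- 1 / sqrt(l$run_var + l$eps)
      }
      xhat <- (x - rep(l$mu, each = S)) * rep(invstd, each = S)
      l$xhat <- xhat
      l$invstd <- invstd
      xhat * rep(l$params$gamma, each = S) + rep(l$params$beta, each = S)
    },
    stop_lungtex(sprintf("unknown layer type %s", l$type), "lungtex_spec_error"))
}

layer_bwd <- function(l, dy) {
  switch(l$type,
    conv2d = {
      g <- cpp_conv2d_bwd(l$x, l$params$W, dy)
      l$grads <- list(W = g$dw, b = g$db)
      g$dx
    },
    conv3d = {
      g <- cpp_conv3d_bwd(l$x, l$params$W, dy)
      l$grads <- list(W = g$dw, b = g$db)
      g$dx
    },
    dense = {
      l$grads <- list(W = dy %*% t(l$x), b = rowSums(dy))
      t(l$params$W) %*% dy
    },
    relu = dy * (l$y > 0),
    pool = cpp_maxpool_hw_bwd(l$idx, dy, l$xdim),
    flatten = {
      dim(dy) <- l$xdim
      dy
    },
    gap = {
      d <- l$xdim
      S <- prod(d[seq_len(length(d) - 2L)])
      array(rep(as.numeric(dy), each = S) / S, dim = d)
    },
    dropout = {
      if (is.null(l$mask)) dy else dy * l$mask
    },
    bn = {
      S <- l$S
      C <- length(l$params$gamma)
      dgamma <- channel_sum(dy * l$xhat, S, C)
      dbeta <- channel_sum(dy, S, C)
      l$grads <- list(gamma = dgamma, beta = dbeta)
      dxhat <- dy * rep(l$params$gamma, each = S)
      if (!isTRUE(l$train_mode)) {
        # inference-mode stats are constants w.r.t. the batch
        dxhat * rep(l$invstd, each = S)
      } else {
        M <- length(dy) / C
        s1 <- channel_sum(dxhat, S, C)
        s2 <- channel_sum(dxhat * l$xhat, S, C)
        rep(l$invstd, each = S) / M *
          (M * dxhat - rep(s1, each = S) - l$xhat * rep(s2, each = S))
      }
    },
    stop_lungtex(sprintf("unknown layer type %s", l$type), "lungtex_spec_error"))
}
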