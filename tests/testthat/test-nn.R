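# The CNN engine: loss values, analytic gradients vs finite differences,
# early stopping and determinism contracts.

tiny_spec <- function(name, input_size = 8L, slab = 3L) {
  arch_spec(name, filters = c(2L, 2L, 3L), dense_units = 4L,
            input_size = input_size, slab_depth = slab)
}

tiny_input <- function(spec, n = 3L) {
  s <- spec$input_size
  x <- switch(spec$input_mode,
    axial2d = array(rnorm(s * s * n), dim = c(s, s, 1, n)),
    ortho2p5d = array(rnorm(s * s * 3 * n), dim = c(s, s, 3, n)),
    slab3d = array(rnorm(s * s * spec$slab_depth * n),
                   dim = c(s, s, spec$slab_depth, 1, n)))
  if (spec$needs_context)
    x <- list(main = x, ctx = array(rnorm(s * s * n), dim = c(s, s, 1, n)))
  x
}

test_that("cross-entropy loss matches closed forms", {
  perfect <- diag(8)[, c(1, 3, 5)]
  expect_equal(cnn_loss(perfect, c(1, 3, 5)), 0, tolerance = 1e-9)
  uniform <- matrix(1 / 8, 8, 4)
  expect_equal(cnn_loss(uniform, c(1, 2, 7, 8)), log(8), tolerance = 1e-12)
  # lambda > 0 with all-zero weights is pure cross-entropy
  expect_equal(cnn_loss(uniform, c(1, 2, 7, 8),
                        weights = list(matrix(0, 3, 3)), l2 = 10), log(8))
  # additive in lambda
  w <- list(matrix(1:4 / 10, 2, 2))
  expect_equal(cnn_loss(uniform, c(1, 2, 7, 8), weights = w, l2 = 0.5),
               log(8) + 0.25 * sum(unlist(w)^2))
  expect_error(cnn_loss(uniform, c(0, 1, 2, 3)), class = "lungtex_label_error")
})

test_that("backpropagation matches finite differences on every topology", {
  set.seed(11)
  for (name in c("BCNN2D", "MSTAGE_CNN2p5D", "MCONTEXT_CNN2D", "BCNN3D")) {
    spec <- tiny_spec(name)
    net <- lungtex:::build_net(spec, dropout = 0)
    x <- tiny_input(spec)
    y <- c(1L, 4L, 8L)
    f <- function() lungtex:::net_loss_grad(net, x, y, l2 = 0.01)
    f()
    worst <- 0
    for (l in lungtex:::net_layers(net)) {
      for (nm in names(l$params)) {
        g <- l$grads[[nm]]
        if (is.null(g)) next
        for (t in sample(length(l$params[[nm]]),
                         min(3L, length(l$params[[nm]])))) {
          eps <- 1e-5
          p0 <- l$params[[nm]][t]
          l$params[[nm]][t] <- p0 + eps; lp <- f()
          l$params[[nm]][t] <- p0 - eps; lm <- f()
          l$params[[nm]][t] <- p0
          num <- (lp - lm) / (2 * eps)
          worst <- max(worst, abs(num - g[t]) /
                         max(1e-6, abs(num) + abs(g[t])))
        }
      }
    }
    expect_lt(worst, 1e-3)
  }
})

test_that("a linearly separable two-class toy is learned to perfect accuracy", {
  # patches whose mean intensity determines the class; a logistic regression
  # on the same feature separates them perfectly, and so must the net
  set.seed(12)
  n <- 40L
  x <- array(rnorm(8 * 8 * n, 0, 0.2), dim = c(8, 8, 1, n))
  y <- rep(c(1L, 2L), each = n / 2)
  x[, , , y == 2] <- x[, , , y == 2] + 2
  feat <- apply(x, 4, mean)
  oracle <- stats::glm(I(y == 2) ~ feat, family = stats::binomial())
  expect_equal(mean((stats::predict(oracle) > 0) + 1 == y), 1)
  idx <- rep(c(TRUE, FALSE), n / 2)
  spec <- tiny_spec("BCNN2D")
  cfg <- train_config(seed = 5, max_epochs = 60, batch_size = 10,
                      patience = 60, l2 = 0, lr = 0.01)
  m <- build_model(spec, cfg)
  m <- train_cnn(m, list(x = lungtex:::slice_batch(x, which(idx)),
                         y = y[idx]),
                 list(x = lungtex:::slice_batch(x, which(!idx)),
                      y = y[!idx]), cfg)
  vp <- predict_proba(m, lungtex:::slice_batch(x, which(!idx)))
  expect_equal(mean(apply(vp, 1, which.max) == y[!idx]), 1)
})

test_that("early stopping honours patience and restores the best epoch", {
  set.seed(13)
  spec <- tiny_spec("BCNN2D")
  x <- tiny_input(spec, 8L)
  y <- rep(1:4, 2)
  # patience 0: stops at the first epoch whose validation loss fails to improve
  cfg0 <- train_config(seed = 3, max_epochs = 50, patience = 0, lr = 0.5)
  m0 <- train_cnn(build_model(spec, cfg0), list(x = x, y = y),
                  list(x = x, y = y), cfg0)
  lg <- m0$training_log
  expect_lt(m0$stopped_epoch, 50)
  expect_equal(m0$best_epoch, which.min(lg$val_loss))
  expect_lte(m0$best_val_loss, lg$val_loss[nrow(lg)])
  # restored parameters reproduce the best validation loss
  vp <- predict_proba(m0, x)
  v_loss <- cnn_loss(t(vp), y, weights = lungtex:::net_weight_arrays(m0$net),
                     l2 = cfg0$l2)
  expect_equal(v_loss, m0$best_val_loss, tolerance = 1e-8)
})

test_that("training is deterministic under a fixed seed", {
  set.seed(14)
  spec <- tiny_spec("BCNN2D")
  x <- tiny_input(spec, 6L)
  y <- c(1L, 2L, 3L, 1L, 2L, 3L)
  run <- function() {
    cfg <- train_config(seed = 77, max_epochs = 4, batch_size = 3)
    train_cnn(build_model(spec, cfg), list(x = x, y = y),
              list(x = x, y = y), cfg)$training_log
  }
  expect_identical(run(), run())
})

test_that("prediction contracts: duplicates, normalization, degenerate input", {
  set.seed(15)
  m <- build_model(tiny_spec("BCNN2D"), train_config(seed = 2))
  x1 <- array(rnorm(64), dim = c(8, 8, 1, 1))
  x2 <- array(c(x1, x1), dim = c(8, 8, 1, 2))
  p <- predict_proba(m, x2)
  expect_equal(p[1, ], p[2, ])
  expect_equal(rowSums(p), c(1, 1), tolerance = 1e-6)
  expect_true(all(p >= 0))
  p0 <- predict_proba(m, array(0, dim = c(8, 8, 1, 1)))
  expect_true(all(is.finite(p0)))
  expect_error(train_cnn(build_model(tiny_spec("BCNN2D")),
                         list(x = x2, y = c(1L, 2L)), NULL),
               class = "lungtex_config_error")
})

test_that("models survive a save/load round trip", {
  set.seed(16)
  spec <- tiny_spec("BCNN2D")
  cfg <- train_config(seed = 9, max_epochs = 2)
  x <- tiny_input(spec, 4L)
  y <- c(1L, 2L, 3L, 4L)
  m <- train_cnn(build_model(spec, cfg), list(x = x, y = y),
                 list(x = x, y = y), cfg)
  path <- tempfile(fileext = ".rds")
  save_model(m, path)
  expect_true(file.exists(paste0(path, ".json")))
  m2 <- load_model(path)
  expect_equal(predict_proba(m2, x), predict_proba(m, x), tolerance = 1e-12)
})
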