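#' Training configuration
#'
#' Shared hyper-parameters of the seven networks. Defaults are the tuned
#' values used throughout the package: Adam (learning rate 0.001, beta1 0.9,
#' beta2 0.999, epsilon 1e-8), L2 strength 0.0025, dropout 0.5, batch size
#' 128 and early-stopping patience of 30 epochs.
#'
#' @param lr,beta1,beta2,eps Adam optimizer settings.
#' @param l2 L2 regularization strength (weights only).
#' @param dropout dropout probability for the dense head.
#' @param batch_size minibatch size.
#' @param patience early stopping patience in epochs; training stops once
#'   the validation loss has not improved for `patience` consecutive epochs
#'   (`patience = 0` stops at the first non-improving epoch).
#' @param max_epochs epoch cap.
#' @param seed RNG seed controlling shuffling, dropout and initialization;
#'   fixed seed gives an identical training log.
#' @param verbose print per-epoch progress.
#' @export
train_config <- function(lr = 0.001, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                         l2 = 0.0025, dropout = 0.5, batch_size = 128L,
                         patience = 30L, max_epochs = 300L, seed = 42L,
                         verbose = FALSE) {
  structure(list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, l2 = l2,
                 dropout = dropout, batch_size = batch_size,
                 patience = as.integer(patience),
                 max_epochs = as.integer(max_epochs), seed = seed,
                 verbose = isTRUE(verbose)),
            class = "train_config")
}

# Slice samples out of a batched tensor (or a main/ctx input pair).
slice_batch <- function(x, idx) {
  if (is.list(x)) return(lapply(x, slice_batch, idx = idx))
  d <- dim(x)
  args <- c(list(x), rep(list(quote(expr = )), length(d) - 1L), list(idx),
            list(drop = FALSE))
  do.call(`[`, args)
}

n_samples <- function(x) {
  if (is.list(x)) x <- x[[1]]
  dim(x)[length(dim(x))]
}

adam_step <- function(net, cfg, t) {
  for (l in net_layers(net)) {
    for (nm in names(l$grads)) {
      g <- l$grads[[nm]]
      st <- l$opt[[nm]] %||% list(m = 0 * g, v = 0 * g)
      st$m <- cfg$beta1 * st$m + (1 - cfg$beta1) * g
      st$v <- cfg$beta2 * st$v + (1 - cfg$beta2) * g * g
      mhat <- st$m / (1 - cfg$beta1^t)
      vhat <- st$v / (1 - cfg$beta2^t)
      l$params[[nm]] <- l$params[[nm]] - cfg$lr * mhat / (sqrt(vhat) + cfg$eps)
      l$opt[[nm]] <- st
    }
  }
}

#' Train a CNN with Adam and early stopping
#'
#' Minimizes the L2-regularized categorical cross-entropy with per-epoch
#' shuffled minibatches. Training stops when the validation loss has not
#' improved for `patience` epochs (or at `max_epochs`); the returned
#' parameters are those of the best-validation epoch.
#'
#' @param model an untrained model from [build_model()], or a `lungtex_model`
#'   to continue training.
#' @param train,val datasets as returned by internal stacking or
#'   [generate_patchset()]: lists with `x` (input tensor, or
#'   `list(main, ctx)` for the multi-context net) and `y` (integer labels
#'   1..8).
#' @param config a [train_config].
#' @return A `lungtex_model`: list with the network, `arch`, `config`,
#'   `training_log` (per-epoch train/validation loss and validation
#'   accuracy), `stopped_epoch`, `best_epoch`.
#' @export
train_cnn <- function(model, train, val, config = train_config()) {
  net <- if (inherits(model, "lungtex_model")) model$net else model
  stopifnot(inherits(net, "lt_net"))
  if (is.null(val) || n_samples(val$x) == 0L)
    stop_lungtex("validation set must be non-empty (early stopping needs it)",
                 "lungtex_config_error")
  n_tr <- n_samples(train$x)
  if (n_tr == 0L)
    stop_lungtex("empty training set", "lungtex_config_error")
  log <- data.frame(epoch = integer(), train_loss = numeric(),
                    val_loss = numeric(), val_acc = numeric())
  best <- list(loss = Inf, state = net_state(net), epoch = 0L)
  stale <- 0L
  t_adam <- 0L
  with_seed(config$seed, {
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n_tr)
      nb <- ceiling(n_tr / config$batch_size)
      tr_loss <- 0
      for (b in seq_len(nb)) {
        idx <- ord[((b - 1L) * config$batch_size + 1L):min(b * config$batch_size, n_tr)]
        loss <- net_loss_grad(net, slice_batch(train$x, idx), train$y[idx],
                              l2 = config$l2)
        t_adam <- t_adam + 1L
        adam_step(net, config, t_adam)
        tr_loss <- tr_loss + loss * length(idx)
      }
      tr_loss <- tr_loss / n_tr
      vp <- net_predict_probs(net, val$x)
      v_loss <- cnn_loss(vp, val$y, weights = net_weight_arrays(net),
                         l2 = config$l2)
      v_acc <- mean(apply(vp, 2, which.max) == val$y)
      log <- rbind(log, data.frame(epoch = epoch, train_loss = tr_loss,
                                   val_loss = v_loss, val_acc = v_acc))
      if (config$verbose)
        message(sprintf("epoch %3d  train %.4f  val %.4f  acc %.3f",
                        epoch, tr_loss, v_loss, v_acc))
      if (v_loss < best$loss) {
        best <- list(loss = v_loss, state = net_state(net), epoch = epoch)
        stale <- 0L
      } else {
        stale <- stale + 1L
        if (stale >= max(1L, config$patience)) break
      }
    }
  })
  net_restore(net, best$state)
  structure(list(net = net, arch = net$arch, config = config,
                 training_log = log, stopped_epoch = nrow(log),
                 best_epoch = best$epoch, best_val_loss = best$loss,
                 trained = TRUE,
                 norm_stats = if (inherits(model, "lungtex_model"))
                   model$norm_stats),
            class = "lungtex_model")
}

# Chunked forward pass in inference mode; returns n_classes x N probabilities.
net_predict_probs <- function(net, x, batch = 256L) {
  n <- n_samples(x)
  out <- NULL
  for (start in seq(1L, n, by = batch)) {
    idx <- start:min(start + batch - 1L, n)
    z <- net_forward(net, slice_batch(x, idx), training = FALSE)
    p <- softmax_cols(z)
    out <- if (is.null(out)) p else cbind(out, p)
  }
  out
}

#' Per-sample class probabilities from a trained model
#'
#' @param model a `lungtex_model` (see [train_cnn()]).
#' @param samples either a list of [roi_sample][extract_roi] objects (the
#'   input mode must match the architecture) or a pre-stacked input tensor.
#' @param batch forward-pass chunk size.
#' @return An `N x 8` matrix of probabilities; each row is nonnegative and
#'   sums to 1.
#' @export
predict_proba <- function(model, samples, batch = 256L) {
  stopifnot(inherits(model, "lungtex_model"))
  x <- model_input(model, samples)
  t(net_predict_probs(model$net, x, batch = batch))
}

#' @export
predict.lungtex_model <- function(object, newdata, ...) {
  predict_proba(object, newdata, ...)
}

# Coerce roi_samples (or a ready tensor) into the model's input tensor,
# validating the input mode.
model_input <- function(model, samples) {
  spec <- model$arch
  if (is.list(samples) && length(samples) > 0 &&
      inherits(samples[[1]], "roi_sample")) {
    modes <- unique(vapply(samples, `[[`, character(1), "mode"))
    if (!identical(modes, spec$input_mode))
      stop_lungtex(sprintf("architecture %s expects %s input, got %s",
                           spec$name, spec$input_mode,
                           paste(modes, collapse = ",")),
                   "lungtex_input_error")
    roi_stack(samples, needs_context = isTRUE(spec$needs_context))$x
  } else {
    check_input_tensor(spec, samples)
    samples
  }
}

check_input_tensor <- function(spec, x) {
  main <- if (is.list(x) && !is.null(x$main)) x$main else x
  nd <- length(dim(main))
  want <- switch(spec$input_mode, axial2d = 4L, ortho2p5d = 4L, slab3d = 5L)
  wantc <- switch(spec$input_mode, axial2d = 1L, ortho2p5d = 3L, slab3d = 1L)
  if (nd != want || dim(main)[nd - 1L] != wantc)
    stop_lungtex(sprintf(
      "input tensor does not match %s input mode of %s (dims %s)",
      spec$input_mode, spec$name, paste(dim(main), collapse = "x")),
      "lungtex_input_error")
  if (isTRUE(spec$needs_context) && (!is.list(x) || is.null(x$ctx)))
    stop_lungtex(sprintf("%s requires a context input (list(main, ctx))",
                         spec$name), "lungtex_input_error")
  invisible(TRUE)
}

#' @export
print.lungtex_model <- function(x, ...) {
  cat(sprintf("<lungtex_model> %s (%s input), %d parameters\n",
              x$arch$name, x$arch$input_mode, net_param_count(x$net)))
  if (isTRUE(x$trained) && x$stopped_epoch > 0)
    cat(sprintf("  trained %d epoch(s), best validation loss %.4f at epoch %d\n",
                x$stopped_epoch, x$best_val_loss, x$best_epoch))
  else cat("  untrained\n")
  invisible(x)
}

#' Save / load a trained model
#'
#' The weights are serialized with `saveRDS`; a JSON sidecar
#' (`<path>.json`) records the architecture, training configuration and
#' normalization statistics for provenance.
#'
#' @param model a `lungtex_model`.
#' @param path destination `.rds` path.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "lungtex_model"))
  payload <- list(arch = model$arch, config = unclass(model$config),
                  state = net_state(model$net),
                  training_log = model$training_log,
                  stopped_epoch = model$stopped_epoch,
                  best_epoch = model$best_epoch,
                  best_val_loss = model$best_val_loss,
                  trained = isTRUE(model$trained),
                  norm_stats = if (!is.null(model$norm_stats))
                    unclass(model$norm_stats))
  saveRDS(payload, path)
  side <- list(arch = model$arch[c("name", "input_mode", "filters",
                                   "dense_units", "n_classes")],
               config = unclass(model$config),
               norm_stats = payload$norm_stats,
               n_parameters = net_param_count(model$net))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  payload <- readRDS(path)
  spec <- do.call(arch_spec, payload$arch[c("name", "filters", "dense_units",
                                            "n_classes")])
  net <- build_net(spec, dropout = payload$config$dropout)
  net_restore(net, payload$state)
  structure(list(net = net, arch = spec,
                 config = do.call(train_config, payload$config),
                 training_log = payload$training_log,
                 stopped_epoch = payload$stopped_epoch,
                 best_epoch = payload$best_epoch,
                 best_val_loss = payload$best_val_loss,
                 trained = isTRUE(payload$trained),
                 norm_stats = if (!is.null(payload$norm_stats))
                   structure(payload$norm_stats, class = "norm_stats")),
            class = "lungtex_model")
}
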