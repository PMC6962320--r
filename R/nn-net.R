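# Network assembly: three topologies cover the seven architectures.
#   chain    - plain sequential stack (baseline nets)
#   mstage   - multi-stage: a mid-level feature branch (global average pooled
#              block-1 output) is concatenated with the final features before
#              the dense classification head
#   mcontext - multi-context: a parallel convolutional path processes the
#              larger-scale (downsampled 96x96) view; both paths are
#              concatenated before the head

new_net <- function(topo, pieces, arch) {
  net <- new.env(parent = emptyenv())
  net$topo <- topo
  for (nm in names(pieces)) assign(nm, pieces[[nm]], envir = net)
  net$arch <- arch
  class(net) <- "lt_net"
  net
}

fwd_seq <- function(layers, x, training) {
  for (l in layers) x <- layer_fwd(l, x, training)
  x
}

bwd_seq <- function(layers, dy) {
  for (l in rev(layers)) dy <- layer_bwd(l, dy)
  dy
}

net_forward <- function(net, x, training = FALSE) {
  switch(net$topo,
    chain = fwd_seq(net$layers, x, training),
    mstage = {
      hs <- fwd_seq(net$stem, x, training)
      ht <- fwd_seq(net$trunk, hs, training)
      f_hi <- layer_fwd(net$final_pool, ht, training)
      f_lo <- layer_fwd(net$branch_pool, hs, training)
      net$split <- c(nrow(f_hi), nrow(f_lo))
      fwd_seq(net$head, rbind(f_hi, f_lo), training)
    },
    mcontext = {
      f1 <- layer_fwd(net$main_flat, fwd_seq(net$main, x$main, training), training)
      f2 <- layer_fwd(net$ctx_flat, fwd_seq(net$ctx, x$ctx, training), training)
      net$split <- c(nrow(f1), nrow(f2))
      fwd_seq(net$head, rbind(f1, f2), training)
    })
}

net_backward <- function(net, dy) {
  switch(net$topo,
    chain = bwd_seq(net$layers, dy),
    mstage = {
      dz <- bwd_seq(net$head, dy)
      n1 <- net$split[1]
      dht <- layer_bwd(net$final_pool, dz[seq_len(n1), , drop = FALSE])
      dhs_b <- layer_bwd(net$branch_pool, dz[-seq_len(n1), , drop = FALSE])
      dhs <- bwd_seq(net$trunk, dht) + dhs_b
      bwd_seq(net$stem, dhs)
    },
    mcontext = {
      dz <- bwd_seq(net$head, dy)
      n1 <- net$split[1]
      d1 <- bwd_seq(net$main, layer_bwd(net$main_flat, dz[seq_len(n1), , drop = FALSE]))
      d2 <- bwd_seq(net$ctx, layer_bwd(net$ctx_flat, dz[-seq_len(n1), , drop = FALSE]))
      list(main = d1, ctx = d2)
    })
}

net_layers <- function(net) {
  switch(net$topo,
    chain = net$layers,
    mstage = c(net$stem, net$trunk, list(net$final_pool, net$branch_pool), net$head),
    mcontext = c(net$main, net$ctx, list(net$main_flat, net$ctx_flat), net$head))
}

net_param_count <- function(net) {
  sum(vapply(net_layers(net), function(l)
    sum(vapply(l$params, length, integer(1)), 0L), numeric(1)))
}

# Deep-copy / restore of all learnable state (params + batch-norm running
# moments), used for best-epoch checkpointing.
net_state <- function(net) {
  lapply(net_layers(net), function(l) {
    s <- list(params = l$params)
    if (l$type == "bn") s$run <- list(mean = l$run_mean, var = l$run_var)
    s
  })
}

net_restore <- function(net, state) {
  ls <- net_layers(net)
  for (t in seq_along(ls)) {
    ls[[t]]$params <- state[[t]]$params
    if (ls[[t]]$type == "bn") {
      ls[[t]]$run_mean <- state[[t]]$run$mean
      ls[[t]]$run_var <- state[[t]]$run$var
    }
  }
  invisible(net)
}

softmax_cols <- function(z) {
  z <- z - rep(apply(z, 2, max), each = nrow(z))
  e <- exp(z)
  e / rep(colSums(e), each = nrow(z))
}

#' L2-regularized categorical cross-entropy
#'
#' The training loss: cross-entropy averaged over the batch plus the weight
#' penalty `lambda/2 * sum(w^2)` over convolutional and dense weights only
#' (biases and batch-norm parameters are not penalized).
#'
#' @param probs numeric matrix of class probabilities, one column (or row,
#'   see `byrow`) per sample.
#' @param labels integer class indices in `1..n_classes`.
#' @param weights optional list/vector of weight arrays entering the penalty
#'   (e.g. from a fitted model); `NULL` means no penalty term.
#' @param l2 regularization strength lambda (default 0).
#' @param byrow set `TRUE` if `probs` has one *row* per sample.
#' @return Scalar loss.
#' @examples
#' p <- matrix(1 / 8, nrow = 8, ncol = 4)
#' cnn_loss(p, c(1, 3, 5, 8))   # log(8)
#' @export
cnn_loss <- function(probs, labels, weights = NULL, l2 = 0, byrow = FALSE) {
  if (byrow) probs <- t(probs)
  labels <- as.integer(labels)
  if (any(labels < 1L | labels > nrow(probs)))
    stop_lungtex(sprintf("labels must lie in 1..%d", nrow(probs)),
                 "lungtex_label_error")
  n <- ncol(probs)
  p <- probs[cbind(labels, seq_len(n))]
  ce <- -mean(log(pmax(p, 1e-12)))
  pen <- 0
  if (l2 > 0 && !is.null(weights))
    pen <- l2 / 2 * sum(vapply(weights, function(w) sum(w^2), numeric(1)))
  ce + pen
}

# Full training step gradient: softmax + CE + L2, computed from logits for
# numerical stability. Fills layer$grads; returns the (regularized) loss.
net_loss_grad <- function(net, x, y, l2 = 0) {
  z <- net_forward(net, x, training = TRUE)
  n <- ncol(z)
  logp <- z - rep(apply(z, 2, max), each = nrow(z))
  logp <- logp - rep(log(colSums(exp(logp))), each = nrow(z))
  ce <- -mean(logp[cbind(y, seq_len(n))])
  P <- exp(logp)
  dz <- P
  dz[cbind(y, seq_len(n))] <- dz[cbind(y, seq_len(n))] - 1
  dz <- dz / n
  net_backward(net, dz)
  pen <- 0
  for (l in net_layers(net)) {
    for (nm in l$decay) {
      if (l2 > 0) {
        pen <- pen + l2 / 2 * sum(l$params[[nm]]^2)
        l$grads[[nm]] <- l$grads[[nm]] + l2 * l$params[[nm]]
      }
    }
  }
  ce + pen
}

net_weight_arrays <- function(net) {
  out <- list()
  for (l in net_layers(net))
    for (nm in l$decay) out[[length(out) + 1L]] <- l$params[[nm]]
  out
}
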