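#' Gradient-weighted class activation map (Grad-CAM)
#'
#' Localizes the input regions driving a prediction: the gradient of the
#' target-class logit is backpropagated to the last convolutional layer's
#' activations, averaged spatially into per-channel weights, and the
#' weighted, rectified activation sum is upsampled to the input patch size.
#' Supported for the 2D architectures (baseline and multi-stage); activation
#' maps on these nets consistently highlight lesion locations on phantom
#' patches.
#'
#' @param model a trained (or frozen) `lungtex_model` with `axial2d` or
#'   `ortho2p5d` input and chain or multi-stage topology.
#' @param sample one [roi_sample][extract_roi] or a single-sample input
#'   tensor.
#' @param target_class class index (1..8) or tissue code whose evidence is
#'   mapped; defaults to the predicted class.
#' @return A nonnegative `48 x 48` matrix (same in-plane size as the input).
#' @export
gradcam <- function(model, sample, target_class = NULL) {
  stopifnot(inherits(model, "lungtex_model"))
  if (!isTRUE(model$trained))
    stop_lungtex("gradcam requires a trained (or explicitly frozen) model",
                 "lungtex_state_error")
  net <- model$net
  if (!(model$arch$input_mode %in% c("axial2d", "ortho2p5d")) ||
      net$topo == "mcontext")
    stop_lungtex(sprintf(
      "gradcam supports the 2D chain/multi-stage architectures, not %s",
      model$arch$name), "lungtex_input_error")
  if (inherits(sample, "roi_sample")) sample <- list(sample)
  x <- model_input(model, sample)
  if (n_samples(x) != 1L)
    stop_lungtex("gradcam maps one sample at a time", "lungtex_input_error")

  z <- net_forward(net, x, training = FALSE)
  if (is.null(target_class)) target_class <- which.max(z[, 1])
  if (is.character(target_class))
    target_class <- match(target_class, tissue_classes())
  if (is.na(target_class) || target_class < 1 || target_class > nrow(z))
    stop_lungtex("invalid target class", "lungtex_input_error")
  dz <- matrix(0, nrow(z), 1)
  dz[target_class, 1] <- 1

  # locate the last conv activation (output of the relu after the final conv)
  if (net$topo == "chain") {
    layers <- net$layers
    conv_pos <- max(which(vapply(layers, function(l) l$type == "conv2d",
                                 logical(1))))
    act_pos <- conv_pos + 1L                   # its relu
    A <- layers[[act_pos]]$y
    dy <- dz
    for (t in rev(seq_along(layers))) {
      if (t == act_pos) { dA <- dy; break }
      dy <- layer_bwd(layers[[t]], dy)
    }
  } else { # mstage
    A <- net$trunk[[length(net$trunk)]]$y      # relu after final conv
    dzc <- bwd_seq(net$head, dz)
    n1 <- net$split[1]
    dA <- layer_bwd(net$final_pool, dzc[seq_len(n1), , drop = FALSE])
  }
  dims <- dim(A)                               # H x W x C x 1
  alpha <- apply(dA, 3, mean)                  # spatial mean per channel
  map <- matrix(0, dims[1], dims[2])
  for (c in seq_len(dims[3])) map <- map + alpha[c] * A[, , c, 1]
  map <- pmax(map, 0)
  upsample_bilinear(map, model$arch$input_size)
}

# Bilinear upsampling of a square map to size n x n.
upsample_bilinear <- function(m, n) {
  if (nrow(m) == n && ncol(m) == n) return(m)
  if (nrow(m) < 2L || ncol(m) < 2L)
    return(matrix(m[1, 1], n, n))
  xi <- seq(0, nrow(m) - 1, length.out = n)
  yi <- seq(0, ncol(m) - 1, length.out = n)
  i0 <- pmin(floor(xi), nrow(m) - 2)
  j0 <- pmin(floor(yi), ncol(m) - 2)
  FI <- matrix(xi - i0, n, n)
  FJ <- matrix(yi - j0, n, n, byrow = TRUE)
  m00 <- m[i0 + 1, j0 + 1]; m10 <- m[i0 + 2, j0 + 1]
  m01 <- m[i0 + 1, j0 + 2]; m11 <- m[i0 + 2, j0 + 2]
  (1 - FI) * (1 - FJ) * m00 + FI * (1 - FJ) * m10 +
    (1 - FI) * FJ * m01 + FI * FJ * m11
}
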