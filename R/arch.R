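#' Architecture specifications for the seven ensemble networks
#'
#' The ensemble combines seven convolutional networks over three input
#' dimensionalities:
#' \describe{
#'   \item{BCNN2D}{baseline 2D net on 48 x 48 axial patches: a deeper LeNet
#'     variant where every 5 x 5 convolution is replaced by two 3 x 3
#'     convolutions, pooling is kept sparse to preserve spatial detail, and a
#'     batch-normalization layer follows every pooling step. Layer plan:
#'     `[conv3x3(32) x2, maxpool2, BN] x2 -> conv3x3(64) x2 -> dense(128) ->
#'     dense(8, softmax)`.}
#'   \item{MSTAGE_CNN2D}{multi-stage variant: block-1 features are branched,
#'     globally average-pooled and concatenated with the final features
#'     before the dense head, mixing mid-level local structure with
#'     high-level context.}
#'   \item{MCONTEXT_CNN2D}{multi-context variant: a parallel convolutional
#'     path processes a larger-scale view (96 x 96 neighbourhood
#'     average-pooled to 48 x 48); both paths are fused before the head.}
#'   \item{BCNN2p5D / MSTAGE_CNN2p5D}{the same plans fed the three
#'     orthogonal planes (axial, sagittal, coronal) as a 3-channel input.}
#'   \item{BCNN3D / MSTAGE_CNN3D}{3 x 3 x 3 kernels on the 48 x 48 x 7 slab
#'     with pooling restricted to the axial plane (the 7-slice z extent is
#'     too thin to pool); global average pooling feeds the dense head.}
#' }
#' All convolutions use "same" zero padding; dropout applies to the dense
#' head only. Filter counts are configurable; the defaults (32, 32, 64;
#' dense 128) keep models around one million parameters or less, since
#' over-deep architectures overfit patch-scale texture data.
#'
#' @param name one of `BCNN2D`, `MSTAGE_CNN2D`, `MCONTEXT_CNN2D`,
#'   `BCNN2p5D`, `MSTAGE_CNN2p5D`, `BCNN3D`, `MSTAGE_CNN3D`.
#' @param filters integer length-3: channels of conv blocks 1-3.
#' @param dense_units width of the dense head.
#' @param n_classes number of output classes (8).
#' @param input_size in-plane patch size (48).
#' @param slab_depth z extent of the 3D slab (7).
#' @return `arch_spec()` returns an `arch_spec` object; `arch_names()` the
#'   seven canonical names in ensemble weight order.
#' @export
arch_spec <- function(name, filters = c(32L, 32L, 64L), dense_units = 128L,
                      n_classes = 8L, input_size = 48L, slab_depth = 7L) {
  if (!(name %in% arch_names()))
    stop_lungtex(sprintf("unknown architecture '%s'; expected one of %s",
                         name, paste(arch_names(), collapse = ", ")),
                 "lungtex_spec_error")
  input_mode <- switch(name,
    BCNN2D = , MSTAGE_CNN2D = , MCONTEXT_CNN2D = "axial2d",
    BCNN2p5D = , MSTAGE_CNN2p5D = "ortho2p5d",
    BCNN3D = , MSTAGE_CNN3D = "slab3d")
  structure(list(name = name, input_mode = input_mode,
                 needs_context = name == "MCONTEXT_CNN2D",
                 filters = as.integer(filters),
                 dense_units = as.integer(dense_units),
                 n_classes = as.integer(n_classes),
                 input_size = as.integer(input_size),
                 slab_depth = as.integer(slab_depth)),
            class = "arch_spec")
}

#' @rdname arch_spec
#' @export
arch_names <- function() {
  c("BCNN2D", "MSTAGE_CNN2D", "MCONTEXT_CNN2D", "BCNN2p5D", "MSTAGE_CNN2p5D",
    "BCNN3D", "MSTAGE_CNN3D")
}

# conv block: two 3x3 convolutions (+ relu); optionally maxpool + BN
conv_block2d <- function(c_in, c_out, pool = TRUE) {
  ls <- list(layer_conv2d(c_in, c_out), layer_relu(),
             layer_conv2d(c_out, c_out), layer_relu())
  if (pool) ls <- c(ls, list(layer_pool(), layer_bn(c_out)))
  ls
}

conv_block3d <- function(c_in, c_out, pool = TRUE) {
  ls <- list(layer_conv3d(c_in, c_out), layer_relu(),
             layer_conv3d(c_out, c_out), layer_relu())
  if (pool) ls <- c(ls, list(layer_pool(), layer_bn(c_out)))
  ls
}

dense_head <- function(n_in, dense_units, n_classes, dropout) {
  list(layer_dense(n_in, dense_units), layer_relu(), layer_dropout(dropout),
       layer_dense(dense_units, n_classes))
}

build_net <- function(spec, dropout = 0.5) {
  f <- spec$filters
  s4 <- (spec$input_size %/% 4L)^2          # spatial cells after two pools
  c_in <- if (spec$input_mode == "ortho2p5d") 3L else 1L
  conv2d_stack <- function() c(conv_block2d(c_in, f[1]),
                               conv_block2d(f[1], f[2]),
                               conv_block2d(f[2], f[3], pool = FALSE))
  switch(spec$name,
    BCNN2D = , BCNN2p5D = new_net("chain", list(layers = c(
      conv2d_stack(), list(layer_flatten()),
      dense_head(s4 * f[3], spec$dense_units, spec$n_classes, dropout))),
      spec),
    MSTAGE_CNN2D = , MSTAGE_CNN2p5D = new_net("mstage", list(
      stem = conv_block2d(c_in, f[1]),
      trunk = c(conv_block2d(f[1], f[2]), conv_block2d(f[2], f[3], pool = FALSE)),
      final_pool = layer_flatten(),
      branch_pool = layer_gap(),
      head = dense_head(s4 * f[3] + f[1], spec$dense_units, spec$n_classes,
                        dropout)), spec),
    MCONTEXT_CNN2D = new_net("mcontext", list(
      main = conv2d_stack(),
      ctx = conv2d_stack(),
      main_flat = layer_flatten(),
      ctx_flat = layer_flatten(),
      head = dense_head(2L * s4 * f[3], spec$dense_units, spec$n_classes,
                        dropout)), spec),
    BCNN3D = new_net("chain", list(layers = c(
      conv_block3d(1L, f[1]), conv_block3d(f[1], f[2]),
      conv_block3d(f[2], f[3], pool = FALSE),
      list(layer_gap()),
      dense_head(f[3], spec$dense_units, spec$n_classes, dropout))), spec),
    MSTAGE_CNN3D = new_net("mstage", list(
      stem = conv_block3d(1L, f[1]),
      trunk = c(conv_block3d(f[1], f[2]), conv_block3d(f[2], f[3], pool = FALSE)),
      final_pool = layer_gap(),
      branch_pool = layer_gap(),
      head = dense_head(f[3] + f[1], spec$dense_units, spec$n_classes,
                        dropout)), spec))
}

#' Build an untrained network
#'
#' Instantiates one of the seven architectures with seeded He-uniform
#' initialization. The returned object already supports [predict_proba()]
#' (outputs are post-softmax probabilities summing to 1) and is trained with
#' [train_cnn()].
#'
#' @param spec an [arch_spec] (or an architecture name).
#' @param config a [train_config] (supplies dropout rate and the
#'   initialization seed).
#' @return An untrained `lungtex_model`.
#' @examples
#' m <- build_model("BCNN2D", train_config(seed = 1))
#' x <- array(rnorm(48 * 48 * 2), dim = c(48, 48, 1, 2))
#' rowSums(predict_proba(m, x))   # each 1
#' @export
build_model <- function(spec, config = train_config()) {
  if (is.character(spec)) spec <- arch_spec(spec)
  stopifnot(inherits(spec, "arch_spec"), inherits(config, "train_config"))
  net <- with_seed(config$seed, build_net(spec, dropout = config$dropout))
  structure(list(net = net, arch = spec, config = config,
                 training_log = data.frame(), stopped_epoch = 0L,
                 best_epoch = 0L, best_val_loss = NA_real_,
                 trained = FALSE, norm_stats = NULL),
            class = "lungtex_model")
}

# Mark an untrained model as frozen (treated as trained for diagnostics).
freeze_model <- function(model) {
  model$trained <- TRUE
  model
}
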