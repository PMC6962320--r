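#' Extract a region of interest around an annotated point
#'
#' Extracts the network input patch centred on an annotated voxel in one of
#' three dimensionalities:
#' \describe{
#'   \item{`axial2d`}{a 48 x 48 axial (x,y) plane through the point;}
#'   \item{`ortho2p5d`}{three 48 x 48 planes (axial, sagittal, coronal)
#'     sharing the point, stacked as channels;}
#'   \item{`slab3d`}{a 48 x 48 x 7 block, seven consecutive axial slices
#'     centred on the point.}
#' }
#' Patch size is in voxel units (native spacing, no resampling); 48 px axial
#' patches cover a secondary pulmonary lobule at typical CT spacings. For an
#' even patch size the centre voxel sits at patch index `size/2` (24 for 48),
#' so the centre value is identical across the three 2.5D planes. Points
#' closer to the volume border than the patch half-width are handled by
#' mirror reflection (`border = "reflect"`, the default, appropriate for
#' subpleural points) or rejected (`border = "strict"`).
#'
#' @param vol a [ct_volume].
#' @param pt either a 1-row annotation data.frame (see [read_annotations()])
#'   or an integer vector `c(i, j, k)` of 1-based voxel indices.
#' @param mode one of `"axial2d"`, `"ortho2p5d"`, `"slab3d"`.
#' @param size in-plane patch size in voxels (default 48).
#' @param slab_depth number of axial slices for `slab3d` (default 7).
#' @param context if `TRUE`, additionally extract a `2*size` axial patch
#'   average-pooled back to `size` (the larger-scale view consumed by the
#'   multi-context architecture).
#' @param border `"reflect"` or `"strict"`.
#' @return An object of class `roi_sample`: list with `mode`, `data` (matrix
#'   or array), optional `context`, `label`, `coord`, `scan_id`,
#'   `normalized`.
#' @export
extract_roi <- function(vol, pt, mode = c("axial2d", "ortho2p5d", "slab3d"),
                        size = 48L, slab_depth = 7L, context = FALSE,
                        border = c("reflect", "strict")) {
  mode <- match.arg(mode)
  border <- match.arg(border)
  stopifnot(inherits(vol, "ct_volume"))
  if (is.data.frame(pt)) {
    coord <- c(pt$i[1], pt$j[1], pt$k[1])
    label <- as.character(pt$label[1])
    scan_id <- as.character(pt$scan_id[1] %||% NA_character_)
  } else {
    coord <- as.integer(pt)
    label <- attr(pt, "label") %||% NA_character_
    scan_id <- NA_character_
  }
  d <- dim(vol$voxels)
  half_lo <- size %/% 2L - 1L     # offsets -(size/2 - 1) .. size/2
  half_hi <- size %/% 2L
  zhalf <- slab_depth %/% 2L
  idx_axis <- function(c0, n, lo, hi) {
    v <- (c0 - lo):(c0 + hi)
    if (border == "strict" && (v[1] < 1L || v[length(v)] > n))
      stop_lungtex(sprintf(
        "point (%d,%d,%d) too close to volume border for a %d-voxel patch (strict mode)",
        coord[1], coord[2], coord[3], size), "lungtex_extraction_error")
    reflect_index(v, n)
  }
  ix <- idx_axis(coord[1], d[1], half_lo, half_hi)
  iy <- idx_axis(coord[2], d[2], half_lo, half_hi)
  if (mode == "slab3d") {
    iz <- idx_axis(coord[3], d[3], zhalf, zhalf)
    dat <- vol$voxels[ix, iy, iz, drop = FALSE]
    dim(dat) <- c(size, size, slab_depth)
  } else if (mode == "axial2d") {
    dat <- vol$voxels[ix, iy, coord[3]]
    dim(dat) <- c(size, size)
  } else { # ortho2p5d
    iz <- idx_axis(coord[3], d[3], half_lo, half_hi)
    axial    <- vol$voxels[ix, iy, coord[3]]
    sagittal <- vol$voxels[coord[1], iy, iz]
    coronal  <- vol$voxels[ix, coord[2], iz]
    dat <- array(c(axial, sagittal, coronal), dim = c(size, size, 3L))
  }
  ctx <- NULL
  if (context) {
    cl <- size - 1L
    ch <- size
    cx <- idx_axis(coord[1], d[1], cl, ch)
    cy <- idx_axis(coord[2], d[2], cl, ch)
    big <- vol$voxels[cx, cy, coord[3]]
    dim(big) <- c(2L * size, 2L * size)
    ctx <- downsample2(big)
  }
  structure(list(mode = mode, data = dat, context = ctx, label = label,
                 coord = coord, scan_id = scan_id, normalized = FALSE),
            class = "roi_sample")
}

# 2x2 average pooling (used for the multi-context large-scale input).
downsample2 <- function(m) {
  h <- nrow(m) %/% 2L
  w <- ncol(m) %/% 2L
  0.25 * (m[seq(1, 2 * h, 2), seq(1, 2 * w, 2)] +
          m[seq(2, 2 * h, 2), seq(1, 2 * w, 2)] +
          m[seq(1, 2 * h, 2), seq(2, 2 * w, 2)] +
          m[seq(2, 2 * h, 2), seq(2, 2 * w, 2)])
}

#' @export
print.roi_sample <- function(x, ...) {
  cat(sprintf("<roi_sample> mode %s, dims %s, label %s%s\n", x$mode,
              paste(dim(x$data) %||% length(x$data), collapse = "x"),
              x$label,
              if (x$normalized) " (normalized)" else " (HU)"))
  invisible(x)
}

#' Attenuation normalization
#'
#' `fit_normalization()` pools every voxel of the supplied patches (the
#' training + validation patches, per the evaluation protocol) and returns
#' their mean and *population* standard deviation (divisor `n`, not `n - 1`;
#' pinned for reproducibility). `apply_normalization()` replaces every voxel
#' `v` by `(v - mean) / std`, leaving label and geometry untouched;
#' `invert_normalization()` undoes it.
#'
#' @param samples list of [roi_sample][extract_roi] objects (at least 2, with
#'   more than one voxel in total).
#' @return `fit_normalization()` returns a `norm_stats` object with fields
#'   `mean` and `std` (HU); the others return the transformed sample.
#' @export
fit_normalization <- function(samples) {
  if (inherits(samples, "roi_sample")) samples <- list(samples)
  if (length(samples) < 2L)
    stop_lungtex("need at least 2 samples to fit normalization",
                 "lungtex_normalization_error")
  v <- unlist(lapply(samples, function(s) as.numeric(s$data)), use.names = FALSE)
  if (length(v) <= 1L)
    stop_lungtex("need more than one voxel to fit normalization",
                 "lungtex_normalization_error")
  mu <- mean(v)
  sdev <- sqrt(mean((v - mu)^2))
  if (!is.finite(sdev) || sdev <= 0)
    stop_lungtex("pooled voxel variance is zero; cannot normalize",
                 "lungtex_normalization_error")
  structure(list(mean = mu, std = sdev), class = "norm_stats")
}

#' @rdname fit_normalization
#' @param s a [roi_sample][extract_roi].
#' @param stats a `norm_stats` object.
#' @export
apply_normalization <- function(s, stats) {
  stopifnot(inherits(s, "roi_sample"), inherits(stats, "norm_stats"))
  if (stats$std <= 0)
    stop_lungtex("invalid normalization stats (std <= 0)",
                 "lungtex_normalization_error")
  s$data <- (s$data - stats$mean) / stats$std
  if (!is.null(s$context)) s$context <- (s$context - stats$mean) / stats$std
  s$normalized <- TRUE
  s
}

#' @rdname fit_normalization
#' @export
invert_normalization <- function(s, stats) {
  stopifnot(inherits(s, "roi_sample"), inherits(stats, "norm_stats"))
  s$data <- s$data * stats$std + stats$mean
  if (!is.null(s$context)) s$context <- s$context * stats$std + stats$mean
  s$normalized <- FALSE
  s
}

# Stack a list of roi_samples into the dense arrays consumed by the CNN
# engine. Returns list(x = array or list(main, ctx), y = integer labels).
roi_stack <- function(samples, needs_context = FALSE) {
  stopifnot(length(samples) > 0)
  mode <- samples[[1]]$mode
  n <- length(samples)
  s1 <- samples[[1]]$data
  if (mode == "axial2d") {
    x <- array(0, dim = c(nrow(s1), ncol(s1), 1L, n))
    for (t in seq_len(n)) x[, , 1L, t] <- samples[[t]]$data
  } else if (mode == "ortho2p5d") {
    x <- array(0, dim = c(dim(s1), n))
    for (t in seq_len(n)) x[, , , t] <- samples[[t]]$data
  } else {
    x <- array(0, dim = c(dim(s1), 1L, n))
    for (t in seq_len(n)) x[, , , 1L, t] <- samples[[t]]$data
  }
  out <- list(x = x)
  if (needs_context) {
    if (is.null(samples[[1]]$context))
      stop_lungtex("samples lack the context patch required by this architecture",
                   "lungtex_input_error")
    ctx <- array(0, dim = c(dim(samples[[1]]$context), 1L, n))
    for (t in seq_len(n)) ctx[, , 1L, t] <- samples[[t]]$context
    out$x <- list(main = x, ctx = ctx)
  }
  labs <- vapply(samples, function(s) as.character(s$label), character(1))
  if (!anyNA(labs)) out$y <- as.integer(as_tissue_factor(labs))
  out
}
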