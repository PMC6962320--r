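# Whole-lung labeling on a sparse grid and certainty-thresholded ILA scoring.

# Classifier contract: anything passed to classify_scan must yield an
# N x 8 (row-)probability matrix for a list of roi_samples. Plain functions,
# single trained models and weighted ensembles all qualify.
predict_tissue_probs <- function(object, vol, nodes, mode = "axial2d",
                                 batch = 256L, norm_stats = NULL, ...) {
  UseMethod("predict_tissue_probs")
}

#' @export
predict_tissue_probs.function <- function(object, vol, nodes, mode = "axial2d",
                                          batch = 256L, norm_stats = NULL, ...) {
  samples <- extract_node_samples(vol, nodes, mode, norm_stats,
                                  context = FALSE)
  object(samples)
}

#' @export
predict_tissue_probs.lungtex_model <- function(object, vol, nodes,
                                               mode = NULL, batch = 256L,
                                               norm_stats = NULL, ...) {
  mode <- object$arch$input_mode
  samples <- extract_node_samples(vol, nodes, mode,
                                  norm_stats %||% object$norm_stats,
                                  context = isTRUE(object$arch$needs_context))
  predict_proba(object, samples, batch = batch)
}

#' @export
predict_tissue_probs.lungtex_ensemble <- function(object, vol, nodes,
                                                  mode = NULL, batch = 256L,
                                                  norm_stats = NULL, ...) {
  P <- lapply(object$models, function(m)
    predict_tissue_probs(m, vol, nodes, batch = batch,
                         norm_stats = norm_stats, ...))
  fuse(P, object$w)
}

extract_node_samples <- function(vol, nodes, mode, norm_stats, context) {
  lapply(seq_len(nrow(nodes)), function(t) {
    s <- extract_roi(vol, as.integer(nodes[t, ]), mode = mode,
                     context = context, border = "reflect")
    if (!is.null(norm_stats)) s <- apply_normalization(s, norm_stats)
    s
  })
}

#' Classify a whole lung on a sparse voxel grid
#'
#' Patches are extracted and classified at every node of a fixed sampling
#' grid (spacing `grid_spacing` voxels per axis) that falls inside the lung
#' mask; every other in-mask voxel then takes the label and certainty of
#' its nearest classified node (voxel-unit Euclidean distance, ties to the
#' lowest node index — a nearest-neighbor interpolation of the sparse
#' labeling). `grid_spacing = 1` is exhaustive per-voxel classification.
#' The certainty of a voxel is the (renormalized) probability the
#' classifier assigns to its predicted label.
#'
#' @param vol a [ct_volume] with a lung mask.
#' @param classifier a trained `lungtex_model`, a `lungtex_ensemble`, or a
#'   function mapping a list of [roi_sample][extract_roi]s to an `N x 8`
#'   probability matrix.
#' @param grid_spacing grid step in voxels (>= 1; default 5).
#' @param batch forward-pass chunk size.
#' @param norm_stats optional [norm_stats][fit_normalization] applied to
#'   each patch before classification.
#' @param ... passed to the classifier dispatch.
#' @return A `label_map`: list with `labels` (integer array; 0 outside the
#'   lung, else 1..8), `certainty` (array in `[0,1]`, `NA` outside),
#'   `classes`, `nodes` (data.frame of classified grid nodes with label and
#'   certainty).
#' @export
classify_scan <- function(vol, classifier, grid_spacing = 5L, batch = 256L,
                          norm_stats = NULL, ...) {
  stopifnot(inherits(vol, "ct_volume"))
  if (is.null(vol$lung_mask))
    stop_lungtex("classify_scan requires a lung mask", "lungtex_input_error")
  grid_spacing <- as.integer(grid_spacing)
  if (grid_spacing < 1L)
    stop_lungtex("grid_spacing must be >= 1", "lungtex_parameter_error")
  d <- dim(vol$voxels)
  gi <- seq(1L, d[1], by = grid_spacing)
  gj <- seq(1L, d[2], by = grid_spacing)
  gk <- seq(1L, d[3], by = grid_spacing)
  nodes <- as.matrix(expand.grid(i = gi, j = gj, k = gk,
                                 KEEP.OUT.ATTRS = FALSE))
  inmask <- vol$lung_mask[nodes] != 0
  nodes <- nodes[inmask, , drop = FALSE]
  if (nrow(nodes) == 0L)
    stop_lungtex("no grid nodes fall inside the lung mask",
                 "lungtex_empty_lung_error")
  P <- predict_tissue_probs(classifier, vol, nodes, batch = batch,
                            norm_stats = norm_stats, ...)
  if (!is.matrix(P) || nrow(P) != nrow(nodes))
    stop_lungtex("classifier must return one probability row per grid node",
                 "lungtex_input_error")
  Pn <- sweep(P, 1, pmax(rowSums(P), 1e-12), "/")
  node_label <- apply(Pn, 1, which.max)
  node_cert <- Pn[cbind(seq_len(nrow(Pn)), node_label)]
  assign_idx <- cpp_nearest_node(as.integer(vol$lung_mask), d,
                                 matrix(as.numeric(nodes), ncol = 3))
  labels <- array(0L, dim = d)
  certainty <- array(NA_real_, dim = d)
  inl <- assign_idx > 0L
  labels[inl] <- node_label[assign_idx[inl]]
  certainty[inl] <- node_cert[assign_idx[inl]]
  nodes_df <- data.frame(i = nodes[, 1], j = nodes[, 2], k = nodes[, 3],
                         label = tissue_classes()[node_label],
                         certainty = node_cert)
  structure(list(labels = labels, certainty = certainty,
                 classes = tissue_classes(), nodes = nodes_df,
                 grid_spacing = grid_spacing),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  n <- sum(x$labels > 0)
  cat(sprintf("<label_map> %d lung voxels, grid spacing %d, %d nodes\n",
              n, x$grid_spacing, nrow(x$nodes)))
  tab <- table(factor(x$classes[x$labels[x$labels > 0]], levels = x$classes))
  print(tab)
  invisible(x)
}

#' Certainty-thresholded ILA score
#'
#' The interstitial-lung-abnormality score of a labeled lung: the
#' percentage of lung voxels carrying any interstitial label (ground glass,
#' reticular, nodular, linear scar, subpleural line — emphysema labels are
#' excluded by default) with certainty strictly greater than the threshold.
#' The score is non-increasing in the threshold; the default threshold used
#' for subject-level ILA detection is 0.95.
#'
#' @param map a `label_map` from [classify_scan()].
#' @param threshold certainty cutoff in `[0, 1]` (strict inequality).
#' @param ila_classes label set counted as interstitial (default
#'   [interstitial_classes()]).
#' @return An `ila_score` object: list with `threshold`, `score`
#'   (percentage in `[0, 100]`), `n_lung`, `n_ila`.
#' @export
ila_score <- function(map, threshold = 0.95,
                      ila_classes = interstitial_classes()) {
  stopifnot(inherits(map, "label_map"))
  if (!is.finite(threshold) || threshold < 0 || threshold > 1)
    stop_lungtex("threshold must lie in [0, 1]", "lungtex_parameter_error")
  lung <- map$labels > 0L
  n_lung <- sum(lung)
  ila_idx <- match(ila_classes, map$classes)
  hit <- lung & (map$labels %in% ila_idx) & !is.na(map$certainty) &
    (map$certainty > threshold)
  n_ila <- sum(hit)
  structure(list(threshold = threshold, score = 100 * n_ila / n_lung,
                 n_lung = n_lung, n_ila = n_ila),
            class = "ila_score")
}

#' @export
print.ila_score <- function(x, ...) {
  cat(sprintf("ILA score %.2f%% (certainty > %.2f; %d of %d lung voxels)\n",
              x$score, x$threshold, x$n_ila, x$n_lung))
  invisible(x)
}

#' @rdname ila_score
#' @param thresholds vector of cutoffs.
#' @return `ila_curve()` returns a data.frame of `threshold`, `score`.
#' @export
ila_curve <- function(map, thresholds = seq(0, 1, by = 0.05),
                      ila_classes = interstitial_classes()) {
  data.frame(threshold = thresholds,
             score = vapply(thresholds, function(t)
               ila_score(map, t, ila_classes)$score, numeric(1)))
}

#' Certainty overlay raster
#'
#' Exports the certainty of one axial slice partitioned into ILA-labeled
#' (yellow) and non-ILA (blue) voxel groups, as an RGB raster suitable for
#' 8-bit PNG export; background is black.
#'
#' @param map a `label_map`.
#' @param k axial slice index.
#' @param ila_classes labels forming the ILA group.
#' @return `certainty_overlay()` returns an `H x W x 3` RGB array in
#'   `[0, 1]`; `write_certainty_png()` writes it 8-bit quantized and
#'   returns the path.
#' @export
certainty_overlay <- function(map, k, ila_classes = interstitial_classes()) {
  stopifnot(inherits(map, "label_map"))
  lab <- map$labels[, , k]
  cert <- map$certainty[, , k]
  ila_idx <- match(ila_classes, map$classes)
  rgb <- array(0, dim = c(dim(lab), 3L))
  inl <- lab > 0L
  is_ila <- inl & matrix(lab %in% ila_idx, nrow(lab))
  c0 <- ifelse(is.na(cert), 0, cert)
  rgb[, , 1][is_ila] <- c0[is_ila]              # yellow = R + G
  rgb[, , 2][is_ila] <- c0[is_ila]
  rgb[, , 3][inl & !is_ila] <- c0[inl & !is_ila] # blue
  rgb
}

#' @rdname certainty_overlay
#' @param path output PNG path.
#' @export
write_certainty_png <- function(map, k, path,
                                ila_classes = interstitial_classes()) {
  rgb <- certainty_overlay(map, k, ila_classes)
  png::writePNG(round(rgb * 255) / 255, path)
  invisible(path)
}

#' Export a label map as an integer-coded volume
#'
#' Writes the label array aligned to the source volume plus a JSON legend
#' mapping integer codes to tissue classes.
#'
#' @param map a `label_map`.
#' @param vol the source [ct_volume] (supplies spacing).
#' @param path output volume path (`.nii`, `.nii.gz` or `.nrrd`).
#' @export
write_label_map <- function(map, vol, path) {
  lv <- ct_volume(array(as.numeric(map$labels), dim = dim(map$labels)),
                  spacing = vol$spacing)
  write_volume(lv, path)
  legend <- as.list(stats::setNames(seq_along(map$classes), map$classes))
  jsonlite::write_json(list(background = 0, classes = legend),
                       paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Extract every network input representation for a set of points
#'
#' Convenience for running the seven-member ensemble on arbitrary points:
#' extracts the axial 2D patch (with the large-scale context view), the
#' 2.5D orthogonal-plane triplet and the 3D slab for each point.
#'
#' @param vol a [ct_volume].
#' @param points annotation data.frame.
#' @param norm_stats optional normalization applied to each patch.
#' @return List with elements `axial2d`, `ortho2p5d`, `slab3d`, each a list
#'   of [roi_sample][extract_roi]s.
#' @export
extract_point_inputs <- function(vol, points, norm_stats = NULL) {
  per_mode <- function(mode, context = FALSE) {
    lapply(seq_len(nrow(points)), function(t) {
      s <- extract_roi(vol, points[t, ], mode = mode, context = context)
      if (!is.null(norm_stats)) s <- apply_normalization(s, norm_stats)
      s
    })
  }
  list(axial2d = per_mode("axial2d", context = TRUE),
       ortho2p5d = per_mode("ortho2p5d"),
       slab3d = per_mode("slab3d"))
}
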