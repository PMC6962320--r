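#' Geometric patch transforms
#'
#' In-plane affine augmentation combining rotation, horizontal/vertical
#' shifts, flips and shearing, applied about the patch centre with bilinear
#' interpolation and mirror-reflected boundaries. The identity transform
#' returns the input unchanged.
#'
#' @param rotation rotation angle in degrees (counter-clockwise in index
#'   space).
#' @param shift length-2 numeric, translation in pixels along the two patch
#'   axes.
#' @param flip_h,flip_v flip along the first / second patch axis.
#' @param shear shear angle in degrees.
#' @return `geom_transform()` returns a `geom_transform` object;
#'   `identity_transform()` is the all-zero transform.
#' @export
geom_transform <- function(rotation = 0, shift = c(0, 0), flip_h = FALSE,
                           flip_v = FALSE, shear = 0) {
  structure(list(rotation = rotation, shift = as.numeric(shift),
                 flip_h = isTRUE(flip_h), flip_v = isTRUE(flip_v),
                 shear = shear),
            class = "geom_transform")
}

#' @rdname geom_transform
#' @export
identity_transform <- function() geom_transform()

is_identity_transform <- function(t) {
  t$rotation == 0 && all(t$shift == 0) && !t$flip_h && !t$flip_v && t$shear == 0
}

# Inverse affine map (2x3, 0-based pixel coordinates, output -> source) of
# the forward transform: flip, then rotate+shear about the centre, then shift.
transform_inverse_matrix <- function(t, h, w) {
  th <- t$rotation * pi / 180
  sh <- tan(t$shear * pi / 180)
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  S <- matrix(c(1, 0, sh, 1), 2, 2)
  Fm <- diag(c(if (t$flip_h) -1 else 1, if (t$flip_v) -1 else 1))
  A <- R %*% S %*% Fm
  Ainv <- solve(A)
  centre <- c((h - 1) / 2, (w - 1) / 2)
  offset <- centre - Ainv %*% (centre + t$shift)
  cbind(Ainv, offset)
}

#' Apply a geometric transform to a patch
#'
#' Applies the transform plane-by-plane (each channel of a 2.5D sample and
#' the optional context patch are warped with the same parameters). The
#' label, geometry and normalization state are preserved. 3D slabs are not
#' supported (geometric balancing targets the 2D/2.5D representations).
#'
#' @param s a [roi_sample][extract_roi] (2D or 2.5D).
#' @param t a [geom_transform].
#' @return The transformed `roi_sample`.
#' @export
apply_geometric <- function(s, t) {
  stopifnot(inherits(s, "roi_sample"), inherits(t, "geom_transform"))
  if (s$mode == "slab3d")
    stop_lungtex("geometric augmentation operates on 2D/2.5D samples",
                 "lungtex_input_error")
  if (is_identity_transform(t)) return(s)
  warp <- function(m) {
    M <- transform_inverse_matrix(t, nrow(m), ncol(m))
    cpp_affine_warp2d(m, M)
  }
  if (is.matrix(s$data)) {
    s$data <- warp(s$data)
  } else {
    for (c in seq_len(dim(s$data)[3])) s$data[, , c] <- warp(s$data[, , c])
  }
  if (!is.null(s$context)) s$context <- warp(s$context)
  s
}

#' Augmentation parameter ranges
#'
#' Configuration for drawing random geometric transforms: rotation, shift and
#' shear are drawn uniformly from symmetric ranges; flips are fair coin
#' tosses when enabled.
#'
#' @param rotation_range max |rotation| in degrees.
#' @param shift_range max |shift| in pixels (both axes).
#' @param shear_range max |shear| in degrees.
#' @param flip enable random flips.
#' @export
augment_config <- function(rotation_range = 15, shift_range = 3,
                           shear_range = 8, flip = TRUE) {
  structure(list(rotation_range = rotation_range, shift_range = shift_range,
                 shear_range = shear_range, flip = flip),
            class = "augment_config")
}

#' @rdname augment_config
#' @param config an `augment_config`.
#' @param seed optional RNG seed (caller's RNG state is restored).
#' @return `draw_geom_transform()` returns a random [geom_transform].
#' @export
draw_geom_transform <- function(config = augment_config(), seed = NULL) {
  with_seed(seed, {
    geom_transform(
      rotation = runif(1, -config$rotation_range, config$rotation_range),
      shift = runif(2, -config$shift_range, config$shift_range),
      flip_h = config$flip && runif(1) < 0.5,
      flip_v = config$flip && runif(1) < 0.5,
      shear = runif(1, -config$shear_range, config$shear_range))
  })
}

# --- sponge-model density augmentation ---------------------------------------

#' Sponge-model inspiration-level augmentation
#'
#' The sponge model of the lung assumes tissue mass is conserved over the
#' respiratory cycle, so a change in lung volume from `V` to `V + dV`
#' rescales tissue density (attenuation above air) by `V / (V + dV)`:
#' `HU' = (HU - air_hu) * V / (V + dV) + air_hu`. Random volume
#' perturbations of +/-100 mL (the default range) emulate mild fluctuations
#' in inspiratory level, making trained models robust to the respiratory
#' state at acquisition.
#'
#' @param lung_volume scan-level total lung volume V in mL (> 0); when a
#'   lung mask is available use [lung_volume_ml()], otherwise a nominal
#'   default (5000 mL) stands in.
#' @param delta_v volume perturbation dV in mL; `lung_volume + delta_v` must
#'   be positive.
#' @param air_hu HU reference for zero density (default -1000, air).
#' @return `sponge_params()` returns a validated parameter object.
#' @export
sponge_params <- function(lung_volume = 5000, delta_v = 0, air_hu = -1000) {
  if (!is.finite(lung_volume) || lung_volume <= 0)
    stop_lungtex("lung_volume must be positive (mL)", "lungtex_parameter_error")
  if (!is.finite(delta_v) || lung_volume + delta_v <= 0)
    stop_lungtex("lung_volume + delta_v must be positive (mL)",
                 "lungtex_parameter_error")
  structure(list(lung_volume = lung_volume, delta_v = delta_v,
                 air_hu = air_hu),
            class = "sponge_params")
}

#' @rdname sponge_params
#' @param s a [roi_sample][extract_roi] in HU (pre-normalization), or a bare
#'   numeric array of HU values.
#' @param p a `sponge_params` object.
#' @return `sponge_augment()` returns the density-rescaled sample (same
#'   type as `s`). Mass conservation holds exactly:
#'   `mean(density') * (V + dV) == mean(density) * V`.
#' @export
sponge_augment <- function(s, p) {
  stopifnot(inherits(p, "sponge_params"))
  scale <- p$lung_volume / (p$lung_volume + p$delta_v)
  rescale <- function(v) (v - p$air_hu) * scale + p$air_hu
  if (inherits(s, "roi_sample")) {
    if (isTRUE(s$normalized))
      stop_lungtex("sponge augmentation must be applied to HU patches before normalization",
                   "lungtex_parameter_error")
    s$data <- rescale(s$data)
    if (!is.null(s$context)) s$context <- rescale(s$context)
    s
  } else {
    rescale(s)
  }
}

#' @rdname sponge_params
#' @param range length-2 range (mL) for the uniform volume perturbation.
#' @param seed optional RNG seed.
#' @return `draw_sponge_params()` returns a `sponge_params` with a random
#'   `delta_v` drawn uniformly from `range`.
#' @export
draw_sponge_params <- function(lung_volume = 5000, range = c(-100, 100),
                               air_hu = -1000, seed = NULL) {
  dv <- with_seed(seed, runif(1, range[1], range[2]))
  sponge_params(lung_volume, dv, air_hu)
}

#' @rdname sponge_params
#' @param vol a [ct_volume] with a lung mask.
#' @return `lung_volume_ml()` returns the masked lung volume in mL.
#' @export
lung_volume_ml <- function(vol) {
  stopifnot(inherits(vol, "ct_volume"))
  if (is.null(vol$lung_mask))
    stop_lungtex("volume has no lung mask", "lungtex_parameter_error")
  sum(vol$lung_mask != 0) * prod(vol$spacing) / 1000
}

# --- class balancing ---------------------------------------------------------

#' Balance per-class training rosters by geometric augmentation
#'
#' Builds an equally distributed training roster: classes at or above
#' `target` points are subsampled to `target` without augmentation; classes
#' below `target` keep all their originals and add randomly transformed
#' copies (source points drawn with replacement) until the roster reaches
#' `target`. Augmented entries carry the drawn transform parameters so the
#' roster is fully reproducible from `(inputs, seed)`.
#'
#' @param points annotation data.frame (column `label`).
#' @param target roster size per class (default 600).
#' @param config an [augment_config] for drawing transforms.
#' @param seed RNG seed; fixed seed gives an identical roster.
#' @return A data.frame with the original annotation columns plus
#'   `augmented` (logical) and transform columns `rotation`, `shift_i`,
#'   `shift_j`, `flip_h`, `flip_v`, `shear`.
#' @export
balance_classes <- function(points, target = 600L,
                            config = augment_config(), seed = NULL) {
  points$label <- as_tissue_factor(points$label)
  cls <- levels(points$label)
  counts <- table(points$label)
  present <- cls[cls %in% unique(as.character(points$label))]
  if (length(present) == 0 || any(counts[present] == 0))
    stop_lungtex("cannot balance an empty class", "lungtex_balancing_error")
  empty <- cls[counts[cls] == 0]
  if (length(empty) > 0)
    stop_lungtex(sprintf("cannot balance empty class(es): %s",
                         paste(empty, collapse = ", ")),
                 "lungtex_balancing_error")
  with_seed(seed, {
    rosters <- lapply(cls, function(cl) {
      rows <- which(points$label == cl)
      n <- length(rows)
      if (n >= target) {
        sel <- if (n == target) rows else sort(sample(rows, target))
        out <- points[sel, , drop = FALSE]
        out$augmented <- FALSE
        out$rotation <- 0; out$shift_i <- 0; out$shift_j <- 0
        out$flip_h <- FALSE; out$flip_v <- FALSE; out$shear <- 0
        out
      } else {
        base <- points[rows, , drop = FALSE]
        base$augmented <- FALSE
        base$rotation <- 0; base$shift_i <- 0; base$shift_j <- 0
        base$flip_h <- FALSE; base$flip_v <- FALSE; base$shear <- 0
        deficit <- target - n
        src <- sample(rows, deficit, replace = TRUE)
        aug <- points[src, , drop = FALSE]
        aug$augmented <- TRUE
        tr <- replicate(deficit, draw_geom_transform(config), simplify = FALSE)
        aug$rotation <- vapply(tr, `[[`, numeric(1), "rotation")
        aug$shift_i <- vapply(tr, function(t) t$shift[1], numeric(1))
        aug$shift_j <- vapply(tr, function(t) t$shift[2], numeric(1))
        aug$flip_h <- vapply(tr, `[[`, logical(1), "flip_h")
        aug$flip_v <- vapply(tr, `[[`, logical(1), "flip_v")
        aug$shear <- vapply(tr, `[[`, numeric(1), "shear")
        rbind(base, aug)
      }
    })
    out <- do.call(rbind, rosters)
    rownames(out) <- NULL
    out
  })
}

# Materialize one roster row into a patch: extract the ROI and apply the
# recorded geometric transform (augmented rows only).
roster_to_sample <- function(vol, row, mode, context = FALSE, ...) {
  s <- extract_roi(vol, row, mode = mode, context = context, ...)
  if (isTRUE(row$augmented)) {
    t <- geom_transform(rotation = row$rotation,
                        shift = c(row$shift_i, row$shift_j),
                        flip_h = row$flip_h, flip_v = row$flip_v,
                        shear = row$shear)
    if (mode != "slab3d") s <- apply_geometric(s, t)
  }
  s
}
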