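#' Synthetic texture phantom specification
#'
#' Parametric CT phantoms with eight texture classes placed inside an
#' elliptic-cylinder "lung" mask. Textures are designed for separability
#' and geometric plausibility (subpleural lesions near the pleural border,
#' centrilobular holes central), not radiological realism:
#' \describe{
#'   \item{NP}{lung-base attenuation (-850 HU) + Gaussian noise;}
#'   \item{GG}{smooth +150 HU haze plateau with tapered rim;}
#'   \item{RETIC}{oriented +300 HU line lattice;}
#'   \item{NOD}{cluster of small bright spheres;}
#'   \item{LINSC}{single elongated bright streak;}
#'   \item{SUBPL}{bright band within 5 voxels of the mask border;}
#'   \item{PS}{subpleural low-density (-980 HU) pocket;}
#'   \item{CL}{scattered central low-density holes.}
#' }
#' Default per-class point counts mimic the heavily skewed clinical
#' annotation database (23696 NP down to 117 NOD), scaled down by
#' `count_scale` for desk-size volumes.
#'
#' @param shape volume dimensions in voxels.
#' @param spacing voxel spacing in mm.
#' @param class_counts named integer vector of points per class.
#' @param base_hu lung parenchyma base attenuation (HU).
#' @param air_hu attenuation outside the lung (HU).
#' @param noise_sd additive Gaussian noise (HU).
#' @param lesion_radius in-plane lesion half-width in voxels.
#' @param blur optional Gaussian in-plane blur sigma (voxels) emulating a
#'   softer reconstruction kernel (0 = off).
#' @param seed RNG seed; generation is fully deterministic under it.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(shape = c(96L, 96L, 16L), spacing = c(0.65, 0.65, 2.5),
                         class_counts = default_class_counts(scale = 0.01),
                         base_hu = -850, air_hu = -1000, noise_sd = 25,
                         lesion_radius = 14, blur = 0, seed = 1L) {
  class_counts <- class_counts[tissue_classes()]
  names(class_counts) <- tissue_classes()
  class_counts[is.na(class_counts)] <- 0L
  if (any(class_counts < 0))
    stop_lungtex("class_counts must be nonnegative", "lungtex_parameter_error")
  structure(list(shape = as.integer(shape), spacing = spacing,
                 class_counts = as.integer(class_counts),
                 base_hu = base_hu, air_hu = air_hu, noise_sd = noise_sd,
                 lesion_radius = lesion_radius, blur = blur,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @rdname phantom_spec
#' @param scale multiplier applied to the clinical per-class point counts
#'   (NP 23696, GG 137, RETIC 5409, NOD 117, LINSC 195, SUBPL 413, PS 3845,
#'   CL 3613); counts are rounded up so no class vanishes.
#' @export
default_class_counts <- function(scale = 1) {
  n <- c(NP = 23696L, GG = 137L, RETIC = 5409L, NOD = 117L, LINSC = 195L,
         SUBPL = 413L, PS = 3845L, CL = 3613L)
  if (scale == 1) n else ceiling(n * scale)
}

# in-plane squared elliptical radius (1 on the mask border)
ellipse_r2 <- function(d) {
  ci <- (d[1] + 1) / 2; cj <- (d[2] + 1) / 2
  ai <- 0.46 * d[1]; aj <- 0.46 * d[2]
  ii <- ((seq_len(d[1]) - ci) / ai)^2
  jj <- ((seq_len(d[2]) - cj) / aj)^2
  outer(ii, jj, `+`)
}

#' Generate a synthetic CT phantom with annotated texture lesions
#'
#' Builds one volume containing the requested number of lesions per class;
#' every annotated point lies inside its lesion and inside the lung mask.
#' Subpleural-line and paraseptal lesions are anchored within 5 voxels of
#' the mask border, centrilobular holes in the central lung. Generation is
#' byte-deterministic under the spec seed.
#'
#' @param spec a [phantom_spec].
#' @return List with `volume` (a [ct_volume] with lung mask) and `points`
#'   (annotation data.frame, 1-based indices).
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$shape
  with_seed(spec$seed, {
    r2 <- ellipse_r2(d)
    mask2d <- r2 <= 1
    vox <- array(spec$air_hu, dim = d)
    mask <- array(0L, dim = d)
    noise <- array(rnorm(prod(d), 0, spec$noise_sd), dim = d)
    for (k in seq_len(d[3])) {
      sl <- matrix(spec$air_hu, d[1], d[2])
      sl[mask2d] <- spec$base_hu + noise[, , k][mask2d]
      vox[, , k] <- sl
      mask[, , k] <- mask2d * 1L
    }
    # border distance proxy: voxels with r2 in (border_in, 1] are "subpleural"
    rr <- sqrt(r2)
    border_band <- mask2d & (rr >= 1 - 5 / (0.46 * min(d[1:2])))
    central <- mask2d & (rr <= 0.55)
    pts <- list()
    total_requested <- sum(spec$class_counts)
    capacity <- floor(sum(mask2d) * d[3] / 64)
    if (total_requested > capacity)
      stop_lungtex(sprintf(
        "requested %d points exceed placeable capacity %d for this volume",
        total_requested, capacity), "lungtex_capacity_error")
    for (cl in tissue_classes()) {
      n_cl <- spec$class_counts[[match(cl, tissue_classes())]]
      if (n_cl == 0) next
      for (t in seq_len(n_cl)) {
        res <- paint_lesion(vox, cl, mask2d, border_band, central, rr, spec)
        vox <- res$vox
        pts[[length(pts) + 1L]] <- data.frame(
          scan_id = "phantom", subject_id = "phantom",
          i = res$coord[1], j = res$coord[2], k = res$coord[3],
          label = cl, kernel = if (spec$blur > 0) "B35" else "B50",
          stringsAsFactors = FALSE)
      }
    }
    if (spec$blur > 0) {
      for (k in seq_len(d[3])) vox[, , k] <- gauss_blur2d(vox[, , k], spec$blur)
    }
    points <- do.call(rbind, pts)
    points$label <- as_tissue_factor(points$label)
    list(volume = ct_volume(vox, spacing = spec$spacing, lung_mask = mask),
         points = points)
  })
}

# Draw a lesion of class cl into the volume; returns updated voxels and the
# annotated coordinate (guaranteed inside the lesion and the mask).
paint_lesion <- function(vox, cl, mask2d, border_band, central, rr, spec) {
  d <- dim(vox)
  R <- spec$lesion_radius
  zone <- switch(cl,
    SUBPL = , PS = border_band,
    CL = central,
    mask2d & (rr <= 0.85))
  cand <- which(zone, arr.ind = TRUE)
  c2 <- cand[sample.int(nrow(cand), 1L), ]
  k0 <- sample(seq_len(d[3]), 1L)
  ci <- c2[1]; cj <- c2[2]
  zs <- max(1L, k0 - 3L):min(d[3], k0 + 3L)
  ii <- pmax(1L, ci - R):pmin(d[1], ci + R)
  jj <- pmax(1L, cj - R):pmin(d[2], cj + R)
  di <- outer(ii - ci, rep(1, length(jj)))
  dj <- outer(rep(1, length(ii)), jj - cj)
  rad2 <- di^2 + dj^2
  inles <- rad2 <= R^2
  add_patch <- function(vox, delta2d) {
    for (k in zs) {
      zfade <- 1 - 0.12 * abs(k - k0)
      sl <- vox[ii, jj, k]
      sl <- sl + delta2d * zfade
      vox[ii, jj, k] <- sl
    }
    vox
  }
  set_floor <- function(vox, region, value) {
    for (k in zs) {
      sl <- vox[ii, jj, k]
      sl[region] <- value
      vox[ii, jj, k] <- sl
    }
    vox
  }
  coord <- c(ci, cj, k0)
  if (cl == "NP") {
    # no lesion: normal parenchyma point
  } else if (cl == "GG") {
    delta <- ifelse(inles, 150, 150 * exp(-(sqrt(rad2) - R)^2 / 8))
    vox <- add_patch(vox, delta)
  } else if (cl == "RETIC") {
    theta <- runif(1, 0, pi)
    u <- di * cos(theta) + dj * sin(theta)
    v <- -di * sin(theta) + dj * cos(theta)
    lattice <- inles & ((round(u) %% 5 == 0) | (round(v) %% 5 == 0))
    vox <- add_patch(vox, ifelse(lattice, 300, 0))
  } else if (cl == "NOD") {
    n_sph <- 6L
    delta <- matrix(0, length(ii), length(jj))
    centers <- cbind(runif(n_sph, -R * 0.7, R * 0.7),
                     runif(n_sph, -R * 0.7, R * 0.7))
    centers[1, ] <- c(0, 0)               # one sphere at the annotated point
    for (s in seq_len(n_sph)) {
      ds2 <- (di - centers[s, 1])^2 + (dj - centers[s, 2])^2
      delta <- pmax(delta, ifelse(ds2 <= 2.5^2, 400, 0))
    }
    vox <- add_patch(vox, delta)
  } else if (cl == "LINSC") {
    theta <- runif(1, 0, pi)
    u <- di * cos(theta) + dj * sin(theta)
    v <- -di * sin(theta) + dj * cos(theta)
    streak <- abs(v) <= 1.5 & abs(u) <= R
    vox <- add_patch(vox, ifelse(streak, 300, 0))
  } else if (cl == "SUBPL") {
    band <- inles & border_band[ii, jj]
    vox <- add_patch(vox, ifelse(band, 300, 0))
  } else if (cl == "PS") {
    pocket <- rad2 <= (0.55 * R)^2
    vox <- set_floor(vox, pocket, -980)
  } else if (cl == "CL") {
    n_holes <- 8L
    holes <- matrix(FALSE, length(ii), length(jj))
    centers <- cbind(runif(n_holes, -R * 0.7, R * 0.7),
                     runif(n_holes, -R * 0.7, R * 0.7))
    centers[1, ] <- c(0, 0)
    for (s in seq_len(n_holes)) {
      ds2 <- (di - centers[s, 1])^2 + (dj - centers[s, 2])^2
      holes <- holes | (ds2 <= 3^2)
    }
    vox <- set_floor(vox, holes, -980)
  }
  list(vox = vox, coord = coord)
}

# separable Gaussian blur (reflect boundary) for the soft-kernel toggle
gauss_blur2d <- function(m, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, 0, sigma)
  k <- k / sum(k)
  pad <- function(v) v[reflect_index(seq(1 - r, length(v) + r), length(v))]
  m1 <- apply(m, 2, function(col) stats::filter(pad(col), k)[(r + 1):(r + nrow(m))])
  t(apply(t(m1), 2, function(row) stats::filter(pad(row), k)[(r + 1):(r + ncol(m))]))
}

#' Generate a balanced labeled patch set from phantoms
#'
#' Draws `n_per_class` patches per tissue class by generating a sequence of
#' phantom volumes (one lesion neighbourhood per annotated point) and
#' extracting patches with [extract_roi()]. The classes are separable by
#' construction, so simple baselines already beat chance by a wide margin
#' and the seven networks can be exercised end-to-end at desk scale.
#'
#' @param n_per_class patches per class.
#' @param mode ROI mode(s) to extract; `"all"` extracts every
#'   representation (axial 2D with context, 2.5D, 3D slab).
#' @param spec_template a [phantom_spec] providing texture parameters;
#'   per-volume class counts and seeds are managed internally.
#' @param points_per_volume lesions placed in each generated volume.
#' @param seed RNG seed.
#' @return List with `samples` (for a single mode: list of
#'   [roi_sample][extract_roi]s) or `sample_sets` (for `"all"`: one list
#'   per mode), `labels` (factor), `points`.
#' @export
generate_patchset <- function(n_per_class = 50L,
                              mode = c("axial2d", "ortho2p5d", "slab3d", "all"),
                              spec_template = phantom_spec(),
                              points_per_volume = 8L, seed = 1L) {
  mode <- match.arg(mode)
  cls <- tissue_classes()
  need <- stats::setNames(rep(as.integer(n_per_class), length(cls)), cls)
  all_modes <- mode == "all"
  sets <- list(axial2d = list(), ortho2p5d = list(), slab3d = list())
  labels <- character(0)
  points <- NULL
  vol_seed <- seed
  while (any(need > 0)) {
    take <- pmin(need, ceiling(points_per_volume / sum(need > 0)))
    take[need == 0] <- 0L
    if (sum(take) == 0) break
    vs <- phantom_spec(shape = spec_template$shape,
                       spacing = spec_template$spacing,
                       class_counts = take,
                       base_hu = spec_template$base_hu,
                       air_hu = spec_template$air_hu,
                       noise_sd = spec_template$noise_sd,
                       lesion_radius = spec_template$lesion_radius,
                       blur = spec_template$blur,
                       seed = vol_seed)
    vol_seed <- vol_seed + 1L
    ph <- generate_phantom(vs)
    for (t in seq_len(nrow(ph$points))) {
      pt <- ph$points[t, ]
      if (all_modes || mode == "axial2d")
        sets$axial2d[[length(sets$axial2d) + 1L]] <-
          extract_roi(ph$volume, pt, "axial2d", context = TRUE)
      if (all_modes || mode == "ortho2p5d")
        sets$ortho2p5d[[length(sets$ortho2p5d) + 1L]] <-
          extract_roi(ph$volume, pt, "ortho2p5d")
      if (all_modes || mode == "slab3d")
        sets$slab3d[[length(sets$slab3d) + 1L]] <-
          extract_roi(ph$volume, pt, "slab3d")
      labels <- c(labels, as.character(pt$label))
    }
    points <- rbind(points, ph$points)
    need <- need - take
  }
  labels <- as_tissue_factor(labels)
  if (all_modes)
    list(sample_sets = sets, labels = labels, points = points)
  else
    list(samples = sets[[mode]], labels = labels, points = points)
}
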