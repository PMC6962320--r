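one_each <- function() stats::setNames(rep(1L, 8), tissue_classes())

test_that("phantom generation is byte-deterministic under the seed", {
  sp <- phantom_spec(shape = c(64L, 64L, 8L), class_counts = one_each(),
                     seed = 99L)
  a <- generate_phantom(sp)
  b <- generate_phantom(sp)
  expect_identical(a$volume$voxels, b$volume$voxels)
  expect_identical(a$points, b$points)
  c_ <- generate_phantom(phantom_spec(shape = c(64L, 64L, 8L),
                                      class_counts = one_each(), seed = 100L))
  expect_false(identical(a$volume$voxels, c_$volume$voxels))
})

test_that("annotated points sit inside the mask and honour placement zones", {
  sp <- phantom_spec(shape = c(96L, 96L, 12L),
                     class_counts = stats::setNames(rep(3L, 8),
                                                    tissue_classes()),
                     seed = 17L)
  ph <- generate_phantom(sp)
  m <- ph$volume$lung_mask
  for (t in seq_len(nrow(ph$points))) {
    p <- ph$points[t, ]
    expect_equal(m[p$i, p$j, p$k], 1L)
  }
  # subpleural points within 5 voxels of the border (elliptical radius proxy)
  r2 <- lungtex:::ellipse_r2(dim(ph$volume$voxels))
  rr <- sqrt(r2)
  border <- 1 - 5 / (0.46 * 96)
  sub <- ph$points[ph$points$label == "SUBPL", ]
  for (t in seq_len(nrow(sub)))
    expect_gte(rr[sub$i[t], sub$j[t]], border)
  cen <- ph$points[ph$points$label == "CL", ]
  for (t in seq_len(nrow(cen)))
    expect_lte(rr[cen$i[t], cen$j[t]], 0.55)
})

test_that("ground-glass lesions add ~150 HU over normal parenchyma", {
  sp <- phantom_spec(shape = c(96L, 96L, 8L),
                     class_counts = c(NP = 4L, GG = 2L, RETIC = 0L, NOD = 0L,
                                      LINSC = 0L, SUBPL = 0L, PS = 0L,
                                      CL = 0L),
                     seed = 23L)
  ph <- generate_phantom(sp)
  gg <- ph$points[ph$points$label == "GG", ][1, ]
  R <- sp$lesion_radius
  ii <- (gg$i - R + 2):(gg$i + R - 2)
  jj <- (gg$j - R + 2):(gg$j + R - 2)
  sel <- outer(ii - gg$i, jj - gg$j,
               function(a, b) a^2 + b^2) <= (R - 2)^2
  lesion_mean <- mean(ph$volume$voxels[ii, jj, gg$k][sel])
  np <- ph$points[ph$points$label == "NP", ][1, ]
  np_mean <- mean(ph$volume$voxels[np$i + (-3:3), np$j + (-3:3), np$k])
  expect_lt(abs((lesion_mean - np_mean) - 150), 30)
})

test_that("class mean attenuations have the constructed signs", {
  ps <- generate_patchset(12L, mode = "axial2d", seed = 31L)
  mu <- tapply(vapply(ps$samples, function(s) mean(s$data), numeric(1)),
               ps$labels, mean)
  expect_lt(mu[["PS"]], mu[["NP"]])            # emphysema: lower density
  expect_gt(mu[["GG"]], mu[["NP"]] + 20)       # interstitial: higher
  expect_gt(mu[["RETIC"]], mu[["NP"]])
})

test_that("requested class imbalance is reproduced exactly", {
  counts <- c(NP = 6L, GG = 1L, RETIC = 4L, NOD = 1L, LINSC = 2L,
              SUBPL = 2L, PS = 3L, CL = 3L)
  ph <- generate_phantom(phantom_spec(shape = c(96L, 96L, 10L),
                                      class_counts = counts, seed = 37L))
  expect_equal(as.integer(table(ph$points$label)), unname(counts))
  big <- default_class_counts(scale = 0.01)
  expect_equal(names(big), tissue_classes())
  expect_true(all(big >= 1))
  expect_error(generate_phantom(phantom_spec(shape = c(16L, 16L, 2L),
                                             class_counts = counts * 50L)),
               class = "lungtex_capacity_error")
})

test_that("a nearest-centroid histogram baseline clears 40% on 100/class", {
  ps <- generate_patchset(100L, mode = "axial2d", seed = 7L)
  y <- as.integer(ps$labels)
  br <- seq(-1100, 700, by = 50)
  H <- t(vapply(ps$samples, function(s)
    hist(pmin(pmax(s$data, -1099), 699), breaks = br,
         plot = FALSE)$counts / length(s$data),
    numeric(length(br) - 1)))
  tr <- unlist(lapply(split(seq_along(y), y), function(r) r[1:60]))
  te <- setdiff(seq_along(y), tr)
  cen <- t(vapply(1:8, function(c)
    colMeans(H[intersect(tr, which(y == c)), , drop = FALSE]),
    numeric(ncol(H))))
  pred <- apply(H[te, ], 1, function(h) which.min(colSums((t(cen) - h)^2)))
  expect_gt(mean(pred == y[te]), 0.40)
})

test_that("patch labels round-trip through annotation export", {
  ps <- generate_patchset(3L, mode = "axial2d", seed = 41L)
  path <- tempfile(fileext = ".csv")
  write_annotations(ps$points, path)
  back <- read_annotations(path)
  expect_equal(as.character(back$label), as.character(ps$points$label))
  expect_equal(back$i, ps$points$i)
})

test_that("the soft-kernel blur toggle tags annotations and smooths texture", {
  sp_sharp <- phantom_spec(shape = c(64L, 64L, 6L), class_counts = one_each(),
                           seed = 43L)
  sp_soft <- phantom_spec(shape = c(64L, 64L, 6L), class_counts = one_each(),
                          blur = 1.5, seed = 43L)
  a <- generate_phantom(sp_sharp)
  b <- generate_phantom(sp_soft)
  expect_equal(unique(a$points$kernel), "B50")
  expect_equal(unique(b$points$kernel), "B35")
  inl <- a$volume$lung_mask[, , 3] == 1
  expect_lt(sd(b$volume$voxels[, , 3][inl]), sd(a$volume$voxels[, , 3][inl]))
})
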