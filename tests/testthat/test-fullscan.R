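# classifier stubs obeying the probability-output contract
stub_constant <- function(class_idx, certainty = 1) {
  function(samples) {
    P <- matrix((1 - certainty) / 7, length(samples), 8)
    P[, class_idx] <- certainty
    P
  }
}

# label depends deterministically on the patch centre intensity
stub_by_mean <- function() {
  function(samples) {
    P <- matrix(0, length(samples), 8)
    idx <- vapply(samples, function(s) 1L + (mean(s$data) > -900), integer(1))
    P[cbind(seq_along(samples), idx)] <- 1
    P
  }
}

test_that("grid classification matches brute-force nearest-node assignment", {
  vol <- const_volume(-850, dims = c(10L, 10L, 10L), mask = TRUE)
  map <- classify_scan(vol, stub_constant(2), grid_spacing = 5L)
  expect_equal(nrow(map$nodes), 8L)          # nodes at {1,6}^3
  expect_true(all(map$labels > 0))           # every voxel assigned
  # brute force: nearest node, ties to lowest node index
  nodes <- as.matrix(map$nodes[, c("i", "j", "k")])
  for (v in list(c(1, 1, 1), c(3, 3, 3), c(4, 8, 2), c(10, 10, 10),
                 c(3, 4, 9))) {
    d2 <- colSums((t(nodes) - v)^2)
    expect_equal(lungtex:::cpp_nearest_node(
      as.integer(vol$lung_mask), dim(vol$voxels), nodes * 1.0
    )[v[1], v[2], v[3]], which(d2 == min(d2))[1])
  }
})

test_that("spacing 1 equals exhaustive classification at every voxel", {
  set.seed(61)
  vox <- array(-1000 + 200 * (runif(8^3) > 0.5), dim = c(8, 8, 8))
  vol <- ct_volume(vox, lung_mask = array(1L, dim = c(8, 8, 8)))
  clf <- stub_by_mean()
  map <- classify_scan(vol, clf, grid_spacing = 1L)
  samples <- lapply(seq_len(8^3), function(t) {
    ijk <- arrayInd(t, c(8L, 8L, 8L))
    extract_roi(vol, as.integer(ijk), "axial2d")
  })
  direct <- apply(clf(samples), 1, which.max)
  expect_equal(as.integer(map$labels), direct)
  # grid nodes agree between spacing s and spacing 1
  map5 <- classify_scan(vol, clf, grid_spacing = 5L)
  for (r in seq_len(nrow(map5$nodes))) {
    n <- map5$nodes[r, ]
    expect_equal(map5$labels[n$i, n$j, n$k], map$labels[n$i, n$j, n$k])
  }
})

test_that("constant classifiers give uniform maps; labels never invent classes", {
  vol <- const_volume(-850, dims = c(10L, 10L, 10L), mask = TRUE)
  map <- classify_scan(vol, stub_constant(4), grid_spacing = 3L)
  inl <- map$labels > 0
  expect_true(all(map$labels[inl] == 4L))
  expect_true(all(map$certainty[inl] == 1))
  # interpolated labels are a subset of node labels
  set.seed(62)
  vol2 <- ct_volume(array(-1000 + 300 * runif(1000), dim = c(10, 10, 10)),
                    lung_mask = array(1L, dim = c(10, 10, 10)))
  map2 <- classify_scan(vol2, stub_by_mean(), grid_spacing = 4L)
  expect_true(all(unique(as.integer(map2$labels[map2$labels > 0])) %in%
                  match(unique(map2$nodes$label), tissue_classes())))
})

test_that("degenerate full-scan inputs raise typed errors", {
  vol <- const_volume(-850, dims = c(10L, 10L, 10L), mask = TRUE)
  vol$lung_mask[] <- 0L
  expect_error(classify_scan(vol, stub_constant(1)),
               class = "lungtex_empty_lung_error")
  expect_error(classify_scan(const_volume(-850), stub_constant(1)),
               class = "lungtex_input_error")
  vol2 <- const_volume(-850, dims = c(10L, 10L, 10L), mask = TRUE)
  expect_error(classify_scan(vol2, stub_constant(1), grid_spacing = 0L),
               class = "lungtex_parameter_error")
})

test_that("the ILA score is the thresholded interstitial voxel percentage", {
  # half the lung GG at certainty 1, half NP: exactly 50 below threshold 1
  vol <- const_volume(-850, dims = c(10L, 10L, 10L), mask = TRUE)
  clf <- function(samples) {
    P <- matrix(0, length(samples), 8)
    gg <- vapply(samples, function(s) s$coord[3] <= 5L, logical(1))
    P[cbind(seq_along(samples), ifelse(gg, 2L, 1L))] <- 1
    P
  }
  map <- classify_scan(vol, clf, grid_spacing = 1L)
  for (tau in c(0, 0.5, 0.95, 0.999))
    expect_equal(ila_score(map, tau)$score, 50)
  expect_equal(ila_score(map, 1)$score, 0)   # strict inequality at the top
  # all-normal map scores zero everywhere
  map_np <- classify_scan(vol, stub_constant(1), grid_spacing = 2L)
  expect_equal(ila_score(map_np, 0)$score, 0)
  expect_error(ila_score(map, 1.2), class = "lungtex_parameter_error")
})

test_that("the ILA score is non-increasing in the certainty threshold", {
  set.seed(63)
  vol <- const_volume(-850, dims = c(12L, 12L, 6L), mask = TRUE)
  clf <- function(samples) {
    P <- matrix(rexp(length(samples) * 8), length(samples), 8)
    P / rowSums(P)
  }
  map <- classify_scan(vol, clf, grid_spacing = 2L)
  curve <- ila_curve(map, seq(0, 1, by = 0.02))
  expect_true(all(diff(curve$score) <= 1e-12))
  # emphysema labels are excluded from the score by default
  map_ps <- classify_scan(vol, stub_constant(7), grid_spacing = 2L)
  expect_equal(ila_score(map_ps, 0)$score, 0)
})

test_that("certainty overlays partition the lung and survive 8-bit export", {
  vol <- const_volume(-850, dims = c(10L, 10L, 4L), mask = TRUE)
  clf <- function(samples) {
    P <- matrix(0.02, length(samples), 8)
    gg <- vapply(samples, function(s) s$coord[1] <= 5L, logical(1))
    P[cbind(seq_along(samples), ifelse(gg, 2L, 1L))] <- 0.86
    P
  }
  map <- classify_scan(vol, clf, grid_spacing = 1L)
  rgb <- certainty_overlay(map, 2L)
  lit <- rgb[, , 1] + rgb[, , 2] + rgb[, , 3] > 0
  expect_true(all(lit))                      # union covers the lung slice
  expect_true(all(rgb[, , 1][rgb[, , 3] > 0] == 0))  # groups are disjoint
  path <- tempfile(fileext = ".png")
  write_certainty_png(map, 2L, path)
  back <- png::readPNG(path)
  expect_equal(back, round(rgb * 255) / 255, tolerance = 1e-9)
  # single-group overlay for an all-NP map
  map_np <- classify_scan(vol, stub_constant(1), grid_spacing = 2L)
  rgb_np <- certainty_overlay(map_np, 2L)
  expect_true(all(rgb_np[, , 1] == 0) && all(rgb_np[, , 2] == 0))
})

test_that("label maps export as integer volumes with a JSON legend", {
  vol <- const_volume(-850, dims = c(10L, 10L, 4L), mask = TRUE)
  map <- classify_scan(vol, stub_constant(3), grid_spacing = 2L)
  path <- tempfile(fileext = ".nii.gz")
  write_label_map(map, vol, path)
  back <- read_volume(path)
  expect_equal(array(as.integer(back$voxels), dim = dim(back$voxels)),
               map$labels)
  legend <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(legend$classes$RETIC, 3L)
})
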