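test_that("identity transform returns the input unchanged", {
  set.seed(31)
  s <- make_sample(rand_patch(48))
  expect_identical(apply_geometric(s, identity_transform()), s)
})

test_that("flips are involutions and label/geometry are preserved", {
  set.seed(32)
  s <- make_sample(rand_patch(48), label = "GG")
  t_h <- geom_transform(flip_h = TRUE)
  twice <- apply_geometric(apply_geometric(s, t_h), t_h)
  expect_equal(twice$data, s$data, tolerance = 1e-9)
  once <- apply_geometric(s, t_h)
  expect_equal(once$label, "GG")
  expect_equal(dim(once$data), dim(s$data))
})

test_that("90-degree rotation moves a bright pixel to the rotated index", {
  m <- matrix(0, 48, 48)
  m[10 + 1, 20 + 1] <- 7          # 0-based (10, 20)
  s <- make_sample(m)
  out <- apply_geometric(s, geom_transform(rotation = 90))$data
  # oracle by index arithmetic about the patch centre c = 23.5:
  # (i,j) -> (c - (j - c), c + (i - c)) = (27, 10) for (10, 20)
  expect_equal(which(out == max(out), arr.ind = TRUE)[1, ] - 1,
               c(row = 27, col = 10))
  expect_equal(max(out), 7, tolerance = 1e-9)
})

test_that("2.5D samples are transformed plane-by-plane; 3D slabs refuse", {
  set.seed(33)
  a <- array(rnorm(48 * 48 * 3), dim = c(48, 48, 3))
  s <- make_sample(a, mode = "ortho2p5d")
  t1 <- geom_transform(rotation = 90)
  out <- apply_geometric(s, t1)
  for (c in 1:3)
    expect_equal(out$data[, , c],
                 apply_geometric(make_sample(a[, , c]), t1)$data)
  slab <- make_sample(array(0, dim = c(48, 48, 7)), mode = "slab3d")
  expect_error(apply_geometric(slab, t1), class = "lungtex_input_error")
})

test_that("sponge rescaling matches the mass-conservation closed form", {
  p <- sponge_params(lung_volume = 5000, delta_v = 100)
  expect_equal(sponge_augment(-900, p), -1000 + 100 * 5000 / 5100,
               tolerance = 1e-9)                      # -901.9608 HU
  expect_equal(sponge_augment(-900, p), -901.9608, tolerance = 1e-4)
  # dV = 0 is the identity; air is a fixed point for any dV
  expect_identical(sponge_augment(-900, sponge_params(5000, 0)), -900)
  expect_equal(sponge_augment(-1000, sponge_params(5000, 87)), -1000)
})

test_that("sponge augmentation conserves mass and composes", {
  set.seed(34)
  for (r in 1:50) {
    V <- runif(1, 3000, 7000)
    dv <- runif(1, -100, 100)
    patch <- rand_patch(8, mean = -850, sd = 120)
    out <- sponge_augment(patch, sponge_params(V, dv))
    m0 <- mean(patch + 1000)
    m1 <- mean(out + 1000)
    expect_lt(abs(m1 * (V + dv) - m0 * V) / (m0 * V), 1e-9)
    # inspiration (dv > 0) moves every density toward air (zero), away else
    if (dv > 0) expect_true(all(abs(out + 1000) <= abs(patch + 1000) + 1e-12))
    else expect_true(all(abs(out + 1000) >= abs(patch + 1000) - 1e-12))
    # two-step composition equals the single step dv1 + dv2
    dv1 <- dv / 3; dv2 <- dv - dv1
    two <- sponge_augment(sponge_augment(patch, sponge_params(V, dv1)),
                          sponge_params(V + dv1, dv2))
    one <- sponge_augment(patch, sponge_params(V, dv))
    expect_equal(two, one, tolerance = 1e-9)
  }
  expect_error(sponge_params(100, -200), class = "lungtex_parameter_error")
  s_norm <- make_sample(rand_patch(8), normalized = TRUE)
  expect_error(sponge_augment(s_norm, sponge_params(5000, 10)),
               class = "lungtex_parameter_error")
})

test_that("lung volume derives from the mask and drives the sponge model", {
  vol <- const_volume(-850, dims = c(10L, 10L, 10L), spacing = c(1, 1, 2),
                      mask = TRUE)
  expect_equal(lung_volume_ml(vol), 10 * 10 * 10 * 2 / 1000)
  expect_error(lung_volume_ml(const_volume(-850)),
               class = "lungtex_parameter_error")
})

test_that("class balancing fills every class to the target", {
  counts <- c(NP = 650L, GG = 103L, RETIC = 700L, NOD = 30L, LINSC = 50L,
              SUBPL = 103L, PS = 610L, CL = 600L)
  pts <- count_points(counts)
  roster <- balance_classes(pts, target = 600L, seed = 7)
  tab <- table(roster$label)
  expect_true(all(tab == 600L))
  gg <- roster[roster$label == "GG", ]
  expect_equal(sum(!gg$augmented), 103L)   # all originals kept
  expect_equal(sum(gg$augmented), 497L)
  cl <- roster[roster$label == "CL", ]     # exactly at target: untouched
  expect_true(all(!cl$augmented))
  expect_true(all(cl$rotation == 0))
  np <- roster[roster$label == "NP", ]     # above target: subsampled only
  expect_true(all(!np$augmented))
})

test_that("balancing is deterministic under seed and rejects empty classes", {
  counts <- clinical_counts()
  pts <- count_points(counts)
  r1 <- balance_classes(pts, target = 600L, seed = 11)
  r2 <- balance_classes(pts, target = 600L, seed = 11)
  expect_identical(r1, r2)
  expect_equal(nrow(r1), 4800L)
  bad <- pts[pts$label != "GG", ]
  expect_error(balance_classes(bad, target = 600L, seed = 1),
               class = "lungtex_balancing_error")
})
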