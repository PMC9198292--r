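test_that("affine application, composition and inversion behave algebraically", {
  I2 <- affine_params(ndim = 2)
  expect_equal(affine_apply(I2, c(3.5, -1)), c(3.5, -1))
  tr <- affine_params(translation = c(2, -1), ndim = 2)
  expect_equal(affine_apply(tr, c(0, 0)), c(2, -1))
  rot <- affine_rotation(90)
  expect_equal(affine_apply(rot, c(1, 0)), c(0, 1), tolerance = 1e-12)
  set.seed(1)
  for (i in 1:10) {
    A <- affine_params(linear = diag(2) + matrix(runif(4, -0.2, 0.2), 2),
                       translation = runif(2, -5, 5))
    B <- affine_params(linear = diag(2) + matrix(runif(4, -0.2, 0.2), 2),
                       translation = runif(2, -5, 5))
    p <- runif(2, -10, 10)
    expect_equal(affine_apply(affine_compose(A, B), p),
                 affine_apply(A, affine_apply(B, p)), tolerance = 1e-9)
    expect_equal(affine_apply(affine_invert(A), affine_apply(A, p)), p,
                 tolerance = 1e-9)
  }
  v <- affine_vector(tr)
  expect_equal(v, c(1, 0, 0, 1, 2, -1))
  expect_equal(affine_from_vector(v, 2)$matrix, tr$matrix)
  expect_error(affine_params(linear = matrix(0, 2, 2)), "singular")
  expect_error(affine_params(matrix = rbind(diag(2), c(1, 1))), "3x3 or 4x4")
})

test_that("B-spline basis matches the closed forms, sums to one, stays nonnegative", {
  expect_equal(as.vector(bspline_basis(0)), c(1, 4, 1, 0) / 6)
  expect_equal(as.vector(bspline_basis(0.5)),
               c(0.125, 2.875, 2.875, 0.125) / 6)
  u <- seq(0, 1, length.out = 1001)[-1001]
  B <- bspline_basis(u)
  expect_true(all(abs(rowSums(B) - 1) < 1e-12))
  expect_true(all(B >= 0))
  expect_error(bspline_basis(1), "\\[0, 1\\)")
  expect_error(bspline_basis(-0.1), "\\[0, 1\\)")
})

test_that("FFD grids enforce divisibility and local coordinates follow the lattice", {
  g <- make_ffd_grid(c(64, 64), 16)
  expect_equal(g$n, c(4L, 4L))
  expect_equal(dim(g$phi), c(8L, 8L, 2L))
  expect_equal(make_ffd_grid(c(64, 64), 64)$n, c(1L, 1L))
  expect_error(make_ffd_grid(c(64, 64), 10), "does not divide")
  lc <- ffd_local_coords(c(0, 0), g)
  expect_equal(lc$index[1, ], c(-1L, -1L))
  expect_equal(lc$frac[1, ], c(0, 0))
  lc <- ffd_local_coords(c(24, 16), g)
  expect_equal(lc$index[1, ], c(0L, 0L))
  expect_equal(lc$frac[1, ], c(0.5, 0))
  expect_error(ffd_local_coords(c(-1, 0), g), "outside")
})

test_that("FFD evaluation equals the brute-force tensor-product oracle", {
  set.seed(3)
  g <- make_ffd_grid(c(64, 64), 16)
  g$phi <- array(runif(length(g$phi), -3, 3), dim = dim(g$phi))
  for (i in 1:20) {
    p <- runif(2, 0, 63.9)
    expect_equal(ffd_apply(g, p), oracle_ffd_apply(g, p), tolerance = 1e-13)
  }
  g3 <- make_ffd_grid(c(32, 32, 32), 16)
  g3$phi <- array(runif(length(g3$phi), -2, 2), dim = dim(g3$phi))
  for (i in 1:10) {
    p <- runif(3, 0, 31.9)
    expect_equal(ffd_apply(g3, p), oracle_ffd_apply(g3, p), tolerance = 1e-13)
  }
})

test_that("zero and uniform control displacements give identity and pure shift", {
  g <- make_ffd_grid(c(64, 64), 16)
  pts <- sample_grid(c(64, 64), 5)$points
  expect_equal(ffd_apply(g, pts), pts + 0)
  g$phi[, , 1] <- 2.5
  g$phi[, , 2] <- -1.25
  out <- ffd_apply(g, pts)
  expect_equal(out[, 1], pts[, 1] + 2.5, tolerance = 1e-12)
  expect_equal(out[, 2], pts[, 2] - 1.25, tolerance = 1e-12)
})

test_that("warping is exact for identity and integer shifts", {
  img <- random_image(c(16, 16), seed = 21)
  expect_equal(warp_image(img, NULL, "nearest")$data, unclass(img$data))
  expect_equal(warp_image(img, NULL, "linear")$data, unclass(img$data))
  shifted <- warp_image(img, affine_params(translation = c(2, 0), ndim = 2),
                        "nearest")
  expect_equal(shifted$data[1:14, ], unclass(img$data)[3:16, ])
  expect_true(all(shifted$data[15:16, ] == 0))
})

test_that("half-voxel linear warp of a two-value edge image averages the edge", {
  m <- matrix(0, 16, 16); m[9:16, ] <- 200    # step edge along x at x = 8
  img <- npv_image(m)
  w <- warp_image(img, affine_params(translation = c(0.5, 0), ndim = 2),
                  "linear")
  expect_true(all(w$data[8, ] == 100))        # blended edge column
  expect_true(all(w$data[10:15, ] == 200))
  expect_true(all(w$data[1:7, ] == 0))
})

test_that("affine warp round-trip returns the original within interpolation blur", {
  # smooth image: linear-interpolation error stays at the gray-level scale
  smooth <- outer(0:63, 0:63, function(x, y)
    120 + 60 * cos(2 * pi * x / 40) * cos(2 * pi * y / 32))
  img <- npv_image(smooth)
  A <- affine_compose(affine_rotation(7, center = c(31.5, 31.5)),
                      affine_params(translation = c(1.3, -0.8), ndim = 2))
  back <- warp_image(warp_image(img, A, "linear"), affine_invert(A), "linear")
  interior <- unclass(img$data)[9:56, 9:56]
  expect_lt(mean(abs(unclass(back$data)[9:56, 9:56] - interior)), 2)
})

test_that("transforms survive a JSON round-trip", {
  A <- affine_rotation(30, center = c(10, 12))
  g <- make_ffd_grid(c(32, 32), 16)
  g$phi <- array(seq_len(length(g$phi)) / 7, dim = dim(g$phi))
  for (tr in list(A, g, compose_transform(A, g))) {
    back <- transform_from_json(transform_to_json(tr))
    pts <- matrix(c(5, 7, 20.5, 11), 2, byrow = TRUE)
    expect_equal(transform_points(back, pts), transform_points(tr, pts),
                 tolerance = 1e-12)
  }
})
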