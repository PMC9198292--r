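test_that("image containers validate shape, range and spacing", {
  expect_error(npv_image(1:10), "2 or 3 axes")
  expect_error(npv_image(matrix(-1, 4, 4)), "lie in")
  expect_error(npv_image(matrix(300, 4, 4)), "lie in")
  expect_error(npv_image(matrix(1, 4, 4), spacing = 0), "positive")
  img <- npv_image(matrix(0:15, 4, 4), spacing = c(1, 2.5))
  expect_equal(dim(img), c(4L, 4L))
  expect_equal(img$spacing, c(1, 2.5))
})

test_that("PNG, TIFF and NIfTI round-trips are lossless for integer gray data", {
  ph <- make_shape_phantom(c(64, 64), 3, seed = 1)
  for (ext in c(".png", ".tif", ".nii.gz")) {
    f <- tempfile(fileext = ext)
    write_image(ph, f)
    back <- read_image(f)
    expect_equal(back$data, unclass(ph$data), ignore_attr = TRUE, info = ext)
  }
})

test_that("3-D NIfTI round-trip preserves anisotropic spacing", {
  img <- npv_image(array(seq_len(4 * 4 * 4) %% 256, c(4, 4, 4)),
                   spacing = c(1, 1.5, 3))
  f <- tempfile(fileext = ".nii.gz")
  write_image(img, f)
  back <- read_image(f)
  expect_equal(back$spacing, c(1, 1.5, 3))
  expect_equal(back$data, unclass(img$data), ignore_attr = TRUE)
})

test_that("RGB input and unknown extensions are rejected with guidance", {
  f <- tempfile(fileext = ".png")
  png::writePNG(array(runif(12), c(2, 2, 3)), f)
  expect_error(read_image(f), "grayscale")
  expect_error(read_image("x.xyz"), "unknown image format")
  expect_error(write_image(npv_image(matrix(1, 4, 4)), "x.xyz"),
               "unknown image format")
})

test_that("gray normalization forces endpoints, rounds linearly and is idempotent", {
  expect_equal(sort(unique(as.vector(
    normalize_gray(npv_image(matrix(c(10, 20), 8, 8)))$data))), c(0, 255))
  img <- npv_image(matrix(c(0, 128, 255, 0), 2, 2))
  expect_equal(sort(unique(as.vector(normalize_gray(img, 64)$data))),
               c(0, 32, 63))   # round(v * 63 / 255)
  already <- npv_image(matrix(c(0, 100, 255, 30), 2, 2))
  expect_equal(normalize_gray(already)$data, already$data)
  once <- normalize_gray(npv_image(matrix(c(3, 17, 200, 90), 2, 2)))
  expect_equal(normalize_gray(once)$data, once$data)
  expect_error(normalize_gray(npv_image(matrix(5, 4, 4))), "constant")
})

test_that("background stripping zeroes below threshold and keeps the largest component", {
  ph <- make_shape_phantom(c(64, 64), 2, seed = 3)
  expect_equal(strip_background(ph, 0)$data, ph$data)
  speck <- ph
  speck$data[2, 2] <- 200                       # bright corner speck
  cleaned <- strip_background(speck, 10, keep_largest = TRUE)
  expect_equal(cleaned$data[2, 2], 0)
  body <- which(ph$data > 0)
  expect_equal(cleaned$data[body], ph$data[body])
  expect_warning(out <- strip_background(ph, 255), "empty foreground")
  expect_true(all(out$data == 0))
})

test_that("intensity centroid matches its defining sums and translates with content", {
  m <- matrix(0, 8, 8); m[4, 6] <- 10           # single voxel at (3, 5)
  expect_equal(intensity_centroid(npv_image(m)), c(3, 5))
  m2 <- matrix(0, 16, 16); m2[1, 3] <- 7; m2[11, 3] <- 7
  expect_equal(intensity_centroid(npv_image(m2)), c(5, 2))
  disk <- matrix(0, 33, 33)
  pts <- as.matrix(expand.grid(0:32, 0:32))
  disk[(pts[, 1] - 16)^2 + (pts[, 2] - 16)^2 <= 100] <- 50
  expect_equal(intensity_centroid(npv_image(disk)), c(16, 16), tolerance = 1e-9)
  shifted <- matrix(0, 16, 16); shifted[6, 8] <- 10
  expect_equal(intensity_centroid(npv_image(shifted)), c(5, 7))
  expect_error(intensity_centroid(npv_image(matrix(0, 8, 8))), "all-zero")
})

test_that("sample grids enumerate the full regular sub-lattice", {
  expect_equal(nrow(sample_grid(c(64, 64), 1)$points), 4096)
  expect_equal(nrow(sample_grid(c(64, 64), 4)$points), 256)
  expect_equal(nrow(sample_grid(c(64, 64, 64), c(8, 8, 8))$points), 512)
  # product over axes of ceiling(size / stride), including non-dividing strides
  for (st in list(c(3, 5), 7, c(9, 2))) {
    s <- sample_grid(c(20, 30), st)
    st2 <- rep_len(st, 2)
    expect_equal(nrow(s$points), prod(ceiling(c(20, 30) / st2)))
    expect_true(all(s$points >= 0))
    expect_true(all(sweep(s$points, 2, c(20, 30) - 1, `<=`)))
  }
  big <- sample_grid(c(16, 16), 99)   # stride beyond extent: origin retained
  expect_equal(big$points, matrix(c(0L, 0L), 1))
  expect_error(sample_grid(c(16, 16), 0), ">= 1")
})
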