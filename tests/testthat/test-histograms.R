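test_that("identity transform on a self-pair gives a diagonal histogram", {
  img <- random_image(c(16, 16), seed = 1)
  s <- sample_grid(img, 1)
  h <- pv_accumulate(joint_histogram(64), img, img, NULL, s)
  expect_equal(sum(h$counts), nrow(s$points))
  expect_equal(h$n_skipped, 0L)
  expect_equal(sum(diag(h$counts)), sum(h$counts))   # all mass on the diagonal
})

test_that("constant-image pair under a half-voxel shift keeps all mass in one cell", {
  img <- npv_image(matrix(100, 16, 16))
  s <- sample_grid(img, 1)
  tr <- affine_params(translation = c(0.5, 0), ndim = 2)
  h <- pv_accumulate(joint_histogram(64), img, img, tr, s)
  expect_equal(sum(h$counts > 0), 1L)
  expect_equal(max(h$counts), h$n_samples)
})

test_that("mass equals the number of in-bounds samples for any kernel and shift", {
  ref <- random_image(c(16, 16), seed = 2)
  flt <- random_image(c(16, 16), seed = 3)
  s <- sample_grid(ref, 1)
  set.seed(7)
  for (kind in c("linear", "cubic_hermite", "cubic_bspline")) {
    spec <- kernel_spec(kind)
    for (rep in 1:5) {
      tr <- affine_params(translation = runif(2, -3, 3), ndim = 2)
      h <- npv_accumulate(joint_histogram(64), ref, flt, tr, s, spec)
      expect_equal(sum(h$counts), h$n_samples, tolerance = 1e-9)
      expect_equal(h$n_samples + h$n_skipped, nrow(s$points))
      expect_true(all(h$counts >= 0))
    }
  }
})

test_that("accumulators equal the per-sample brute-force oracle", {
  ref <- random_image(c(16, 16), seed = 4)
  flt <- random_image(c(16, 16), seed = 5)
  s <- sample_grid(ref, 1)
  tr <- affine_params(translation = c(0.3, 0.7), ndim = 2)
  for (kind in c("linear", "cubic_hermite", "cubic_bspline")) {
    spec <- kernel_spec(kind)
    got <- npv_accumulate(joint_histogram(64), ref, flt, tr, s, spec)
    want <- oracle_accumulate(ref, flt, tr, s, spec)
    expect_equal(got$counts, want$counts, tolerance = 1e-14, info = kind)
    expect_equal(got$n_samples, want$n_used, info = kind)
  }
  # 3-D
  ref3 <- random_image(c(8, 8, 8), seed = 6)
  flt3 <- random_image(c(8, 8, 8), seed = 7)
  s3 <- sample_grid(ref3, 1)
  tr3 <- affine_params(translation = c(0.4, -0.6, 1.2), ndim = 3)
  got <- npv_accumulate(joint_histogram(64), ref3, flt3, tr3, s3, kernel_spec())
  want <- oracle_accumulate(ref3, flt3, tr3, s3, kernel_spec())
  expect_equal(got$counts, want$counts, tolerance = 1e-14)
})

test_that("npv with the linear kernel reproduces pv exactly", {
  ref <- random_image(c(16, 16), seed = 8)
  flt <- random_image(c(16, 16), seed = 9)
  s <- sample_grid(ref, 1)
  tr <- affine_params(translation = c(1.3, -0.7), ndim = 2)
  a <- pv_accumulate(joint_histogram(64), ref, flt, tr, s)
  b <- npv_accumulate(joint_histogram(64), ref, flt, tr, s, kernel_spec("linear"))
  expect_identical(a$counts, b$counts)
})

test_that("on-lattice transforms give identical diagonal mass for pv and cubic", {
  img <- random_image(c(16, 16), seed = 10)
  s <- sample_grid(img, 1)
  tr <- affine_params(translation = c(2, -1), ndim = 2)
  flt <- warp_image(img, tr, "nearest")      # floating = shifted copy
  a <- pv_accumulate(joint_histogram(64), img, flt, tr, s)
  b <- npv_accumulate(joint_histogram(64), img, flt, tr, s, kernel_spec())
  # eta = 0 at every sample: the single unit-weight neighbor makes the
  # cubic accumulation collapse to PV, and matched pairs sit on the diagonal
  expect_equal(a$counts, b$counts, tolerance = 1e-12)
  expect_equal(sum(diag(b$counts)), sum(b$counts))
  expect_gt(b$n_samples, 0)
})

test_that("out-of-bounds samples are skipped and counted", {
  img <- random_image(c(16, 16), seed = 11)
  s <- sample_grid(img, 1)
  tr <- affine_params(translation = c(12, 0), ndim = 2)
  h <- pv_accumulate(joint_histogram(64), img, img, tr, s)
  expect_gt(h$n_skipped, 0L)
  expect_equal(sum(h$counts), h$n_samples)
})

test_that("histogram validation and normalization behave", {
  expect_error(joint_histogram(bins = 48), "divide")
  expect_error(joint_histogram(bins = 64, levels = 100), "divide")
  img <- random_image(c(16, 16), seed = 12)
  expect_error(pv_accumulate(joint_histogram(64), img, img, NULL,
                             list(points = NULL)), "empty sample set")
  expect_error(to_probability(joint_histogram(64)), "zero mass")
  h <- hist_from_counts(matrix(c(2, 2, 2, 1), 2))
  p <- to_probability(h)
  expect_equal(sum(p), 1)
  h1 <- hist_from_counts(matrix(c(0, 0, 7, 0), 2))
  expect_equal(to_probability(h1)[1, 2], 1)
  expect_equal(unname(to_probability(hist_from_counts(matrix(1, 2, 2)))),
               matrix(0.25, 2, 2))
})

test_that("TSV export writes bin centers and the count matrix", {
  h <- hist_from_counts(matrix(1:4, 2), levels = 256)
  f <- tempfile(fileext = ".tsv")
  export_histogram_tsv(h, f)
  tab <- read.delim(f)
  expect_equal(nrow(tab), 2)
  expect_equal(tab[[1]], c(64, 192))   # centers of 2 bins over 256 levels
  expect_equal(unname(as.matrix(tab[, -1])), matrix(as.numeric(1:4), 2),
               ignore_attr = TRUE)
})
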