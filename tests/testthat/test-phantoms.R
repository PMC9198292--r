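test_that("shape phantoms have the promised class structure and determinism", {
  ph <- make_shape_phantom(c(64, 64), 3, seed = 1)
  expect_equal(length(unique(as.vector(ph$data))), 4)   # 3 classes + background
  expect_equal(min(ph$data), 0)
  expect_lte(max(ph$data), 255)
  expect_identical(ph$data, make_shape_phantom(c(64, 64), 3, seed = 1)$data)
  expect_false(identical(ph$data,
                         make_shape_phantom(c(64, 64), 3, seed = 2)$data))
  expect_equal(length(unique(as.vector(
    make_shape_phantom(c(32, 32), 1, seed = 1)$data))), 2)
  ph3 <- make_shape_phantom(c(24, 24, 24), 2, seed = 4)
  expect_equal(length(dim(ph3$data)), 3)
  expect_equal(length(unique(as.vector(ph3$data))), 3)
  expect_error(make_shape_phantom(c(8, 8)), ">= 16")
  expect_error(make_shape_phantom(c(64, 64), 0), "at least 1")
})

test_that("modality simulation remaps classes and reproduces noise per seed", {
  ph <- make_shape_phantom(c(48, 48), 3, seed = 5)
  u <- sort(unique(as.vector(ph$data)))
  ident <- setNames(u, u)
  expect_equal(simulate_modality(ph, ident, 0)$data, ph$data)
  # class-permuting remap: one nonzero column per occupied histogram row
  perm <- setNames(c(u[1], rev(u[-1])), u)
  out <- simulate_modality(ph, perm, 0)
  h <- pv_accumulate(joint_histogram(64), ph, out, NULL, sample_grid(ph, 1))
  occupied <- which(rowSums(h$counts) > 0)
  expect_true(all(rowSums(h$counts[occupied, , drop = FALSE] > 0) == 1))
  n1 <- simulate_modality(ph, ident, 5, seed = 9)
  expect_identical(n1$data, simulate_modality(ph, ident, 5, seed = 9)$data)
  expect_false(identical(n1$data, simulate_modality(ph, ident, 5, seed = 10)$data))
  expect_error(simulate_modality(ph, ident[-2], 0), "missing gray classes")
})

test_that("registration cases record ground truth exactly and are deterministic", {
  cs <- make_registration_case(c(64, 64), "translation", c(3.5, -2.25),
                               noise_sigma = 0, seed = 1)
  expect_equal(affine_apply(cs$true_transform, c(0, 0)), c(3.5, -2.25))
  expect_identical(dim(cs$reference$data), dim(cs$floating$data))
  cs2 <- make_registration_case(c(64, 64), "translation", c(3.5, -2.25),
                                noise_sigma = 0, seed = 1)
  expect_identical(cs$floating$data, cs2$floating$data)
  cs0 <- make_registration_case(c(64, 64), "translation", c(0, 0),
                                noise_sigma = 0, seed = 3)
  # zero translation: floating differs from reference only by the remap
  back <- cs0$modality_remap[as.character(as.vector(cs0$reference$data))]
  expect_equal(as.vector(cs0$floating$data), unname(back))
})

test_that("ffd cases bound the displacement field by the requested magnitude", {
  cs <- make_registration_case(c(64, 64), "ffd", 4, noise_sigma = 0, seed = 5)
  expect_lte(max(abs(cs$true_transform$phi)), 4)
  pts <- sample_grid(c(64, 64), 2)$points
  disp <- ffd_displacement(cs$true_transform, pts)
  expect_lte(max(abs(disp)), 4)        # convex blend of bounded controls
  expect_error(make_registration_case(c(64, 64), "translation", c(40, 0)),
               "frame")
})

test_that("inverting the generating warp recovers the reference up to noise", {
  sigma <- 2
  # integer translation: the inverse warp is exact on the lattice, so the
  # check isolates the remap/warp/noise bookkeeping from resampling error
  cs <- make_registration_case(c(64, 64), "translation", c(3, -2),
                               noise_sigma = sigma, seed = 6)
  inv <- affine_invert(cs$true_transform)
  # floating(v) = remap(ref)(T(v)); sampling floating at T^{-1}(x) and
  # undoing the remap must reproduce the reference on interior voxels
  aligned <- warp_image(cs$floating, inv, "nearest")
  interior <- as.matrix(expand.grid(12:51, 12:51))
  vals <- aligned$data[interior + 1]
  # snap each noisy value to the nearest remapped class, then undo the remap
  targets <- unname(cs$modality_remap)
  sources <- as.numeric(names(cs$modality_remap))
  recovered <- sources[apply(abs(outer(vals, targets, "-")), 1, which.min)]
  refvals <- cs$reference$data[interior + 1]
  expect_lte(mean(abs(recovered - refvals)), 3 * sigma)
  expect_gt(mean(recovered == refvals), 0.95)   # only edge voxels may differ
})

test_that("cases survive a save/load round-trip in both 2-D and 3-D", {
  for (shape in list(c(48, 48), c(24, 24, 24))) {
    kind <- if (length(shape) == 2) "rigid" else "translation"
    cs <- make_registration_case(shape, kind, if (kind == "rigid") 5 else c(1.5, -1, 0.5),
                                 noise_sigma = 1, seed = 7)
    d <- file.path(tempdir(), paste0("case", length(shape)))
    save_case(cs, d)
    back <- load_case(d)
    expect_equal(back$reference$data, unclass(cs$reference$data),
                 ignore_attr = TRUE)
    expect_equal(back$floating$data, unclass(cs$floating$data),
                 ignore_attr = TRUE)
    expect_equal(back$true_transform$matrix, cs$true_transform$matrix,
                 tolerance = 1e-12)
    expect_equal(back$modality_remap, cs$modality_remap)
  }
})
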