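#' Piecewise-constant anatomy phantom
#'
#' Generates a deterministic synthetic "anatomy": `n_structures` nested
#' ellipses (2-D) or ellipsoids (3-D) with distinct gray values on
#' `[0, 255]` over a zero background. Structures are anisotropic, rotated
#' and center-jittered (seeded) so that rotations and deformations of the
#' phantom are detectable by intensity-based similarity.
#'
#' @param shape integer dimensions, each >= 16 (2 or 3 axes).
#' @param n_structures number of nested intensity classes (>= 1).
#' @param seed RNG seed; the same call is bit-identical across runs.
#' @return An [npv_image()] with exactly `n_structures + 1` distinct gray
#'   values (classes + background).
#' @examples
#' ph <- make_shape_phantom(c(64, 64), 3, seed = 1)
#' length(unique(as.vector(ph$data)))   # 4
#' @export
make_shape_phantom <- function(shape, n_structures = 3, seed = 1) {
  shape <- as.integer(shape)
  nd <- length(shape)
  if (!(nd %in% c(2L, 3L))) stop_npv("shape must have 2 or 3 axes")
  if (any(shape < 16L)) stop_npv("each dimension must be >= 16")
  if (n_structures < 1L) stop_npv("need at least 1 structure")
  scene <- with_seed(seed, {
    center0 <- (shape - 1) / 2
    rmax <- min(shape) / 2 - 5
    radii <- seq(rmax, max(rmax * 0.2, 2.5), length.out = n_structures + 1L)[-1L]
    if (n_structures == 1L) radii <- rmax * 0.75
    vals <- round(seq(250, 60, length.out = n_structures))
    if (anyDuplicated(vals)) stop_npv("too many structures for distinct gray values")
    center <- center0
    prev_r <- rmax + 2
    structures <- vector("list", n_structures)
    for (l in seq_len(n_structures)) {
      r <- radii[l]
      center <- center + runif(nd, -1, 1) * min((radii[1] - r) / 2 + 0.5, 1.5)
      # pronounced eccentricity keeps rotations identifiable from intensity
      structures[[l]] <- list(center = center,
                              semi = r * c(runif(1, 0.9, 1),
                                           runif(nd - 1, 0.55, 0.75)),
                              theta = runif(1, 0, pi), value = vals[l])
      prev_r <- r
    }
    structures
  })
  rasterize_scene(scene, shape)
}

# Evaluate the analytic phantom scene (nested rotated ellipses/ellipsoids)
# at arbitrary real-valued coordinates; later structures overwrite earlier
# ones, points outside every structure are background 0.
scene_eval <- function(scene, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, nrow = 1L)
  vals <- numeric(nrow(pts))
  for (st in scene) {
    rel <- sweep(pts, 2L, st$center, `-`)
    rot <- rel
    rot[, 1] <- rel[, 1] * cos(st$theta) + rel[, 2] * sin(st$theta)
    rot[, 2] <- -rel[, 1] * sin(st$theta) + rel[, 2] * cos(st$theta)
    q <- rowSums(sweep(rot^2, 2L, st$semi^2, `/`))
    vals[q <= 1] <- st$value
  }
  vals
}

# Sample a scene on the integer lattice; keeps the scene as an attribute so
# registration cases can evaluate the warped anatomy analytically.
rasterize_scene <- function(scene, shape) {
  pts <- sample_grid(shape, 1L)$points
  img <- array(0, dim = shape)
  img[lattice_index(pts, shape)] <- scene_eval(scene, pts)
  out <- npv_image(img, levels = 256)
  attr(out, "scene") <- scene
  out
}

#' Simulate a different imaging modality
#'
#' Applies a per-class intensity remap (monotone or non-monotone — e.g. a
#' class permutation, emulating how tissue contrasts reorder between CT,
#' MRI and PET) followed by additive Gaussian noise, clipped to the gray
#' range and rounded.
#'
#' @param img source image.
#' @param remap named numeric vector mapping each gray value present in
#'   `img` (names) to its new value, or a vectorized function of gray
#'   values.
#' @param noise_sigma Gaussian noise standard deviation in gray levels.
#' @param seed RNG seed for the noise.
#' @return Remapped [npv_image()].
#' @examples
#' ph <- make_shape_phantom(c(32, 32), 2, seed = 1)
#' u <- sort(unique(as.vector(ph$data)))
#' rm <- setNames(rev(u), u)            # non-monotone class permutation
#' sim <- simulate_modality(ph, rm, noise_sigma = 0)
#' @export
simulate_modality <- function(img, remap, noise_sigma = 0, seed = 1) {
  img <- as_npv_image(img)
  v <- img$data
  if (is.function(remap)) {
    out <- remap(v)
  } else {
    u <- unique(as.vector(v))
    missing <- setdiff(as.character(u), names(remap))
    if (length(missing))
      stop_npv("remap is missing gray classes: %s",
               paste(missing, collapse = ", "))
    out <- array(unname(remap[as.character(as.vector(v))]), dim = dim(v))
  }
  if (noise_sigma > 0)
    out <- out + with_seed(seed, array(rnorm(length(out), 0, noise_sigma),
                                       dim = dim(out)))
  out <- round(pmin(pmax(out, 0), img$levels - 1))
  npv_image(out, img$spacing, img$levels)
}

# Seeded non-monotone remap over the gray classes of an image: background
# stays 0, the class values are sent to well-separated targets in a
# shuffled (non-monotone) order.
default_modality_remap <- function(img, seed) {
  u <- sort(unique(as.vector(as_npv_image(img)$data)))
  classes <- u[u > 0]
  if (length(classes) == 0L) return(setNames(0, "0"))
  targets <- round(seq(60, 250, length.out = max(length(classes), 2)))[seq_along(classes)]
  perm <- with_seed(seed, {
    p <- sample(length(classes))
    tries <- 0
    while (length(classes) > 1 && all(p == seq_along(p)) && tries < 10) {
      p <- sample(length(classes)); tries <- tries + 1
    }
    p
  })
  setNames(c(0, targets[perm]), c(0, classes))
}

#' Synthetic registration case with known ground truth
#'
#' Builds a multimodal phantom pair: the floating image is a
#' modality-remapped, warped, noised copy of the reference, and the exact
#' generating transform (in the same model family the registrar fits) is
#' recorded. Transforms map floating-frame coordinates into the reference
#' frame, the direction in which registration estimates them, so recovery
#' tests compare parameters directly.
#'
#' @param shape image dimensions (default 64 x 64).
#' @param transform_kind `"translation"`, `"rigid"`, `"affine"` or `"ffd"`.
#' @param magnitude translation vector in voxels, rotation angle in degrees
#'   (rigid/affine), or maximum control-point displacement in voxels (ffd).
#'   Scalar translations are drawn uniformly per axis in `[-m, m]`.
#' @param noise_sigma Gaussian noise sd in gray levels added to the
#'   floating image.
#' @param seed master seed; the whole case is bit-identical per seed.
#' @param n_structures phantom classes.
#' @param ffd_spacing control-point spacing for `"ffd"` cases (must divide
#'   `shape`).
#' @return Object of class `npv_case`: `reference`, `floating`,
#'   `true_transform`, `transform_kind`, `modality_remap`, `noise_sigma`,
#'   `seed`.
#' @export
make_registration_case <- function(shape = c(64, 64),
                                   transform_kind = c("translation", "rigid",
                                                      "affine", "ffd"),
                                   magnitude = 3, noise_sigma = 0, seed = 1,
                                   n_structures = 3, ffd_spacing = 16) {
  transform_kind <- match.arg(transform_kind)
  shape <- as.integer(shape)
  nd <- length(shape)
  ref <- make_shape_phantom(shape, n_structures, seed)
  remap <- default_modality_remap(ref, seed + 1000L)
  center <- (shape - 1) / 2
  tr <- switch(transform_kind,
    translation = {
      t <- if (length(magnitude) == nd) as.numeric(magnitude)
           else with_seed(seed + 2000L, runif(nd, -magnitude, magnitude))
      affine_params(translation = t, ndim = nd)
    },
    rigid = affine_rotation(magnitude, center = center, ndim = nd),
    affine = with_seed(seed + 2000L, {
      rot <- affine_rotation(magnitude, center = center, ndim = nd)
      sc <- diag(runif(nd, 0.95, 1.05))
      scale_tr <- affine_params(linear = sc,
                                translation = as.numeric(center - sc %*% center))
      affine_compose(affine_params(translation = runif(nd, -2, 2), ndim = nd),
                     affine_compose(rot, scale_tr))
    }),
    ffd = with_seed(seed + 2000L, {
      g <- make_ffd_grid(shape, ffd_spacing)
      g$phi <- array(runif(length(g$phi), -magnitude, magnitude), dim = dim(g$phi))
      g
    }))
  # content must stay >= 2 voxels inside the frame after warping
  fg <- which(ref$data > 0, arr.ind = TRUE) - 1L
  margin <- min(vapply(seq_len(nd), function(a)
    min(min(fg[, a]), shape[a] - 1L - max(fg[, a])), numeric(1)))
  maxdisp <- if (transform_kind == "ffd") max(abs(tr$phi)) else {
    pts <- sample_grid(shape, 4L)$points
    max(sqrt(rowSums((affine_apply(tr, pts) - pts)^2)))
  }
  if (maxdisp > margin - 2)
    stop_npv(paste("transform magnitude %.2f voxels exceeds the %.0f-voxel",
                   "frame margin; warped content would leave the frame"),
             maxdisp, margin)
  # The warp is applied analytically: the floating voxel at p takes the
  # remapped anatomy value at T(p), evaluated from the scene model rather
  # than by resampling the discrete reference, so the pair is free of
  # interpolation blur and the ground truth is exact.
  scene <- attr(ref, "scene")
  pts <- sample_grid(shape, 1L)$points
  fvals <- unname(remap[as.character(scene_eval(scene, transform_points(tr, pts)))])
  flt <- array(0, dim = shape)
  flt[lattice_index(pts, shape)] <- fvals
  if (noise_sigma > 0)
    flt <- flt + with_seed(seed + 3000L,
      array(rnorm(length(flt), 0, noise_sigma), dim = dim(flt)))
  flt <- npv_image(round(pmin(pmax(flt, 0), 255)), ref$spacing, ref$levels)
  structure(list(reference = ref, floating = flt, true_transform = tr,
                 transform_kind = transform_kind, modality_remap = remap,
                 noise_sigma = noise_sigma, seed = seed),
            class = "npv_case")
}

#' @export
print.npv_case <- function(x, ...) {
  cat(sprintf("<npv_case> %s, %s transform, noise sigma %.2f, seed %d\n",
              paste(dim(x$reference$data), collapse = "x"),
              x$transform_kind, x$noise_sigma, x$seed))
  invisible(x)
}

#' Save a registration case to a directory
#'
#' Writes `reference` and `floating` images (PNG for 2-D, NIfTI for 3-D)
#' plus `case.json` with the ground-truth transform, remap, noise level and
#' seed.
#'
#' @param case an [make_registration_case()] result.
#' @param dir destination directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_case <- function(case, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (img_ndim(case$reference) == 2L) ".png" else ".nii.gz"
  write_image(case$reference, file.path(dir, paste0("reference", ext)))
  write_image(case$floating, file.path(dir, paste0("floating", ext)))
  meta <- list(transform_kind = case$transform_kind,
               true_transform = jsonlite::fromJSON(
                 transform_to_json(case$true_transform)),
               modality_remap = as.list(case$modality_remap),
               noise_sigma = case$noise_sigma, seed = case$seed,
               image_format = ext)
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA),
             file.path(dir, "case.json"))
  invisible(dir)
}

#' Load a registration case saved by [save_case()]
#' @param dir case directory.
#' @return An `npv_case`.
#' @export
load_case <- function(dir) {
  meta <- jsonlite::fromJSON(file.path(dir, "case.json"),
                             simplifyDataFrame = FALSE)
  ext <- meta$image_format
  structure(list(
    reference = read_image(file.path(dir, paste0("reference", ext))),
    floating = read_image(file.path(dir, paste0("floating", ext))),
    true_transform = transform_from_json(
      jsonlite::toJSON(meta$true_transform, auto_unbox = TRUE, digits = NA)),
    transform_kind = meta$transform_kind,
    modality_remap = setNames(as.numeric(unlist(meta$modality_remap)),
                              names(meta$modality_remap)),
    noise_sigma = meta$noise_sigma, seed = meta$seed),
    class = "npv_case")
}
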