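#' Scalar image on an integer lattice
#'
#' Container for a 2-D or 3-D gray-level image. Values are scalar
#' intensities in `[0, levels - 1]`; `spacing` records physical units per
#' voxel per axis (informational; registration operates on the voxel
#' lattice). The first array dimension is the x axis.
#'
#' @param data numeric matrix (2-D) or 3-dimensional array of finite values
#'   in `[0, levels - 1]`.
#' @param spacing positive numeric vector of voxel spacings, recycled to the
#'   number of axes. Default 1.
#' @param levels number of gray levels L; values must lie in `[0, L - 1]`.
#' @return An object of class `npv_image` with fields `data`, `spacing`,
#'   `levels`.
#' @examples
#' img <- npv_image(matrix(0:255, 16, 16))
#' dim(img)
#' @export
npv_image <- function(data, spacing = 1, levels = 256) {
  data <- unclass(data)
  if (is.null(dim(data)) || !(length(dim(data)) %in% c(2L, 3L)))
    stop_npv("image data must have 2 or 3 axes")
  if (!is.numeric(data) || any(!is.finite(data)))
    stop_npv("image data must be finite numeric")
  if (any(data < 0) || any(data > levels - 1))
    stop_npv("image values must lie in [0, %d]", levels - 1L)
  nd <- length(dim(data))
  spacing <- rep_len(as.numeric(spacing), nd)
  if (any(spacing <= 0)) stop_npv("spacing must be strictly positive")
  structure(list(data = data, spacing = spacing, levels = as.integer(levels)),
            class = "npv_image")
}

#' @export
dim.npv_image <- function(x) dim(x$data)

#' @export
print.npv_image <- function(x, ...) {
  cat(sprintf("<npv_image> %s, %d gray levels, spacing %s\n",
              paste(dim(x$data), collapse = "x"), x$levels,
              paste(format(x$spacing), collapse = "x")))
  invisible(x)
}

as_npv_image <- function(x, levels = 256) {
  if (inherits(x, "npv_image")) x else npv_image(x, levels = levels)
}

img_ndim <- function(img) length(dim(img$data))

#' Read an image from disk
#'
#' NIfTI (`.nii`, `.nii.gz`) for volumes and 2-D slices; PNG and TIFF for
#' 2-D 8/16-bit grayscale slices. Gray values are returned on the integer
#' scale `0..levels-1` (PNG/TIFF assumed 8-bit unless 16-bit is detected).
#'
#' @param path file path; format is chosen by extension.
#' @param levels gray levels to assume for NIfTI data (default 256).
#' @return An [npv_image()].
#' @export
read_image <- function(path, levels = 256) {
  ext <- tolower(sub("^.*?((\\.nii)?\\.[a-z]+)$", "\\1", path))
  if (ext %in% c(".nii", ".nii.gz")) {
    nii <- RNifti::readNifti(path)
    arr <- as.array(nii)
    nd <- length(dim(arr))
    if (!(nd %in% c(2L, 3L)))
      stop_npv("NIfTI image has %d axes; only 2-D/3-D scalar images supported", nd)
    sp <- RNifti::pixdim(nii)[seq_len(nd)]
    return(npv_image(arr, spacing = sp, levels = levels))
  }
  if (ext %in% c(".png", ".tif", ".tiff")) {
    raw <- if (ext == ".png") png::readPNG(path) else tiff::readTIFF(path)
    if (length(dim(raw)) == 3L)
      stop_npv(paste("multi-channel (RGB/RGBA) input is not a scalar image;",
                     "convert to grayscale before registration"))
    # readers return [row = y, col = x] in [0, 1]; transpose to [x, y]
    return(npv_image(t(round(raw * 255)), levels = 256))
  }
  stop_npv("unknown image format '%s' (use .nii, .nii.gz, .png, .tif)", ext)
}

#' Write an image to disk
#'
#' Inverse of [read_image()]; integer gray data round-trips losslessly.
#' PNG/TIFF accept 2-D images only.
#'
#' @param img an [npv_image()] (or bare array).
#' @param path destination; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  img <- as_npv_image(img)
  ext <- tolower(sub("^.*?((\\.nii)?\\.[a-z]+)$", "\\1", path))
  if (ext %in% c(".nii", ".nii.gz")) {
    nii <- RNifti::asNifti(img$data)
    nii <- RNifti::`pixdim<-`(nii, img$spacing)
    RNifti::writeNifti(nii, path)
    return(invisible(path))
  }
  if (ext %in% c(".png", ".tif", ".tiff")) {
    if (img_ndim(img) != 2L) stop_npv("PNG/TIFF output requires a 2-D image")
    mat <- t(img$data) / 255
    if (ext == ".png") png::writePNG(mat, path)
    else tiff::writeTIFF(mat, path, bits.per.sample = 8L)
    return(invisible(path))
  }
  stop_npv("unknown image format '%s'", ext)
}

#' Min-max gray normalization
#'
#' Linearly rescales intensities so the minimum maps to 0 and the maximum to
#' `levels - 1`, rounding to integers (e.g. body pixels from different
#' devices normalized to a common 256-level scale). Idempotent on its own
#' output.
#'
#' @param img image (constant images are rejected as degenerate).
#' @param levels target number of gray levels (default 256).
#' @return Normalized [npv_image()] with `levels` set.
#' @examples
#' normalize_gray(npv_image(matrix(c(10, 20), 8, 8)))$data[1, 1:2]
#' @export
normalize_gray <- function(img, levels = 256) {
  if (!inherits(img, "npv_image"))
    img <- npv_image(img, levels = max(levels, max(img) + 1))
  rng <- range(img$data)
  if (rng[1] == rng[2])
    stop_npv("constant image cannot be gray-normalized (degenerate input)")
  out <- round((img$data - rng[1]) * (levels - 1) / (rng[2] - rng[1]))
  npv_image(out, spacing = img$spacing, levels = levels)
}

#' Strip low-intensity background
#'
#' Removes interference such as masks or bed frames: voxels below
#' `threshold` are set to 0 and, optionally, only the largest above-threshold
#' connected component (face connectivity) is retained.
#'
#' @param img image.
#' @param threshold gray level in `[0, levels)`; voxels `< threshold` are
#'   zeroed.
#' @param keep_largest if `TRUE`, keep only the largest connected foreground
#'   component.
#' @return Cleaned [npv_image()]. An empty foreground yields an all-zero
#'   image with a warning.
#' @export
strip_background <- function(img, threshold, keep_largest = FALSE) {
  img <- as_npv_image(img)
  if (threshold < 0 || threshold >= img$levels)
    stop_npv("threshold must lie in [0, levels)")
  data <- img$data
  data[data < threshold] <- 0
  if (all(data == 0)) {
    warning("strip_background: empty foreground, returning all-zero image")
    return(npv_image(data, img$spacing, img$levels))
  }
  if (keep_largest) {
    lab <- label_components(data > 0)
    sizes <- tabulate(lab[lab > 0])
    data[lab != which.max(sizes)] <- 0
  }
  npv_image(data, img$spacing, img$levels)
}

# Face-connected component labelling (2-D: 4-neighbor, 3-D: 6-neighbor) by
# breadth-first flood fill over linear indices.
label_components <- function(mask) {
  dims <- dim(mask)
  nd <- length(dims)
  strides <- c(1, cumprod(dims))[seq_len(nd)]
  lab <- array(0L, dims)
  cur <- 0L
  coords <- which(mask, arr.ind = TRUE)
  lin <- which(mask)
  pos <- integer(prod(dims))
  pos[lin] <- seq_along(lin)   # map linear index -> row in coords
  for (s in lin) {
    if (lab[s] > 0L) next
    cur <- cur + 1L
    queue <- s
    lab[s] <- cur
    while (length(queue)) {
      v <- queue[[length(queue)]]
      queue <- queue[-length(queue)]
      cv <- coords[pos[v], ]
      for (a in seq_len(nd)) for (dlt in c(-1L, 1L)) {
        ca <- cv[a] + dlt
        if (ca < 1L || ca > dims[a]) next
        nb <- v + dlt * strides[a]
        if (mask[nb] && lab[nb] == 0L) {
          lab[nb] <- cur
          queue <- c(queue, nb)
        }
      }
    }
  }
  lab
}

#' Intensity centroid (gray center)
#'
#' The gray-weighted center of mass, `c_x = sum(x * g) / sum(g)` per axis,
#' in 0-based voxel coordinates. Used to pre-align the reference and
#' floating images before affine optimization.
#'
#' @param img image with positive total intensity.
#' @return Numeric vector `(c_x, c_y[, c_z])`.
#' @examples
#' m <- matrix(0, 8, 8); m[4, 6] <- 10   # voxel (x, y) = (3, 5), 0-based
#' intensity_centroid(npv_image(m))
#' @export
intensity_centroid <- function(img) {
  img <- as_npv_image(img)
  tot <- sum(img$data)
  if (tot <= 0) stop_npv("all-zero image has no intensity centroid")
  vapply(seq_len(img_ndim(img)), function(a) {
    marg <- apply(img$data, a, sum)
    sum((seq_along(marg) - 1) * marg) / tot
  }, numeric(1))
}

#' Regular-grid sample set
#'
#' Selects every `stride`-th lattice point per axis (0-based coordinates,
#' x varying fastest) as the sample set over which joint histograms are
#' accumulated — the speed/accuracy balance of sparse sampling.
#'
#' @param img image, or an integer vector of lattice dimensions.
#' @param stride positive integer stride per axis (recycled).
#' @return Object of class `npv_samples` with fields `points` (n x D matrix
#'   of 0-based coordinates), `stride`, `dims`.
#' @examples
#' nrow(sample_grid(c(64, 64), 4)$points)   # 256
#' @export
sample_grid <- function(img, stride = 1) {
  dims <- if (inherits(img, "npv_image")) dim(img$data)
          else if (is.numeric(img)) as.integer(img)
          else dim(img)
  nd <- length(dims)
  stride <- rep_len(as.integer(stride), nd)
  if (any(stride < 1)) stop_npv("stride must be >= 1 per axis")
  axes <- lapply(seq_len(nd), function(a) seq.int(0L, dims[a] - 1L, by = stride[a]))
  pts <- as.matrix(expand.grid(axes, KEEP.OUT.ATTRS = FALSE))
  dimnames(pts) <- NULL
  structure(list(points = pts, stride = stride, dims = dims),
            class = "npv_samples")
}

# 1-based linear index of 0-based lattice coordinates into an array of `dims`
lattice_index <- function(pts, dims) {
  strides <- c(1, cumprod(dims[-length(dims)]))
  as.integer(pts %*% strides) + 1L
}
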