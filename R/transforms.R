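#' Affine transform parameters
#'
#' A homogeneous `(D+1) x (D+1)` matrix with linear block `a_11..a_DD` and a
#' translation column; the last row is `(0, ..., 0, 1)`. The parameter
#' vector ordering used throughout the package is the linear entries
#' row-major followed by the translation components.
#'
#' @param matrix full homogeneous matrix, or `NULL` to build from parts.
#' @param linear `D x D` linear block (default identity).
#' @param translation length-D translation (default 0).
#' @param ndim dimensionality (2 or 3) when building from parts.
#' @return Object of class `npv_affine`.
#' @examples
#' A <- affine_params(translation = c(2, -1), ndim = 2)
#' affine_apply(A, c(0, 0))
#' @export
affine_params <- function(matrix = NULL, linear = NULL, translation = NULL,
                          ndim = NULL) {
  if (is.null(matrix)) {
    if (is.null(ndim))
      ndim <- if (!is.null(linear)) nrow(linear)
              else if (!is.null(translation)) length(translation)
              else stop_npv("need ndim, linear or translation")
    if (is.null(linear)) linear <- diag(ndim)
    if (is.null(translation)) translation <- rep(0, ndim)
    matrix <- diag(ndim + 1)
    matrix[seq_len(ndim), seq_len(ndim)] <- linear
    matrix[seq_len(ndim), ndim + 1] <- translation
  }
  d <- nrow(matrix) - 1L
  if (nrow(matrix) != ncol(matrix) || !(d %in% c(2L, 3L)))
    stop_npv("affine matrix must be 3x3 or 4x4")
  if (any(matrix[d + 1L, ] != c(rep(0, d), 1)))
    stop_npv("last homogeneous row must be (0, ..., 0, 1)")
  if (abs(det(matrix[seq_len(d), seq_len(d), drop = FALSE])) <= 1e-12)
    stop_npv("affine linear block is singular")
  structure(list(matrix = matrix, ndim = d), class = "npv_affine")
}

#' @export
print.npv_affine <- function(x, ...) {
  cat(sprintf("<npv_affine> %d-D\n", x$ndim)); print(x$matrix); invisible(x)
}

affine_linear <- function(p) p$matrix[seq_len(p$ndim), seq_len(p$ndim), drop = FALSE]
affine_translation <- function(p) p$matrix[seq_len(p$ndim), p$ndim + 1L]

#' Affine parameter vector (linear row-major, then translation)
#' @param params an [affine_params()].
#' @return Numeric vector of length `D^2 + D`.
#' @export
affine_vector <- function(params) {
  c(as.vector(t(affine_linear(params))), affine_translation(params))
}

#' Rebuild an affine transform from its parameter vector
#' @param v vector as produced by [affine_vector()].
#' @param ndim dimensionality.
#' @return An [affine_params()].
#' @export
affine_from_vector <- function(v, ndim) {
  L <- matrix(v[seq_len(ndim^2)], ndim, ndim, byrow = TRUE)
  affine_params(linear = L, translation = v[ndim^2 + seq_len(ndim)])
}

#' Apply an affine transform to points
#'
#' Homogeneous matrix-vector product `q = L p + t`.
#'
#' @param params an [affine_params()].
#' @param pts length-D point or `n x D` matrix of points.
#' @return Transformed points, same shape as the input.
#' @export
affine_apply <- function(params, pts) {
  vec <- is.null(dim(pts))
  if (vec) pts <- matrix(pts, nrow = 1L)
  if (ncol(pts) != params$ndim) stop_npv("point dimensionality mismatch")
  out <- pts %*% t(affine_linear(params))
  out <- sweep(out, 2L, affine_translation(params), `+`)
  if (vec) drop(out) else out
}

#' Compose two affine transforms
#'
#' `affine_apply(affine_compose(A, B), p)` equals
#' `affine_apply(A, affine_apply(B, p))`.
#'
#' @param a,b [affine_params()] objects of equal dimensionality.
#' @return The composed [affine_params()].
#' @export
affine_compose <- function(a, b) affine_params(matrix = a$matrix %*% b$matrix)

#' Invert an affine transform
#' @param params an [affine_params()].
#' @return The inverse [affine_params()].
#' @export
affine_invert <- function(params) affine_params(matrix = solve(params$matrix))

#' Rotation about a center point
#'
#' 2-D rotation, or 3-D rotation about the z axis, by `theta_deg` degrees
#' around `center` (defaults to the origin).
#'
#' @param theta_deg rotation angle in degrees (counter-clockwise in the
#'   x-y plane).
#' @param center rotation center (0-based voxel coordinates).
#' @param ndim 2 or 3.
#' @return An [affine_params()].
#' @export
affine_rotation <- function(theta_deg, center = NULL, ndim = 2) {
  th <- theta_deg * pi / 180
  R2 <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2, byrow = TRUE)
  L <- diag(ndim)
  L[1:2, 1:2] <- R2
  if (is.null(center)) center <- rep(0, ndim)
  t <- center - L %*% center
  affine_params(linear = L, translation = as.numeric(t))
}

#' Cubic B-spline basis weights
#'
#' The four cubic B-spline basis functions at local coordinate `u`:
#' `B0 = (1-u)^3/6`, `B1 = (3u^3 - 6u^2 + 4)/6`,
#' `B2 = (-3u^3 + 3u^2 + 3u + 1)/6`, `B3 = u^3/6`. They are nonnegative and
#' sum to 1 for every u (partition of unity), which makes a uniform control
#' lattice displacement translate every image point by exactly that amount.
#'
#' @param u numeric vector of local coordinates in `[0, 1)`.
#' @return `length(u) x 4` matrix of weights (columns B0..B3).
#' @examples
#' bspline_basis(0)     # 1/6, 4/6, 1/6, 0
#' bspline_basis(0.5)
#' @export
bspline_basis <- function(u) {
  if (any(u < 0 | u >= 1)) stop_npv("B-spline local coordinate must lie in [0, 1)")
  cbind((1 - u)^3, 3 * u^3 - 6 * u^2 + 4, -3 * u^3 + 3 * u^2 + 3 * u + 1, u^3) / 6
}

#' Free-form deformation control lattice
#'
#' A cubic B-spline FFD over the image domain `[0, X] x [0, Y] (x [0, Z])`.
#' Control points are spaced `lambda` voxels apart (`lambda` must divide the
#' image extent, giving `n = extent / lambda` interior intervals per axis)
#' and the lattice is padded so every image point has a full 4-point support
#' per axis. Displacements are in voxels and start at zero (identity map).
#'
#' @param extent integer image dimensions `(X, Y[, Z])`.
#' @param spacing control-point spacing `lambda` per axis (recycled); must
#'   divide the extent.
#' @return Object of class `npv_ffd` with fields `phi` (array of control
#'   displacements, last dimension the D components), `spacing`, `n`
#'   (interior intervals per axis), `extent`, `ndim`, `raw_fractions`.
#' @examples
#' g <- make_ffd_grid(c(64, 64), 16)
#' g$n
#' @export
make_ffd_grid <- function(extent, spacing) {
  extent <- as.numeric(extent)
  nd <- length(extent)
  if (!(nd %in% c(2L, 3L))) stop_npv("extent must have 2 or 3 axes")
  spacing <- rep_len(as.numeric(spacing), nd)
  if (any(spacing <= 0)) stop_npv("spacing must be positive")
  if (any(extent %% spacing != 0)) {
    a <- which(extent %% spacing != 0)[1]
    div <- Filter(function(s) extent[a] %% s == 0, seq_len(extent[a]))
    stop_npv("spacing %g does not divide image extent %g on axis %d (valid: %s)",
             spacing[a], extent[a], a,
             paste(utils::head(div[div >= 2], 12), collapse = ", "))
  }
  n <- as.integer(extent / spacing)
  # control indices -1 .. n+2 per axis (n+4 points): full 4-point support
  # for every x in [0, extent]
  phi <- array(0, dim = c(n + 4L, nd))
  structure(list(phi = phi, spacing = spacing, n = n, extent = extent,
                 ndim = nd, raw_fractions = FALSE),
            class = "npv_ffd")
}

#' @export
print.npv_ffd <- function(x, ...) {
  cat(sprintf("<npv_ffd> %d-D, spacing %s, %s interior intervals, max |phi| %.3g\n",
              x$ndim, paste(x$spacing, collapse = "x"),
              paste(x$n, collapse = "x"), max(abs(x$phi))))
  invisible(x)
}

#' FFD local coordinates of points
#'
#' Base control index `i = floor(x / lambda) - 1` and lattice-normalized
#' fraction `u = x / lambda - floor(x / lambda)` per axis. (With
#' `raw_fractions = TRUE` on the grid, fractions are taken from the raw
#' coordinate, `u = x - floor(x)`.)
#'
#' @param pts point or `n x D` matrix, inside the image extent.
#' @param grid an [make_ffd_grid()] lattice.
#' @return List with integer `index` and real `frac` matrices (`n x D`).
#' @export
ffd_local_coords <- function(pts, grid) {
  if (is.null(dim(pts))) pts <- matrix(pts, nrow = 1L)
  for (a in seq_len(grid$ndim))
    if (any(pts[, a] < 0 | pts[, a] > grid$extent[a]))
      stop_npv("point outside image extent on axis %d", a)
  tt <- sweep(pts, 2L, grid$spacing, `/`)
  fl <- floor(tt)
  frac <- if (isTRUE(grid$raw_fractions)) pts - floor(pts) else tt - fl
  list(index = matrix(as.integer(fl), nrow(pts)) - 1L, frac = frac)
}

# Precompute the tensor-product weights and flat phi indices for a fixed
# point set, so repeated evaluation under changing control displacements
# (the optimizer's inner loop) is a single indexed sum.
ffd_plan <- function(grid, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, nrow = 1L)
  lc <- ffd_local_coords(pts, grid)
  nd <- grid$ndim
  n <- nrow(pts)
  basis <- lapply(seq_len(nd), function(a) bspline_basis(lc$frac[, a]))
  npts_axis <- grid$n + 4L
  combos <- as.matrix(expand.grid(rep(list(0:3), nd), KEEP.OUT.ATTRS = FALSE))
  W <- matrix(1, n, nrow(combos))
  idx <- matrix(0L, n, nrow(combos))
  strides <- c(1L, cumprod(npts_axis))[seq_len(nd)]
  for (r in seq_len(nrow(combos))) {
    w <- rep(1, n)
    flat <- rep(0L, n)
    for (a in seq_len(nd)) {
      l <- combos[r, a]
      w <- w * basis[[a]][, l + 1L]
      # control index i+l in -1..n+2 maps to array slot i+l+2 (1-based)
      flat <- flat + (lc$index[, a] + l + 1L) * strides[a]
    }
    W[, r] <- w
    idx[, r] <- flat + 1L
  }
  list(W = W, idx = idx, n = n, comp_stride = prod(npts_axis))
}

ffd_disp_from_plan <- function(plan, phi) {
  nd <- length(dim(phi))
  ncomp <- dim(phi)[nd]
  phiv <- as.vector(phi)
  out <- matrix(0, plan$n, ncomp)
  for (comp in seq_len(ncomp)) {
    vals <- phiv[plan$idx + (comp - 1L) * plan$comp_stride]
    out[, comp] <- rowSums(plan$W * matrix(vals, plan$n))
  }
  out
}

#' FFD displacement field at points
#'
#' Tensor-product B-spline blend of the 4x4 (2-D) or 4x4x4 (3-D)
#' surrounding control displacements:
#' `disp(x) = sum_{l,m[,n]} B_l(u) B_m(v) [B_n(w)] phi_{i+l, j+m[, k+n]}`.
#'
#' @param grid an [make_ffd_grid()] lattice.
#' @param pts point or `n x D` matrix inside the extent.
#' @return `n x D` matrix of displacements (voxels).
#' @export
ffd_displacement <- function(grid, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, nrow = 1L)
  ffd_disp_from_plan(ffd_plan(grid, pts), grid$phi)
}

#' Apply an FFD transform to points
#'
#' `T(p) = p + disp(p)`; an all-zero lattice is the identity map.
#'
#' @inheritParams ffd_displacement
#' @return Displaced points, same shape as input.
#' @export
ffd_apply <- function(grid, pts) {
  vec <- is.null(dim(pts))
  if (vec) pts <- matrix(pts, nrow = 1L)
  out <- pts + ffd_displacement(grid, pts)
  if (vec) drop(out) else out
}

#' Compose an affine transform with an FFD
#'
#' The two-stage transform hierarchy: `T(p) = A(p) + disp_ffd(p)`, a global
#' affine plus a local B-spline displacement evaluated in the floating
#' frame.
#'
#' @param affine an [affine_params()] (or `NULL` for identity).
#' @param ffd an [make_ffd_grid()] lattice (or `NULL` for none).
#' @return Object of class `npv_composed`.
#' @export
compose_transform <- function(affine = NULL, ffd = NULL) {
  structure(list(affine = affine, ffd = ffd), class = "npv_composed")
}

#' Map points through any supported transform
#'
#' Generic entry point used by the histogram accumulators and the warper:
#' accepts [affine_params()], an FFD lattice, a [compose_transform()]
#' object, a function of an `n x D` matrix, or `NULL` (identity).
#'
#' @param transform the transform.
#' @param pts `n x D` matrix of points.
#' @return `n x D` matrix of mapped points.
#' @export
transform_points <- function(transform, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, nrow = 1L)
  if (is.null(transform)) return(pts)
  if (inherits(transform, "npv_affine")) return(affine_apply(transform, pts))
  if (inherits(transform, "npv_ffd")) return(ffd_apply(transform, pts))
  if (inherits(transform, "npv_composed")) {
    out <- if (is.null(transform$affine)) pts
           else affine_apply(transform$affine, pts)
    if (!is.null(transform$ffd))
      out <- out + ffd_displacement_clamped(transform$ffd, pts)
    return(out)
  }
  if (is.function(transform)) return(transform(pts))
  stop_npv("unsupported transform of class %s", paste(class(transform), collapse = "/"))
}

# FFD displacement with points clamped to the valid extent, so composed
# transforms can be queried slightly outside the domain (e.g. during
# inverse iteration); identical to ffd_displacement inside the extent.
ffd_displacement_clamped <- function(grid, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, nrow = 1L)
  for (a in seq_len(grid$ndim))
    pts[, a] <- pmin(pmax(pts[, a], 0), grid$extent[a])
  ffd_displacement(grid, pts)
}

#' Warp an image through a transform (backward resampling)
#'
#' Each output voxel v receives the input image sampled at `T(v)` with the
#' chosen intensity interpolation; locations outside the input are treated
#' as 0 background. Note that the transform argument maps output-frame
#' coordinates to input-frame coordinates, matching the direction in which
#' registration transforms are estimated.
#'
#' @param img input image.
#' @param transform any transform accepted by [transform_points()].
#' @param interpolation `"linear"` (default), `"nearest"`, or `"cubic"`
#'   (Keys cubic convolution, a = -0.5).
#' @return Warped [npv_image()] of the same shape.
#' @export
warp_image <- function(img, transform,
                       interpolation = c("linear", "nearest", "cubic")) {
  img <- as_npv_image(img)
  interpolation <- match.arg(interpolation)
  dims <- dim(img$data)
  pts <- sample_grid(dims, 1L)$points
  src <- transform_points(transform, pts)
  vals <- interp_image(img$data, src, interpolation)
  vals <- pmin(pmax(vals, 0), img$levels - 1)
  out <- array(0, dims)
  out[lattice_index(pts, dims)] <- vals
  npv_image(out, img$spacing, img$levels)
}

# Sample `data` (0 outside) at real-valued 0-based coordinates `src`.
interp_image <- function(data, src, interpolation) {
  dims <- dim(data)
  nd <- ncol(src)
  fetch <- function(coords) {
    ok <- rep(TRUE, nrow(coords))
    for (a in seq_len(nd))
      ok <- ok & coords[, a] >= 0 & coords[, a] <= dims[a] - 1L
    v <- numeric(nrow(coords))
    if (any(ok))
      v[ok] <- data[lattice_index(coords[ok, , drop = FALSE], dims)]
    v
  }
  if (interpolation == "nearest") return(fetch(round(src)))
  spec <- if (interpolation == "linear") list(support = 1L, kind = "linear")
          else list(support = 2L, kind = "keys")
  kfun <- if (interpolation == "linear") linear_kernel else keys_kernel
  s <- spec$support
  base <- floor(src)
  frac <- src - base
  offs <- as.matrix(expand.grid(rep(list(seq.int(1L - s, s)), nd),
                                KEEP.OUT.ATTRS = FALSE))
  vals <- numeric(nrow(src))
  for (r in seq_len(nrow(offs))) {
    w <- rep(1, nrow(src))
    for (a in seq_len(nd)) w <- w * kfun(offs[r, a] - frac[, a])
    vals <- vals + w * fetch(sweep(base, 2L, offs[r, ], `+`))
  }
  vals
}

# Keys cubic convolution kernel (a = -0.5), the standard image resampling
# cubic; interpolating, support 2.
keys_kernel <- function(x) {
  t <- abs(x)
  ifelse(t < 1, 1.5 * t^3 - 2.5 * t^2 + 1,
         ifelse(t < 2, -0.5 * t^3 + 2.5 * t^2 - 4 * t + 2, 0))
}

#' Serialize a transform to JSON
#'
#' Affine matrices serialize to their entries; FFD lattices to shape,
#' spacing and the displacement table; compositions to both parts.
#'
#' @param transform an affine, FFD or composed transform.
#' @param path optional file; if omitted the JSON string is returned.
#' @return JSON string (invisibly, if written to `path`).
#' @export
transform_to_json <- function(transform, path = NULL) {
  enc <- function(tr) {
    if (is.null(tr)) return(NULL)
    if (inherits(tr, "npv_affine"))
      return(list(type = "affine", matrix = tr$matrix))
    if (inherits(tr, "npv_ffd"))
      return(list(type = "ffd", spacing = tr$spacing, n = tr$n,
                  extent = tr$extent, phi_dim = dim(tr$phi),
                  phi = as.vector(tr$phi),
                  raw_fractions = isTRUE(tr$raw_fractions)))
    if (inherits(tr, "npv_composed"))
      return(list(type = "composed", affine = enc(tr$affine), ffd = enc(tr$ffd)))
    stop_npv("cannot serialize transform of class %s", class(tr)[1])
  }
  js <- jsonlite::toJSON(enc(transform), digits = NA, auto_unbox = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Deserialize a transform from JSON
#' @param json JSON string or file path produced by [transform_to_json()].
#' @return The transform object.
#' @export
transform_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  dec <- function(o) {
    if (is.null(o)) return(NULL)
    switch(o$type,
      affine = {
        m <- o$matrix
        if (!is.matrix(m)) m <- do.call(rbind, m)
        affine_params(matrix = m)
      },
      ffd = {
        g <- make_ffd_grid(o$extent, o$spacing)
        g$phi <- array(o$phi, dim = o$phi_dim)
        g$raw_fractions <- isTRUE(o$raw_fractions)
        g
      },
      composed = compose_transform(dec(o$affine), dec(o$ffd)),
      stop_npv("unknown transform type '%s'", o$type))
  }
  dec(obj)
}
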