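#' Interpolation kernel specification
#'
#' Kernels used to distribute each sample's unit mass over the reference
#' grid neighbors during joint-histogram accumulation. Every admissible
#' kernel f must satisfy the two accumulation conditions: nonnegativity
#' (f(x) >= 0) and partition of unity (sum over integer shifts m of
#' f(m - eta) = 1 for every fractional offset eta in [0, 1)), which together
#' guarantee that each sample contributes exactly weight 1 to the histogram.
#'
#' Available kinds:
#' \describe{
#'   \item{`linear`}{the classical PV kernel, `1 - |x|` on `|x| < 1`.}
#'   \item{`cubic_hermite`}{default NPV kernel `a|x|^3 + b|x|^2 + c|x| + d`
#'     on `|x| < 1` (even extension) with coefficients `(2, -3, 0, 1)` —
#'     the degree-3 interpolating kernel satisfying both conditions exactly
#'     with f(0) = 1 and zero slope at the support boundary.}
#'   \item{`cubic_bspline`}{the classical cubic B-spline, support half-width
#'     2, non-interpolating (f(0) = 2/3); spreads mass over 4 neighbors per
#'     axis.}
#' }
#'
#' @param kind kernel family.
#' @param coefficients for `cubic_hermite`, numeric `(a, b, c, d)`; ignored
#'   otherwise. The constructor rejects coefficient sets violating either
#'   accumulation condition (checked on a 101-point offset grid to 1e-12).
#' @return Object of class `npv_kernel` with fields `kind`, `coefficients`,
#'   `support` (half-width in voxels).
#' @examples
#' kernel_spec()                      # default cubic Hermite
#' kernel_spec("linear")              # classical PV
#' @export
kernel_spec <- function(kind = c("cubic_hermite", "linear", "cubic_bspline"),
                        coefficients = NULL) {
  kind <- match.arg(kind)
  spec <- switch(kind,
    linear = list(kind = kind, coefficients = NULL, support = 1L),
    cubic_hermite = list(
      kind = kind,
      coefficients = if (is.null(coefficients)) c(a = 2, b = -3, c = 0, d = 1)
                     else setNames(as.numeric(coefficients), c("a", "b", "c", "d")),
      support = 1L),
    cubic_bspline = list(kind = kind, coefficients = NULL, support = 2L))
  spec <- structure(spec, class = "npv_kernel")
  validate_kernel(spec)
  spec
}

validate_kernel <- function(spec, tol = 1e-12) {
  eta <- seq(0, 1, length.out = 101L)[-101L]
  shifts <- seq.int(1L - spec$support, spec$support)
  vals <- outer(eta, shifts, function(e, m) kernel_eval(spec, m - e))
  if (any(vals < -tol))
    stop_npv("invalid kernel: negative values (nonnegativity condition violated)")
  pou <- rowSums(vals)
  if (any(abs(pou - 1) > tol))
    stop_npv("invalid kernel: shifted copies do not sum to 1 (partition of unity violated, max deviation %.3g)",
             max(abs(pou - 1)))
  dense <- seq(-spec$support, spec$support, length.out = 401L)
  if (max(abs(kernel_eval(spec, dense) - kernel_eval(spec, -dense))) > tol)
    stop_npv("invalid kernel: not even")
  invisible(spec)
}

#' Evaluate an interpolation kernel
#'
#' @param spec a [kernel_spec()].
#' @param x numeric vector of offsets in voxels.
#' @return Kernel values, zero outside the support.
#' @export
kernel_eval <- function(spec, x) {
  # expression trees kept identical to the compiled core (src/accumulate.cpp)
  # so the R path and the C++ path agree to the last bit
  t <- abs(x)
  t2 <- t * t
  t3 <- t2 * t
  switch(spec$kind,
    linear = ifelse(t < 1, 1 - t, 0),
    cubic_hermite = {
      co <- spec$coefficients
      ifelse(t < 1, co[1] * t3 + co[2] * t2 + co[3] * t + co[4], 0)
    },
    cubic_bspline = {
      u <- 2 - t
      u3 <- (u * u) * u
      ifelse(t < 1, 2 / 3 - t2 + t3 / 2, ifelse(t < 2, u3 / 6, 0))
    })
}

#' Classical PV (linear) kernel
#'
#' `1 - |x|` for `|x| < 1`, else 0.
#'
#' @param x numeric vector.
#' @return Kernel values.
#' @examples
#' linear_kernel(c(0, 0.5, 1, -2))   # 1, 0.5, 0, 0
#' @export
linear_kernel <- function(x) {
  t <- abs(x)
  ifelse(t < 1, 1 - t, 0)
}

#' Cubic NPV kernel
#'
#' `a|x|^3 + b|x|^2 + c|x| + d` on `|x| < 1` (even extension), 0 outside;
#' defaults to the cubic Hermite coefficients `(2, -3, 0, 1)`.
#'
#' @param x numeric vector.
#' @param spec a [kernel_spec()] of kind `cubic_hermite` or `cubic_bspline`.
#' @return Kernel values.
#' @examples
#' cubic_kernel(c(0, 0.5, 1))   # 1, 0.5, 0
#' @export
cubic_kernel <- function(x, spec = kernel_spec("cubic_hermite")) {
  kernel_eval(spec, x)
}

#' Partial-volume neighbor weights
#'
#' For a transformed point falling at fractional offsets `(d_x, d_y[, d_z])`
#' within its reference-grid cell, the bilinear (2-D) or trilinear (3-D)
#' weights over the `2^D` surrounding lattice neighbors:
#' `w1 = (1-d_x)(1-d_y)`, `w2 = d_x(1-d_y)`, `w3 = d_x d_y`,
#' `w4 = (1-d_x) d_y` in 2-D (neighbor offsets (0,0), (1,0), (1,1), (0,1)).
#' The weights always sum to 1.
#'
#' @param d numeric vector of 2 or 3 fractional offsets, each in `[0, 1)`.
#' @return Object of class `npv_weights` with `weights` (length `2^D`),
#'   `offsets` (`2^D x D` 0/1 matrix, row i the neighbor of weight i) and
#'   `d`.
#' @examples
#' pv_weights(c(0.3, 0.2))$weights   # 0.56 0.24 0.06 0.14
#' @export
pv_weights <- function(d) {
  d <- as.numeric(d)
  nd <- length(d)
  if (!(nd %in% c(2L, 3L))) stop_npv("offsets must have 2 or 3 components")
  if (any(d < 0 | d >= 1)) stop_npv("fractional offsets must lie in [0, 1)")
  offsets <- if (nd == 2L)
    matrix(c(0L, 0L, 1L, 0L, 1L, 1L, 0L, 1L), ncol = 2L, byrow = TRUE)
  else
    as.matrix(expand.grid(0:1, 0:1, 0:1, KEEP.OUT.ATTRS = FALSE))
  dimnames(offsets) <- NULL
  w <- apply(offsets, 1L, function(o) prod(ifelse(o == 1L, d, 1 - d)))
  structure(list(weights = as.numeric(w), offsets = offsets, d = d),
            class = "npv_weights")
}
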