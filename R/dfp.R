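#' DFP optimizer configuration
#'
#' Parameters of the Davidon-Fletcher-Powell quasi-Newton scheme with
#' Armijo backtracking used to minimize the negated similarity objective.
#'
#' @param delta backtracking ratio in (0, 1); the step tried at
#'   backtracking level m is `delta^m`.
#' @param sigma Armijo slope factor in (0, 0.5).
#' @param eps gradient-norm stopping tolerance (>= 0).
#' @param max_iter iteration cap.
#' @param H0 initial inverse-Hessian approximation: a symmetric positive
#'   definite matrix, a positive scalar (times identity), or `NULL` for the
#'   identity.
#' @param fd_step finite-difference step per parameter (scalar or vector)
#'   for the fallback central-difference gradient.
#' @param max_m backtracking cap (largest m tried).
#' @return Object of class `dfp_config`.
#' @export
dfp_config <- function(delta = 0.5, sigma = 0.1, eps = 1e-5, max_iter = 200,
                       H0 = NULL, fd_step = 1e-4, max_m = 30) {
  if (delta <= 0 || delta >= 1) stop_npv("delta must lie in (0, 1)")
  if (sigma <= 0 || sigma >= 0.5) stop_npv("sigma must lie in (0, 0.5)")
  if (eps < 0) stop_npv("eps must be >= 0")
  if (!is.null(H0) && is.matrix(H0)) {
    if (max(abs(H0 - t(H0))) > 1e-10) stop_npv("H0 must be symmetric")
    if (min(eigen(H0, symmetric = TRUE, only.values = TRUE)$values) <= 0)
      stop_npv("H0 must be positive definite")
  }
  structure(list(delta = delta, sigma = sigma, eps = eps,
                 max_iter = as.integer(max_iter), H0 = H0,
                 fd_step = fd_step, max_m = as.integer(max_m)),
            class = "dfp_config")
}

#' Central finite-difference gradient
#'
#' `g_i = (f(x + h_i e_i) - f(x - h_i e_i)) / (2 h_i)`.
#'
#' @param objective function of a numeric vector returning a finite scalar.
#' @param x evaluation point.
#' @param step positive step(s), recycled over coordinates.
#' @return Gradient vector.
#' @examples
#' finite_diff_gradient(function(x) x[1]^2, 3, 1e-4)   # ~6
#' @export
finite_diff_gradient <- function(objective, x, step) {
  step <- rep_len(as.numeric(step), length(x))
  if (any(step <= 0)) stop_npv("finite-difference step must be positive")
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- step[i]
    fp <- objective(x + e); fm <- objective(x - e)
    if (!is.finite(fp) || !is.finite(fm))
      stop_npv("non-finite objective value while differencing coordinate %d", i)
    (fp - fm) / (2 * step[i])
  }, numeric(1))
}

#' Armijo backtracking line search
#'
#' Finds the smallest nonnegative integer m (up to `max_m`) with
#' `f(x + delta^m d) <= f(x) + sigma * delta^m * t(g) %*% d`, and returns
#' the accepted step `alpha = delta^m`.
#'
#' @param objective scalar objective.
#' @param x current iterate.
#' @param d search direction; must be a descent direction (`t(g) %*% d < 0`).
#' @param g gradient at `x`.
#' @param delta,sigma,max_m as in [dfp_config()].
#' @param f0 optional precomputed `objective(x)`.
#' @return List with `success`, `m`, `alpha`, `value` (objective at the
#'   accepted point). `success = FALSE` when no m up to `max_m` satisfies
#'   the inequality.
#' @export
armijo_step <- function(objective, x, d, g, delta = 0.5, sigma = 0.1,
                        max_m = 30, f0 = NULL) {
  gd <- sum(g * d)
  if (gd >= 0) stop_npv("Armijo search requires a descent direction (t(g) d < 0)")
  if (is.null(f0)) f0 <- objective(x)
  for (m in 0:max_m) {
    alpha <- delta^m
    fn <- objective(x + alpha * d)
    if (is.finite(fn) && fn <= f0 + sigma * alpha * gd)
      return(list(success = TRUE, m = m, alpha = alpha, value = fn))
  }
  list(success = FALSE, m = NA_integer_, alpha = NA_real_, value = f0)
}

#' DFP inverse-Hessian update
#'
#' The rank-two update
#' `H' = H - (H y t(y) H) / (t(y) H y) + (s t(s)) / (t(s) y)` applied when
#' the curvature condition `t(s) y > 0` holds; otherwise H is returned
#' unchanged (the skip branch). Symmetry is preserved exactly, and positive
#' definiteness is preserved under accepted curvature.
#'
#' @param H current symmetric inverse-Hessian approximation.
#' @param s iterate difference `x_{k+1} - x_k`.
#' @param y gradient difference `g_{k+1} - g_k`.
#' @return Updated matrix.
#' @export
dfp_update <- function(H, s, y) {
  s <- as.numeric(s); y <- as.numeric(y)
  if (length(s) != length(y) || nrow(H) != length(s))
    stop_npv("dimension mismatch in DFP update")
  sy <- sum(s * y)
  if (sy <= 0) return(H)
  Hy <- as.numeric(H %*% y)
  yHy <- sum(y * Hy)
  if (yHy <= 0)
    stop_npv("degenerate curvature in DFP update (t(y) H y = %g)", yHy)
  Hn <- H - tcrossprod(Hy) / yHy + tcrossprod(s) / sy
  (Hn + t(Hn)) / 2
}

#' DFP quasi-Newton minimization
#'
#' Iterates: gradient, stop test on `||g|| <= eps`, direction `d = -H g`,
#' Armijo backtracking for the step `alpha = delta^m`, iterate update,
#' `s = x_{k+1} - x_k`, `y = g_{k+1} - g_k`, inverse-Hessian update
#' ([dfp_update()]), repeat. Terminates on the gradient test, the iteration
#' cap, or line-search failure, always returning the best iterate seen. If
#' an update ever yields a non-descent direction, H is reset to its initial
#' scaling (a safeguard for non-quadratic objectives).
#'
#' @param objective scalar function to minimize; finite at `x0`.
#' @param gradient gradient function, or `NULL` to use central finite
#'   differences with `config$fd_step`.
#' @param x0 starting point.
#' @param config a [dfp_config()].
#' @param track_hessian if `TRUE`, also return `H_trace`, the list of
#'   inverse-Hessian approximations after each update (diagnostics).
#' @return List with `par` (best iterate), `value`, `converged` (gradient
#'   test met), `iterations`, `message`, and `trace` — a data.frame with
#'   one row per iteration (`k`, `f`, `grad_norm`, `alpha`, `m`). The
#'   objective trace is nonincreasing.
#' @examples
#' r <- dfp_minimize(function(x) sum((x - c(1, -2))^2), x0 = c(0, 0),
#'                   config = dfp_config())
#' round(r$par, 4)
#' @export
dfp_minimize <- function(objective, gradient = NULL, x0,
                         config = dfp_config(), track_hessian = FALSE) {
  x <- as.numeric(x0)
  n <- length(x)
  grad <- if (is.null(gradient))
    function(z) finite_diff_gradient(objective, z, config$fd_step)
  else gradient
  H0 <- config$H0
  H <- if (is.null(H0)) diag(n)
       else if (is.matrix(H0)) H0
       else diag(n) * as.numeric(H0)
  f <- objective(x)
  if (!is.finite(f)) stop_npv("objective is not finite at the starting point")
  g <- grad(x)
  trace <- vector("list", config$max_iter)
  H_trace <- if (track_hessian) vector("list", config$max_iter)
  best_x <- x; best_f <- f
  converged <- FALSE
  message <- "max_iter reached"
  k <- 0L
  while (k < config$max_iter) {
    gn <- sqrt(sum(g^2))
    if (gn <= config$eps) {
      converged <- TRUE
      message <- "gradient norm below eps"
      break
    }
    d <- as.numeric(-H %*% g)
    if (sum(g * d) >= 0) {          # safeguard: H lost descent property
      H <- if (is.null(H0)) diag(n)
           else if (is.matrix(H0)) H0 else diag(n) * as.numeric(H0)
      d <- as.numeric(-H %*% g)
    }
    ls <- armijo_step(objective, x, d, g, config$delta, config$sigma,
                      config$max_m, f0 = f)
    if (!ls$success) {
      message <- "line search failure"
      break
    }
    xn <- x + ls$alpha * d
    gn2 <- grad(xn)
    H <- dfp_update(H, xn - x, gn2 - g)
    k <- k + 1L
    if (track_hessian) H_trace[[k]] <- H
    trace[[k]] <- data.frame(k = k, f = ls$value, grad_norm = gn,
                             alpha = ls$alpha, m = ls$m)
    x <- xn; f <- ls$value; g <- gn2
    if (f < best_f) { best_f <- f; best_x <- x }
  }
  out <- list(par = best_x, value = best_f, converged = converged,
              iterations = k, message = message,
              trace = if (k > 0) do.call(rbind, trace[seq_len(k)])
                      else data.frame(k = integer(), f = numeric(),
                                      grad_norm = numeric(),
                                      alpha = numeric(), m = integer()))
  if (track_hessian) out$H_trace <- H_trace[seq_len(k)]
  out
}

#' Write an optimizer trace as CSV
#' @param trace the `trace` data.frame from [dfp_minimize()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.table(trace, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}
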