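#' Registration configuration
#'
#' Aggregates the knobs of the two-stage pipeline: histogram interpolation
#' (PV or NPV and its kernel), bin count, per-stage sample strides, the FFD
#' control spacing, DFP settings per stage, and preprocessing options.
#'
#' @param interp `"npv"` (cubic kernel, default) or `"pv"` (linear kernel).
#' @param kernel kernel kind for NPV: `"cubic_bspline"` (default for
#'   registration — non-interpolating, so it suppresses the spurious
#'   similarity extrema that interpolating kernels produce at on-lattice
#'   transforms), `"cubic_hermite"`, or `"linear"` (reproduces pv exactly).
#' @param bins histogram bins B in `[8, 256]`; must divide `levels`.
#' @param stride_affine,stride_ffd sample stride per stage (voxels).
#' @param ffd_spacing FFD control spacing lambda (voxels); must divide the
#'   image extent.
#' @param levels gray levels after preprocessing.
#' @param normalize min-max normalize both images to `levels` first.
#' @param strip_threshold if non-`NULL`, [strip_background()] threshold
#'   applied to both images (with `keep_largest = TRUE`).
#' @param affine_model `"affine"` (full linear, default) or `"rigid"`
#'   (rotation + translation, 2-D only).
#' @param dfp_affine,dfp_ffd [dfp_config()] per stage. Defaults cap
#'   iterations at 60 (affine) and 30 (FFD).
#' @param fd_translation,fd_linear,fd_control finite-difference steps:
#'   voxels for translations and control displacements, dimensionless for
#'   linear matrix entries.
#' @param refine run a second affine DFP pass with quarter-size steps to
#'   sharpen sub-voxel recovery (the fine stage needs no such polish for
#'   voxel-scale field accuracy).
#' @param do_ffd run the non-rigid stage after the affine stage.
#' @param seed echoed into results for provenance.
#' @return Object of class `npv_config`.
#' @export
registration_config <- function(interp = c("npv", "pv"),
                                kernel = "cubic_bspline",
                                bins = 64, stride_affine = 1, stride_ffd = 1,
                                ffd_spacing = 16, levels = 256,
                                normalize = TRUE, strip_threshold = NULL,
                                affine_model = c("affine", "rigid"),
                                dfp_affine = dfp_config(max_iter = 60),
                                dfp_ffd = dfp_config(max_iter = 30),
                                fd_translation = 0.5, fd_linear = 0.01,
                                fd_control = 0.25,
                                refine = TRUE, do_ffd = TRUE, seed = 1L) {
  interp <- match.arg(interp)
  affine_model <- match.arg(affine_model)
  if (bins < 8 || bins > 256) stop_npv("bins must lie in [8, 256]")
  if (any(c(stride_affine, stride_ffd) < 1)) stop_npv("stride must be >= 1")
  spec <- if (interp == "pv") kernel_spec("linear") else kernel_spec(kernel)
  structure(list(interp = interp, spec = spec, bins = as.integer(bins),
                 stride_affine = stride_affine, stride_ffd = stride_ffd,
                 ffd_spacing = ffd_spacing, levels = as.integer(levels),
                 normalize = normalize, strip_threshold = strip_threshold,
                 affine_model = affine_model,
                 dfp_affine = dfp_affine, dfp_ffd = dfp_ffd,
                 fd_translation = fd_translation, fd_linear = fd_linear,
                 fd_control = fd_control, refine = refine, do_ffd = do_ffd,
                 seed = as.integer(seed)),
            class = "npv_config")
}

# Fast NMI from a raw count matrix (no validation; zero mass -> NA).
nmi_counts <- function(counts) {
  m <- sum(counts)
  if (m <= 0) return(NA_real_)
  p <- counts / m
  ent <- function(v) { v <- v[v > 0]; -sum(v * log2(v)) }
  hj <- ent(p)
  if (hj == 0) return(2)
  (ent(rowSums(p)) + ent(colSums(p))) / hj
}

# Negated NMI of the mapped sample locations q given precomputed floating
# bins fb; worst finite value when every sample leaves the reference bounds.
neg_nmi_of_q <- function(q, fb, ref, spec, bins) {
  res <- cpp_accumulate(q, fb, as.numeric(ref$data), as.integer(dim(ref$data)),
                        as.integer(bins), as.integer(ref$levels),
                        match(spec$kind, c("linear", "cubic_hermite",
                                           "cubic_bspline")) - 1L,
                        if (is.null(spec$coefficients)) numeric(4)
                        else as.numeric(spec$coefficients),
                        as.integer(spec$support))
  v <- nmi_counts(res$counts)
  if (is.na(v)) 0 else -v
}

stage_fb <- function(flt, pts, bins) {
  as.integer(bin_index(flt$data[lattice_index(pts, dim(flt$data))],
                       flt$levels, bins))
}

# Stage driver: DFP in the scaled parameter space with Shanno-Phua-style
# initial Hessian scaling, restarted with a fresh H after a line-search
# failure for as long as the objective still improves (the similarity
# surface is only piecewise smooth, so a stale inverse Hessian can stall
# the line search far from a stationary point).
stage_dfp <- function(objective, z0, cfg, restarts = 4) {
  cfg$fd_step <- 1
  run1 <- function(z) {
    g0 <- finite_diff_gradient(objective, z, 1)
    cfg$H0 <- min(1 / max(sqrt(sum(g0^2)), 1e-8), 100)
    dfp_minimize(objective, gradient = NULL, x0 = z, config = cfg)
  }
  opt <- run1(z0)
  budget <- cfg$max_iter - opt$iterations
  while (restarts > 0 && budget > 0 && !opt$converged &&
         opt$message == "line search failure") {
    cfg$max_iter <- budget
    nxt <- run1(opt$par)
    budget <- budget - max(nxt$iterations, 1L)
    restarts <- restarts - 1
    if (nxt$value >= opt$value - 1e-9) break
    nxt$trace <- rbind(opt$trace, nxt$trace)
    opt <- nxt
  }
  opt
}

#' Affine coarse registration
#'
#' Optimizes an affine transform (floating frame to reference frame) by DFP
#' on negated NMI with the configured histogram interpolation. The
#' translation is initialized from the intensity-centroid difference; the
#' linear block is parameterized about the floating centroid. Parameters
#' are optimized in units of their finite-difference steps (0.5 voxel for
#' translations, 0.01 for linear entries by default).
#'
#' @param ref,flt preprocessed images of identical shape and gray levels.
#' @param config a [registration_config()].
#' @return List with `affine` (the estimate), `nmi_before`, `nmi_after`
#'   (on the stage sample set), `opt` (DFP result incl. trace),
#'   `converged`.
#' @export
register_affine <- function(ref, flt, config = registration_config()) {
  ref <- as_npv_image(ref); flt <- as_npv_image(flt)
  if (length(unique(as.vector(ref$data))) < 2 ||
      length(unique(as.vector(flt$data))) < 2)
    stop_npv("constant image cannot be registered (degenerate input)")
  nd <- img_ndim(ref)
  samples <- sample_grid(flt, config$stride_affine)
  pts <- samples$points
  fb <- stage_fb(flt, pts, config$bins)
  cen <- intensity_centroid(flt)
  t0 <- intensity_centroid(ref) - cen
  rigid <- config$affine_model == "rigid" && nd == 2L
  nlin <- if (rigid) 1L else nd * nd
  scale <- c(rep(if (rigid) 0.5 else config$fd_linear, nlin),
             rep(config$fd_translation, nd))
  build <- function(z) {
    x <- z * scale
    L <- if (rigid) {
      th <- x[1] * pi / 180
      matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2, byrow = TRUE)
    } else diag(nd) + matrix(x[seq_len(nlin)], nd, nd, byrow = TRUE)
    t <- t0 + x[nlin + seq_len(nd)]
    affine_params(linear = L,
                  translation = as.numeric(cen - L %*% cen + t))
  }
  objective <- function(z) {
    tr <- try(build(z), silent = TRUE)
    if (inherits(tr, "try-error")) return(0)   # singular linear block
    neg_nmi_of_q(affine_apply(tr, pts), fb, ref, config$spec, config$bins)
  }
  z0 <- numeric(nlin + nd)
  f_before <- objective(z0)
  opt <- stage_dfp(objective, z0, config$dfp_affine)
  if (config$refine) {
    scale <- scale / 4
    opt2 <- stage_dfp(objective, opt$par * 4, config$dfp_affine)
    if (opt2$value < opt$value) {
      opt2$trace <- rbind(opt$trace, opt2$trace)
      opt <- opt2
    } else scale <- scale * 4
  }
  list(affine = build(opt$par), nmi_before = -f_before,
       nmi_after = -opt$value, opt = opt, converged = opt$converged)
}

#' Non-rigid (FFD) fine registration
#'
#' Optimizes the control-point displacements of a cubic B-spline free-form
#' deformation, composed with a fixed affine initialization
#' (`T(p) = A(p) + disp(p)`), by DFP on negated NMI. Control displacements
#' are optimized in units of the 0.25-voxel finite-difference step.
#'
#' @param ref,flt preprocessed images.
#' @param init_affine affine stage output (or `NULL` for identity).
#' @param config a [registration_config()].
#' @return List with `ffd` (the estimated lattice), `affine` (echoed),
#'   `nmi_before`, `nmi_after`, `opt`, `converged`.
#' @export
register_ffd <- function(ref, flt, init_affine = NULL,
                         config = registration_config()) {
  ref <- as_npv_image(ref); flt <- as_npv_image(flt)
  nd <- img_ndim(ref)
  grid <- make_ffd_grid(dim(ref$data), config$ffd_spacing)
  samples <- sample_grid(flt, config$stride_ffd)
  pts <- samples$points
  fb <- stage_fb(flt, pts, config$bins)
  plan <- ffd_plan(grid, pts)
  qa <- if (is.null(init_affine)) pts else affine_apply(init_affine, pts)
  phidim <- dim(grid$phi)
  scale <- config$fd_control
  objective <- function(z) {
    disp <- ffd_disp_from_plan(plan, array(z * scale, dim = phidim))
    neg_nmi_of_q(qa + disp, fb, ref, config$spec, config$bins)
  }
  z0 <- numeric(length(grid$phi))
  f_before <- objective(z0)
  opt <- stage_dfp(objective, z0, config$dfp_ffd)
  grid$phi <- array(opt$par * scale, dim = phidim)
  list(ffd = grid, affine = init_affine, nmi_before = -f_before,
       nmi_after = -opt$value, opt = opt, converged = opt$converged)
}

#' End-to-end two-stage registration
#'
#' Preprocess (optional gray normalization and background stripping), then
#' affine coarse registration, then FFD fine registration, then a final
#' similarity report. All similarity reports are computed on the fine-stage
#' sample set so NMI is comparable across stages; the better of the affine
#' estimate and the identity initializes the fine stage, so reported NMI
#' never decreases across stages. Fully deterministic given the config.
#'
#' @param ref reference image (fixed frame).
#' @param flt floating image (to be aligned).
#' @param config a [registration_config()].
#' @return Object of class `npv_result`: preprocessed `ref`/`flt`, `affine`
#'   and `ffd` estimates, `transform` (their composition), similarity
#'   reports `report_initial`, `report_affine`, `report_final`, `converged`
#'   flags, optimizer `traces`, and the echoed `config`.
#' @export
register <- function(ref, flt, config = registration_config()) {
  ref <- as_npv_image(ref); flt <- as_npv_image(flt)
  if (!identical(dim(ref$data), dim(flt$data)))
    stop_npv("reference and floating images must have identical shape")
  if (!is.null(config$strip_threshold)) {
    ref <- strip_background(ref, config$strip_threshold, keep_largest = TRUE)
    flt <- strip_background(flt, config$strip_threshold, keep_largest = TRUE)
  }
  if (config$normalize) {
    ref <- normalize_gray(ref, config$levels)
    flt <- normalize_gray(flt, config$levels)
  }
  rsamp <- sample_grid(flt, config$stride_ffd)
  report <- function(transform)
    similarity_report(ref, flt, transform, rsamp, config$spec, config$bins)
  rep0 <- report(NULL)
  aff <- register_affine(ref, flt, config)
  rep_aff <- report(aff$affine)
  # keep the identity if the affine stage did not improve on the report set
  if (rep_aff$NMI < rep0$NMI) {
    aff$affine <- affine_params(ndim = img_ndim(ref))
    rep_aff <- report(aff$affine)
  }
  if (config$do_ffd) {
    fine <- register_ffd(ref, flt, aff$affine, config)
    transform <- compose_transform(aff$affine, fine$ffd)
    rep_fin <- report(transform)
    traces <- list(affine = aff$opt$trace, ffd = fine$opt$trace)
    conv <- c(affine = aff$converged, ffd = fine$converged)
    ffd_est <- fine$ffd
  } else {
    transform <- compose_transform(aff$affine, NULL)
    rep_fin <- rep_aff
    traces <- list(affine = aff$opt$trace)
    conv <- c(affine = aff$converged)
    ffd_est <- NULL
  }
  structure(list(ref = ref, flt = flt, affine = aff$affine, ffd = ffd_est,
                 transform = transform, report_initial = rep0,
                 report_affine = rep_aff, report_final = rep_fin,
                 converged = conv, traces = traces, config = config,
                 samples = rsamp),
            class = "npv_result")
}

#' @export
print.npv_result <- function(x, ...) {
  cat(sprintf(paste0("<npv_result> %s interpolation | NMI: initial %.4f -> ",
                     "affine %.4f -> final %.4f\n"),
              x$config$interp, x$report_initial$NMI, x$report_affine$NMI,
              x$report_final$NMI))
  invisible(x)
}

#' Resample the floating image into the reference frame
#'
#' Inverts the estimated transform (exactly for affine, by fixed-point
#' iteration on the displacement for FFD compositions) and backward-warps
#' the floating image so it overlays the reference.
#'
#' @param result an [register()] result, or a transform plus explicit
#'   images via `flt`.
#' @param flt floating image (defaults to `result$flt`).
#' @param iterations fixed-point iterations for non-affine inversion.
#' @return The aligned floating [npv_image()] in the reference frame.
#' @export
aligned_floating <- function(result, flt = NULL, iterations = 12) {
  transform <- if (inherits(result, "npv_result")) result$transform else result
  if (is.null(flt)) flt <- result$flt
  flt <- as_npv_image(flt)
  if (inherits(transform, "npv_affine"))
    return(warp_image(flt, affine_invert(transform), "linear"))
  if (inherits(transform, "npv_composed") && is.null(transform$ffd))
    return(warp_image(flt, affine_invert(transform$affine), "linear"))
  dims <- dim(flt$data)
  x <- sample_grid(dims, 1L)$points
  p <- x
  for (it in seq_len(iterations))
    p <- x - (transform_points(transform, p) - p)
  vals <- interp_image(flt$data, p, "linear")
  out <- array(pmin(pmax(vals, 0), flt$levels - 1), dims)
  npv_image(out, flt$spacing, flt$levels)
}

#' False-color fusion overlay
#'
#' Overlays the reference (green channel) and the aligned floating image
#' (magenta: red + blue), each min-max scaled, so aligned structures look
#' gray and misaligned ones show complementary fringes — a quick visual
#' check convenient for reading the registration result.
#'
#' @param ref 2-D reference image.
#' @param warped_flt 2-D aligned floating image of the same shape.
#' @param path optional PNG output path.
#' @return 8-bit integer array of dimension `(nx, ny, 3)` (invisible when
#'   written to `path`).
#' @export
fuse_falsecolor <- function(ref, warped_flt, path = NULL) {
  ref <- as_npv_image(ref); warped_flt <- as_npv_image(warped_flt)
  if (!identical(dim(ref$data), dim(warped_flt$data)))
    stop_npv("images must have identical shape for fusion")
  if (img_ndim(ref) != 2L) stop_npv("false-color fusion is 2-D only")
  sc <- function(v) {
    r <- range(v)
    if (r[1] == r[2]) array(0, dim(v)) else (v - r[1]) / (r[2] - r[1])
  }
  g <- sc(ref$data); m <- sc(warped_flt$data)
  rgb <- array(0L, c(dim(ref$data), 3L))
  rgb[, , 1] <- as.integer(round(m * 255))
  rgb[, , 2] <- as.integer(round(g * 255))
  rgb[, , 3] <- as.integer(round(m * 255))
  if (!is.null(path)) {
    png::writePNG(aperm(rgb, c(2L, 1L, 3L)) / 255, path)
    return(invisible(rgb))
  }
  rgb
}

#' Compare a registration result against phantom ground truth
#'
#' @param result an [register()] result (or a list with `affine`/`ffd`).
#' @param case the [make_registration_case()] the result was computed on.
#' @return List of metrics: `translation_error` (voxels, affine cases),
#'   `rotation_error_deg` (2-D rigid/affine cases), `mean_field_error` and
#'   `max_field_error` (voxels, over the reference foreground),
#'   `nmi_initial`, `nmi_final`.
#' @export
evaluate_case <- function(result, case) {
  if (is.null(case$true_transform)) stop_npv("case carries no ground truth")
  est <- if (inherits(result, "npv_result")) result$transform
         else compose_transform(result$affine, result$ffd)
  true <- case$true_transform
  fg <- which(case$reference$data > 0, arr.ind = TRUE) - 1L
  qe <- transform_points(est, fg)
  qt <- transform_points(true, fg)
  err <- sqrt(rowSums((qe - qt)^2))
  out <- list(mean_field_error = mean(err), max_field_error = max(err))
  est_aff <- if (inherits(est, "npv_composed")) est$affine else
             if (inherits(est, "npv_affine")) est else NULL
  if (inherits(true, "npv_affine") && !is.null(est_aff)) {
    # net translation = mean displacement over the foreground; robust to
    # the scale/translation decomposition ambiguity of a full affine fit
    out$translation_error <- sqrt(sum((colMeans(qe - fg) -
                                       colMeans(qt - fg))^2))
    if (true$ndim == 2L) {
      ang <- function(p) atan2(p$matrix[2, 1], p$matrix[1, 1]) * 180 / pi
      out$rotation_error_deg <- abs(ang(est_aff) - ang(true))
    }
  }
  if (inherits(result, "npv_result")) {
    out$nmi_initial <- result$report_initial$NMI
    out$nmi_final <- result$report_final$NMI
  }
  out
}
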