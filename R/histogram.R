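#' Joint gray-level histogram
#'
#' A `B x B` nonnegative accumulation matrix over (reference-bin,
#' floating-bin) pairs. Each accumulated sample distributes exactly unit
#' mass over the matrix (guaranteed by the kernel partition of unity), so
#' the total mass equals the number of in-bounds samples.
#'
#' @param bins number of bins B per axis; must divide the gray range evenly
#'   (`levels %% bins == 0`).
#' @param levels gray levels of the images to be accumulated.
#' @return Object of class `npv_hist` with fields `counts` (`B x B` matrix,
#'   rows = reference bins), `bins`, `levels`, `n_samples`, `n_skipped`.
#' @export
joint_histogram <- function(bins = 64, levels = 256) {
  bins <- as.integer(bins)
  if (bins < 2) stop_npv("need at least 2 bins")
  if (levels %% bins != 0)
    stop_npv("bins (%d) must divide the gray levels (%d) evenly", bins, levels)
  structure(list(counts = matrix(0, bins, bins), bins = bins,
                 levels = as.integer(levels),
                 n_samples = 0L, n_skipped = 0L),
            class = "npv_hist")
}

#' @export
print.npv_hist <- function(x, ...) {
  cat(sprintf("<npv_hist> %dx%d bins, mass %.6g (%d samples, %d skipped)\n",
              x$bins, x$bins, sum(x$counts), x$n_samples, x$n_skipped))
  invisible(x)
}

hist_mass <- function(hist) sum(hist$counts)

# 1-based bin index of gray values
bin_index <- function(v, levels, bins) {
  pmin(floor(v * bins / levels), bins - 1L) + 1L
}

# Shared accumulation engine. Samples are floating-frame lattice points;
# `transform` maps them into the reference frame. For each sample p with
# q = T(p), every reference-lattice neighbor n of q within the kernel
# support receives weight prod_axes f(offset_axis - frac_axis) in histogram
# cell [bin(ref at n), bin(flt at p)]. Samples whose full neighborhood
# leaves the reference bounds are skipped and counted.
accumulate_engine <- function(hist, ref, flt, transform, samples, spec) {
  ref <- as_npv_image(ref); flt <- as_npv_image(flt)
  if (!identical(dim(ref$data), dim(flt$data)))
    stop_npv("reference and floating images must have identical shape")
  if (ref$levels != hist$levels || flt$levels != hist$levels)
    stop_npv("image gray levels (%d/%d) do not match histogram levels (%d)",
             ref$levels, flt$levels, hist$levels)
  pts <- samples$points
  if (is.null(pts) || nrow(pts) == 0L) stop_npv("empty sample set")
  q <- transform_points(transform, pts)
  res <- accumulate_counts(q, pts, ref$data, flt$data, spec,
                           hist$bins, hist$levels)
  hist$counts <- hist$counts + res$counts
  hist$n_samples <- hist$n_samples + res$n_used
  hist$n_skipped <- hist$n_skipped + res$n_skipped
  hist
}

# Vectorized core: q = transformed sample locations (n x D), pts = integer
# sample coordinates in the floating frame. The per-sample neighbor loop
# runs in compiled code (src/accumulate.cpp).
accumulate_counts <- function(q, pts, ref_data, flt_data, spec, bins, levels) {
  dims <- dim(ref_data)
  fb <- bin_index(flt_data[lattice_index(pts, dims)], levels, bins)
  kind <- match(spec$kind, c("linear", "cubic_hermite", "cubic_bspline")) - 1L
  coef <- if (is.null(spec$coefficients)) numeric(4) else
    as.numeric(spec$coefficients)
  res <- cpp_accumulate(q, as.integer(fb), as.numeric(ref_data),
                        as.integer(dims), as.integer(bins),
                        as.integer(levels), kind, coef,
                        as.integer(spec$support))
  list(counts = res$counts, n_used = res$n_used,
       n_skipped = nrow(q) - res$n_used)
}

#' Accumulate a joint histogram by classical PV interpolation
#'
#' For each floating-frame sample p, the transformed location q = T(p) lies
#' between reference lattice points; the sample's unit mass is split over
#' the 4 (2-D) or 8 (3-D) neighbors with linear-kernel weights and added to
#' the cells pairing each neighbor's reference bin with the floating bin of
#' p. No intensity is ever interpolated — only histogram mass.
#'
#' @param hist a [joint_histogram()].
#' @param ref,flt reference and floating images of identical shape and gray
#'   levels.
#' @param transform transform mapping floating-frame points into the
#'   reference frame ([affine_params()], [make_ffd_grid()] result, a
#'   composition from [compose_transform()], a function of an `n x D`
#'   matrix, or `NULL` for identity).
#' @param samples a [sample_grid()] sample set over the floating lattice.
#' @return Updated histogram.
#' @export
pv_accumulate <- function(hist, ref, flt, transform = NULL, samples) {
  accumulate_engine(hist, ref, flt, transform, samples, kernel_spec("linear"))
}

#' Accumulate a joint histogram by cubic-kernel (NPV) interpolation
#'
#' Identical accumulation geometry to [pv_accumulate()] but with separable
#' per-axis cubic kernel weights over the neighbor offsets within the kernel
#' support. With the linear kernel this reproduces PV exactly; with the
#' default cubic Hermite kernel the histogram — and hence the mutual
#' information surface — varies more smoothly with sub-voxel motion.
#'
#' @inheritParams pv_accumulate
#' @param spec a [kernel_spec()].
#' @return Updated histogram.
#' @export
npv_accumulate <- function(hist, ref, flt, transform = NULL, samples,
                           spec = kernel_spec("cubic_hermite")) {
  accumulate_engine(hist, ref, flt, transform, samples, spec)
}

#' Normalize a histogram to a joint probability matrix
#'
#' @param hist a [joint_histogram()] with positive mass.
#' @return `B x B` matrix with entries summing to 1.
#' @export
to_probability <- function(hist) {
  m <- hist_mass(hist)
  if (m <= 0) stop_npv("histogram has zero mass")
  hist$counts / m
}

#' Export a joint histogram as TSV
#'
#' Writes the count matrix with a header row and first column of bin
#' centers (gray values).
#'
#' @param hist a [joint_histogram()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_histogram_tsv <- function(hist, path) {
  centers <- (seq_len(hist$bins) - 0.5) * hist$levels / hist$bins
  tab <- cbind(ref_bin_center = centers, hist$counts)
  colnames(tab) <- c("ref_bin_center", format(centers, trim = TRUE))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
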