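#' Shannon entropy of a probability distribution
#'
#' `H = -sum(p_i log2 p_i)` in bits, with the limit convention
#' `0 * log 0 = 0`.
#'
#' @param p numeric vector (or matrix) of probabilities: entries nonnegative
#'   and summing to 1 within 1e-9.
#' @return Entropy in bits.
#' @examples
#' shannon_entropy(c(0.5, 0.5))           # 1 bit
#' shannon_entropy(rep(0.25, 4))          # 2 bits
#' @export
shannon_entropy <- function(p) {
  p <- as.numeric(p)
  if (any(p < 0)) stop_npv("probabilities must be nonnegative")
  if (abs(sum(p) - 1) > 1e-9)
    stop_npv("probabilities must sum to 1 (got %.12g)", sum(p))
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Marginal entropies of a joint histogram
#'
#' Entropies of the reference (row-sum) and floating (column-sum) gray
#' distributions, in bits.
#'
#' @param hist a [joint_histogram()] with positive mass.
#' @return Named numeric vector `c(H_R, H_F)`.
#' @export
marginal_entropies <- function(hist) {
  p <- to_probability(hist)
  c(H_R = shannon_entropy(rowSums(p)), H_F = shannon_entropy(colSums(p)))
}

#' Joint entropy of a joint histogram
#'
#' `H(R, F) = -sum p_RF(r, f) log2 p_RF(r, f)` in bits.
#'
#' @inheritParams marginal_entropies
#' @return Joint entropy in bits.
#' @export
joint_entropy <- function(hist) shannon_entropy(to_probability(hist))

#' Mutual information of a joint histogram
#'
#' `MI = H(R) + H(F) - H(R, F)` in bits.
#'
#' @inheritParams marginal_entropies
#' @return Mutual information in bits.
#' @export
mutual_information <- function(hist) {
  m <- marginal_entropies(hist)
  unname(m[1] + m[2] - joint_entropy(hist))
}

#' Normalized mutual information
#'
#' The registration objective `NMI = (H(R) + H(F)) / H(R, F)`, ranging from
#' 1 (independent gray distributions) to 2 (perfect one-to-one dependence).
#' A single-cell histogram (all entropies zero) returns 2 by continuity.
#' NMI is invariant to the logarithm base.
#'
#' @inheritParams marginal_entropies
#' @return Dimensionless NMI in `[1, 2]`.
#' @export
nmi <- function(hist) {
  m <- marginal_entropies(hist)
  hj <- joint_entropy(hist)
  if (hj == 0) return(2)
  unname((m[1] + m[2]) / hj)
}

#' Full similarity report for an image pair under a transform
#'
#' Accumulates a joint histogram of `(ref, flt)` under `transform` and
#' reports marginal entropies, joint entropy, mutual information and NMI.
#'
#' @param ref,flt images of identical shape and gray levels.
#' @param transform transform mapping floating-frame points into the
#'   reference frame (`NULL` = identity).
#' @param samples sample set (default: full lattice).
#' @param spec [kernel_spec()] controlling PV (`"linear"`) vs NPV
#'   accumulation.
#' @param bins histogram bins.
#' @param hist optionally, a pre-accumulated [joint_histogram()]; all other
#'   arguments are then ignored.
#' @return Object of class `npv_similarity` with fields `H_R`, `H_F`,
#'   `H_RF`, `MI`, `NMI` (entropies in bits).
#' @export
similarity_report <- function(ref = NULL, flt = NULL, transform = NULL,
                              samples = NULL, spec = kernel_spec(),
                              bins = 64, hist = NULL) {
  if (is.null(hist)) {
    ref <- as_npv_image(ref); flt <- as_npv_image(flt)
    if (is.null(samples)) samples <- sample_grid(ref, 1L)
    hist <- npv_accumulate(joint_histogram(bins, ref$levels), ref, flt,
                           transform, samples, spec)
  }
  m <- marginal_entropies(hist)
  hj <- joint_entropy(hist)
  structure(list(H_R = unname(m[1]), H_F = unname(m[2]), H_RF = hj,
                 MI = unname(m[1] + m[2] - hj),
                 NMI = if (hj == 0) 2 else unname((m[1] + m[2]) / hj)),
            class = "npv_similarity")
}

#' @export
print.npv_similarity <- function(x, ...) {
  cat(sprintf("<npv_similarity> H_R=%.4f H_F=%.4f H_RF=%.4f MI=%.4f NMI=%.4f\n",
              x$H_R, x$H_F, x$H_RF, x$MI, x$NMI))
  invisible(x)
}

#' @export
format.npv_similarity <- function(x, ...) {
  jsonlite::toJSON(unclass(x), auto_unbox = TRUE, digits = NA)
}
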