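# Independent brute-force oracles used to cross-check the vectorized /
# compiled implementations. Written as plain per-sample loops straight from
# the accumulation definitions; they must stay independent of the package's
# fast paths.

# Joint-histogram accumulation oracle: explicit loops over samples and
# neighbor offsets (offset loops nested x-outer, matching the definition of
# one contribution per neighbor; addition order within a cell mirrors the
# engine so comparisons can be exact).
oracle_accumulate <- function(ref, flt, transform, samples, spec, bins = 64) {
  counts <- matrix(0, bins, bins)
  dims <- dim(ref$data)
  nd <- length(dims)
  s <- spec$support
  offs <- seq.int(1L - s, s)
  binf <- function(v) min(floor(v * bins / ref$levels), bins - 1) + 1
  n_used <- 0L
  for (i in seq_len(nrow(samples$points))) {
    p <- samples$points[i, ]
    q <- as.numeric(transform_points(transform, matrix(p, 1)))
    base <- floor(q)
    d <- q - base
    # a sample is usable when every nonzero-weight neighbor lies inside
    ok <- TRUE
    for (a in seq_len(nd)) {
      wts <- vapply(offs, function(m) kernel_eval(spec, m - d[a]), numeric(1))
      nz <- offs[wts != 0]
      if (length(nz) == 0 || base[a] + min(nz) < 0 ||
          base[a] + max(nz) > dims[a] - 1) { ok <- FALSE; break }
    }
    if (!ok) next
    n_used <- n_used + 1L
    fbin <- binf(flt$data[matrix(p + 1, 1)])
    if (nd == 2L) {
      for (ox in offs) for (oy in offs) {
        w <- kernel_eval(spec, ox - d[1]) * kernel_eval(spec, oy - d[2])
        if (w == 0) next
        rbin <- binf(ref$data[base[1] + ox + 1, base[2] + oy + 1])
        counts[rbin, fbin] <- counts[rbin, fbin] + w
      }
    } else {
      for (ox in offs) for (oy in offs) for (oz in offs) {
        w <- kernel_eval(spec, ox - d[1]) * kernel_eval(spec, oy - d[2]) *
             kernel_eval(spec, oz - d[3])
        if (w == 0) next
        rbin <- binf(ref$data[base[1] + ox + 1, base[2] + oy + 1,
                              base[3] + oz + 1])
        counts[rbin, fbin] <- counts[rbin, fbin] + w
      }
    }
  }
  list(counts = counts, n_used = n_used)
}

# FFD oracle: direct 16/64-term tensor-product sum from the basis formulas.
oracle_ffd_apply <- function(grid, pt) {
  nd <- grid$ndim
  lam <- grid$spacing
  tt <- pt / lam
  i <- floor(tt) - 1
  u <- tt - floor(tt)
  B <- function(l, u) switch(l + 1L,
    (1 - u)^3 / 6,
    (3 * u^3 - 6 * u^2 + 4) / 6,
    (-3 * u^3 + 3 * u^2 + 3 * u + 1) / 6,
    u^3 / 6)
  disp <- numeric(nd)
  if (nd == 2L) {
    for (l in 0:3) for (m in 0:3)
      disp <- disp + B(l, u[1]) * B(m, u[2]) *
        grid$phi[i[1] + l + 2, i[2] + m + 2, ]
  } else {
    for (l in 0:3) for (m in 0:3) for (n in 0:3)
      disp <- disp + B(l, u[1]) * B(m, u[2]) * B(n, u[3]) *
        grid$phi[i[1] + l + 2, i[2] + m + 2, i[3] + n + 2, ]
  }
  pt + disp
}

# Small seeded random image of integer gray values
random_image <- function(dims, seed, levels = 256) {
  set.seed(seed)
  npv_image(array(sample.int(levels, prod(dims), replace = TRUE) - 1L,
                  dim = dims), levels = levels)
}

# Histogram built directly from a count matrix (test fixture shortcut)
hist_from_counts <- function(counts, levels = 256) {
  h <- joint_histogram(nrow(counts), levels)
  h$counts <- counts
  h$n_samples <- sum(counts)
  h
}
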