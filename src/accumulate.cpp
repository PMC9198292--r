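#include <Rcpp.h>
using namespace Rcpp;

// Interpolation kernels used by the histogram accumulators. kind:
// 0 = linear (PV), 1 = cubic with coefficients (a,b,c,d) on |x|<1,
// 2 = cubic B-spline (support 2).
static inline double kernel_val(double x, int kind, const double* co) {
  // expression trees kept identical to the R kernel_eval() so both paths
  // agree to the last bit
  double t = std::abs(x);
  double t2 = t * t;
  double t3 = t2 * t;
  switch (kind) {
  case 0:
    return t < 1.0 ? 1.0 - t : 0.0;
  case 1:
    return t < 1.0 ? co[0] * t3 + co[1] * t2 + co[2] * t + co[3] : 0.0;
  default:
    if (t < 1.0) return 2.0 / 3.0 - t2 + t3 / 2.0;
    if (t < 2.0) { double u = 2.0 - t; return (u * u) * u / 6.0; }
    return 0.0;
  }
}

// Joint-histogram accumulation core. q: transformed sample locations
// (n x D, 0-based reference-frame coordinates); fb: 1-based floating-bin
// index per sample; ref: reference image values (column-major, dims);
// support: kernel half-width in voxels. Each in-bounds sample distributes
// its unit mass over the (2*support)^D reference-lattice neighbors with
// separable kernel weights. Returns the B x B count matrix and the number
// of samples used (those whose full neighborhood stays inside the image).
// [[Rcpp::export]]
List cpp_accumulate(NumericMatrix q, IntegerVector fb, NumericVector ref,
                    IntegerVector dims, int bins, int levels,
                    int kind, NumericVector coef, int support) {
  const int n = q.nrow(), nd = q.ncol(), s = support, w = 2 * s;
  NumericMatrix counts(bins, bins);
  const double* co = coef.size() >= 4 ? &coef[0] : nullptr;
  double cdef[4] = {0, 0, 0, 0};
  if (!co) co = cdef;
  int strides[3] = {1, 1, 1};
  for (int a = 1; a < nd; ++a) strides[a] = strides[a - 1] * dims[a - 1];
  int n_used = 0;
  double wt[3][4];
  int base[3];
  for (int i = 0; i < n; ++i) {
    bool ok = true;
    for (int a = 0; a < nd; ++a) {
      double qa = q(i, a);
      double fl = std::floor(qa);
      base[a] = (int)fl;
      double frac = qa - fl;
      for (int m = 0; m < w; ++m)
        wt[a][m] = kernel_val((1 - s + m) - frac, kind, co);
      // only neighbors carrying nonzero weight must lie inside the image
      int mlo = 0, mhi = w - 1;
      while (mlo < w && wt[a][mlo] == 0.0) ++mlo;
      while (mhi >= 0 && wt[a][mhi] == 0.0) --mhi;
      if (mlo > mhi ||
          base[a] + (1 - s + mlo) < 0 ||
          base[a] + (1 - s + mhi) > dims[a] - 1) { ok = false; break; }
    }
    if (!ok) continue;
    ++n_used;
    const int col = (fb[i] - 1) * bins;
    if (nd == 2) {
      for (int mx = 0; mx < w; ++mx) {
        if (wt[0][mx] == 0.0) continue;
        int ix = base[0] + (1 - s + mx);
        for (int my = 0; my < w; ++my) {
          double ww = wt[0][mx] * wt[1][my];
          if (ww == 0.0) continue;
          int iy = base[1] + (1 - s + my);
          double rv = ref[ix + iy * strides[1]];
          int rb = (int)(rv * bins / levels);
          if (rb > bins - 1) rb = bins - 1;
          counts[rb + col] += ww;
        }
      }
    } else {
      for (int mx = 0; mx < w; ++mx) {
        if (wt[0][mx] == 0.0) continue;
        int ix = base[0] + (1 - s + mx);
        for (int my = 0; my < w; ++my) {
          double wxy = wt[0][mx] * wt[1][my];
          if (wxy == 0.0) continue;
          int iy = base[1] + (1 - s + my);
          for (int mz = 0; mz < w; ++mz) {
            double ww = wxy * wt[2][mz];
            if (ww == 0.0) continue;
            int iz = base[2] + (1 - s + mz);
            double rv = ref[ix + iy * strides[1] + iz * strides[2]];
            int rb = (int)(rv * bins / levels);
            if (rb > bins - 1) rb = bins - 1;
            counts[rb + col] += ww;
          }
        }
      }
    }
  }
  return List::create(_["counts"] = counts, _["n_used"] = n_used);
}
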