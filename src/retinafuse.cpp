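#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Flattened tap list for one kernel: only nonzero taps are visited, so the
// rotated anisotropic stencils (mostly zero inside their bounding box) cost
// what their true support costs.
struct TapSet {
  std::vector<int> dr, dc;
  std::vector<double> w;
};

static TapSet flatten_kernel(const NumericMatrix& k) {
  TapSet t;
  int kr = k.nrow(), kc = k.ncol();
  int cr = (kr - 1) / 2, cc = (kc - 1) / 2;
  for (int j = 0; j < kc; ++j)
    for (int i = 0; i < kr; ++i)
      if (k(i, j) != 0.0) {
        t.dr.push_back(i - cr);
        t.dc.push_back(j - cc);
        t.w.push_back(k(i, j));
      }
  return t;
}

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Correlation of img with each kernel in the bank, replicate-padded borders.
// Returns an nr x nc x K array. Kernels must have odd dimensions.
// [[Rcpp::export]]
NumericVector conv_bank_cpp(const NumericMatrix& img, const List& kernels) {
  int nr = img.nrow(), nc = img.ncol(), K = kernels.size();
  NumericVector out(Dimension(nr, nc, K));
  for (int k = 0; k < K; ++k) {
    TapSet t = flatten_kernel(as<NumericMatrix>(kernels[k]));
    size_t nt = t.w.size();
    double* o = &out[(size_t)k * nr * nc];
    for (int c = 0; c < nc; ++c) {
      for (int r = 0; r < nr; ++r) {
        double acc = 0.0;
        for (size_t i = 0; i < nt; ++i) {
          int rr = clampi(r + t.dr[i], 0, nr - 1);
          int cc = clampi(c + t.dc[i], 0, nc - 1);
          acc += t.w[i] * img(rr, cc);
        }
        o[(size_t)c * nr + r] = acc;
      }
    }
  }
  return out;
}

// Correlation where each output pixel uses the kernel indexed (1-based) by
// orient(r, c). Used by the oriented region-scalable fitting evolution: the
// local averaging window follows the per-pixel vessel orientation.
// [[Rcpp::export]]
NumericMatrix conv_select_cpp(const NumericMatrix& img, const List& kernels,
                              const IntegerMatrix& orient) {
  int nr = img.nrow(), nc = img.ncol(), K = kernels.size();
  if (orient.nrow() != nr || orient.ncol() != nc)
    stop("orientation map dimensions do not match the image");
  std::vector<TapSet> taps(K);
  for (int k = 0; k < K; ++k)
    taps[k] = flatten_kernel(as<NumericMatrix>(kernels[k]));
  NumericMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int k = orient(r, c) - 1;
      if (k < 0 || k >= K) stop("orientation index out of range");
      const TapSet& t = taps[k];
      double acc = 0.0;
      size_t nt = t.w.size();
      for (size_t i = 0; i < nt; ++i) {
        int rr = clampi(r + t.dr[i], 0, nr - 1);
        int cc = clampi(c + t.dc[i], 0, nc - 1);
        acc += t.w[i] * img(rr, cc);
      }
      out(r, c) = acc;
    }
  }
  return out;
}

// 8-connected component labeling of a logical mask (stack-based flood fill).
// Labels are 1..n in scan order of the first pixel encountered.
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(const LogicalMatrix& mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<int> stack;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(c * nr + r);
      lab(r, c) = next;
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int cr = idx % nr, cc = idx / nr;
        for (int dc = -1; dc <= 1; ++dc) {
          for (int dr = -1; dr <= 1; ++dr) {
            if (dr == 0 && dc == 0) continue;
            int r2 = cr + dr, c2 = cc + dc;
            if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
            if (mask(r2, c2) && lab(r2, c2) == 0) {
              lab(r2, c2) = next;
              stack.push_back(c2 * nr + r2);
            }
          }
        }
      }
    }
  }
  return lab;
}
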