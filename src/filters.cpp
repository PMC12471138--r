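#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// symmetric (half-sample) reflection: -1 -> 0, -2 -> 1, n -> n-1
static inline int refl(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - 1 - i;
  }
  return i;
}

// Same-size 2-D correlation with reflective border handling. The matched
// filter kernels are symmetric under 180-degree rotation, so correlation and
// convolution coincide for every caller in this package.
// [[Rcpp::export]]
NumericMatrix cpp_conv2_reflect(NumericMatrix img, NumericMatrix kernel) {
  const int nr = img.nrow(), nc = img.ncol();
  const int kr = kernel.nrow(), kc = kernel.ncol();
  const int hr = kr / 2, hc = kc / 2;
  // reflect-pad once, then accumulate one shifted plane per kernel element:
  // sequential column-major access lets the compiler vectorize the inner loop
  const int pr = nr + kr - 1, pc = nc + kc - 1;
  std::vector<double> pad((size_t) pr * pc);
  for (int j = 0; j < pc; ++j) {
    const int cj = refl(j - hc, nc);
    double *col = &pad[(size_t) j * pr];
    for (int i = 0; i < pr; ++i) col[i] = img(refl(i - hr, nr), cj);
  }
  NumericMatrix out(nr, nc);
  double *o = REAL(out);
  for (int kj = 0; kj < kc; ++kj) {
    for (int ki = 0; ki < kr; ++ki) {
      const double kv = kernel(ki, kj);
      if (kv == 0.0) continue;
      for (int j = 0; j < nc; ++j) {
        const double *p = &pad[(size_t)(j + kj) * pr + ki];
        double *oc = o + (size_t) j * nr;
        for (int i = 0; i < nr; ++i) oc[i] += kv * p[i];
      }
    }
  }
  return out;
}

// k x k median filter with reflective padding; k must be odd.
// [[Rcpp::export]]
NumericMatrix cpp_median_filter(NumericMatrix img, int k) {
  const int nr = img.nrow(), nc = img.ncol();
  const int h = k / 2, nwin = k * k;
  NumericMatrix out(nr, nc);
  std::vector<double> win(nwin);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int m = 0;
      for (int kj = -h; kj <= h; ++kj) {
        const int cj = refl(j + kj, nc);
        for (int ki = -h; ki <= h; ++ki) {
          win[m++] = img(refl(i + ki, nr), cj);
        }
      }
      std::nth_element(win.begin(), win.begin() + nwin / 2, win.end());
      out(i, j) = win[nwin / 2];
    }
  }
  return out;
}

// Connected-component labelling of a binary mask (0 background), 4- or
// 8-connectivity, labels 1..L in scan order of first-encountered pixel.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(IntegerMatrix mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<std::pair<int, int> > stack;
  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nnb = (connectivity == 8) ? 8 : 4;
  int next = 0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (mask(i, j) == 0 || lab(i, j) != 0) continue;
      lab(i, j) = ++next;
      stack.clear();
      stack.push_back(std::make_pair(i, j));
      while (!stack.empty()) {
        const std::pair<int, int> p = stack.back();
        stack.pop_back();
        for (int t = 0; t < nnb; ++t) {
          const int ri = p.first + dr8[t], cj = p.second + dc8[t];
          if (ri < 0 || ri >= nr || cj < 0 || cj >= nc) continue;
          if (mask(ri, cj) != 0 && lab(ri, cj) == 0) {
            lab(ri, cj) = next;
            stack.push_back(std::make_pair(ri, cj));
          }
        }
      }
    }
  }
  return lab;
}
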