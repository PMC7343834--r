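#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// mirror index into [0, n-1] (reflection including the edge sample)
static inline int mirror(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

static void blur_axis(std::vector<double> &src, std::vector<double> &dst,
                      int n0, int n1, int n2, int axis,
                      const std::vector<double> &k) {
  int r = (int)(k.size() / 2);
  int n[3] = {n0, n1, n2};
  long s[3] = {1, (long)n0, (long)n0 * n1};
  int na = n[axis];
  long sa = s[axis];
  // iterate over the two non-filter axes
  int b1 = (axis == 0) ? 1 : 0;
  int b2 = (axis == 2) ? 1 : 2;
  for (int j2 = 0; j2 < n[b2]; ++j2) {
    for (int j1 = 0; j1 < n[b1]; ++j1) {
      long base = (long)j1 * s[b1] + (long)j2 * s[b2];
      for (int i = 0; i < na; ++i) {
        double acc = 0.0;
        for (int t = -r; t <= r; ++t) {
          int ii = mirror(i + t, na);
          acc += k[t + r] * src[base + (long)ii * sa];
        }
        dst[base + (long)i * sa] = acc;
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector gaussian_blur3_cpp(NumericVector vol, IntegerVector dim,
                                 double sigma) {
  int n0 = dim[0], n1 = dim[1], n2 = dim[2];
  long n = (long)n0 * n1 * n2;
  if (sigma <= 0) return clone(vol);
  int r = std::max(1, (int)std::ceil(3.5 * sigma));
  std::vector<double> k(2 * r + 1);
  double sum = 0;
  for (int t = -r; t <= r; ++t) {
    k[t + r] = std::exp(-0.5 * (double)t * t / (sigma * sigma));
    sum += k[t + r];
  }
  for (double &v : k) v /= sum;
  std::vector<double> a(vol.begin(), vol.end()), b(n);
  blur_axis(a, b, n0, n1, n2, 0, k);
  blur_axis(b, a, n0, n1, n2, 1, k);
  blur_axis(a, b, n0, n1, n2, 2, k);
  NumericVector out(n);
  std::copy(b.begin(), b.end(), out.begin());
  out.attr("dim") = dim;
  return out;
}
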