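#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Label connected foreground components (6 or 26 connectivity) by
// iterative flood fill; labels assigned in raster-scan discovery order.
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dim,
                                   int connectivity) {
  int n0 = dim[0], n1 = dim[1], n2 = dim[2];
  long n = (long)n0 * n1 * n2;
  IntegerVector lab(n, 0);
  // neighbour offsets
  std::vector<int> di, dj, dk;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        if (a == 0 && b == 0 && c == 0) continue;
        int manh = std::abs(a) + std::abs(b) + std::abs(c);
        if (connectivity == 6 && manh != 1) continue;
        di.push_back(a); dj.push_back(b); dk.push_back(c);
      }
  int nn = (int)di.size();
  int next = 0;
  std::vector<long> stack;
  for (long p = 0; p < n; ++p) {
    if (!mask[p] || lab[p] != 0) continue;
    ++next;
    lab[p] = next;
    stack.clear();
    stack.push_back(p);
    while (!stack.empty()) {
      long q = stack.back(); stack.pop_back();
      int i = (int)(q % n0);
      int j = (int)((q / n0) % n1);
      int k = (int)(q / ((long)n0 * n1));
      for (int t = 0; t < nn; ++t) {
        int ii = i + di[t], jj = j + dj[t], kk = k + dk[t];
        if (ii < 0 || ii >= n0 || jj < 0 || jj >= n1 || kk < 0 || kk >= n2)
          continue;
        long qq = ii + (long)n0 * (jj + (long)n1 * kk);
        if (mask[qq] && lab[qq] == 0) {
          lab[qq] = next;
          stack.push_back(qq);
        }
      }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}
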