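#include <Rcpp.h>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

static inline int clampi(int i, int n) {
  return i < 0 ? 0 : (i >= n ? n - 1 : i);
}

// Eigenvalues of a symmetric 3x3 matrix, closed form (trigonometric
// method). Output sorted by |lambda| ascending; |.|-ties broken by
// signed value ascending.
static void eig3_sym(double a11, double a12, double a13, double a22,
                     double a23, double a33, double out[3]) {
  double p1 = a12 * a12 + a13 * a13 + a23 * a23;
  double e[3];
  if (p1 == 0.0) {
    e[0] = a11; e[1] = a22; e[2] = a33;
  } else {
    double q = (a11 + a22 + a33) / 3.0;
    double p2 = (a11 - q) * (a11 - q) + (a22 - q) * (a22 - q) +
                (a33 - q) * (a33 - q) + 2.0 * p1;
    double p = std::sqrt(p2 / 6.0);
    double b11 = (a11 - q) / p, b22 = (a22 - q) / p, b33 = (a33 - q) / p;
    double b12 = a12 / p, b13 = a13 / p, b23 = a23 / p;
    double detB = b11 * (b22 * b33 - b23 * b23) -
                  b12 * (b12 * b33 - b23 * b13) +
                  b13 * (b12 * b23 - b22 * b13);
    double r = detB / 2.0;
    if (r < -1.0) r = -1.0;
    if (r > 1.0) r = 1.0;
    double phi = std::acos(r) / 3.0;
    e[0] = q + 2.0 * p * std::cos(phi);
    e[2] = q + 2.0 * p * std::cos(phi + 2.0 * M_PI / 3.0);
    e[1] = 3.0 * q - e[0] - e[2];
  }
  std::sort(e, e + 3, [](double x, double y) {
    double ax = std::fabs(x), ay = std::fabs(y);
    if (ax != ay) return ax < ay;
    return x < y;
  });
  out[0] = e[0]; out[1] = e[1]; out[2] = e[2];
}

// Per-voxel Hessian eigenvalues of a (pre-smoothed) volume.
// Second derivatives by central differences with edge replication,
// multiplied by scale_factor (sigma^2 in voxel units for gamma-normalized
// scale-space derivatives). Returns l1, l2, l3 with |l1| <= |l2| <= |l3|.
// [[Rcpp::export]]
List hessian_eigenvalues_cpp(NumericVector vol, IntegerVector dim,
                             double scale_factor) {
  int n0 = dim[0], n1 = dim[1], n2 = dim[2];
  long n = (long)n0 * n1 * n2;
  NumericVector l1(n), l2(n), l3(n);
  const double *f = vol.begin();
  long s0 = 1, s1 = n0, s2 = (long)n0 * n1;
  for (int k = 0; k < n2; ++k)
    for (int j = 0; j < n1; ++j)
      for (int i = 0; i < n0; ++i) {
        long p = i + (long)n0 * (j + (long)n1 * k);
        int im = clampi(i - 1, n0), ip = clampi(i + 1, n0);
        int jm = clampi(j - 1, n1), jp = clampi(j + 1, n1);
        int km = clampi(k - 1, n2), kp = clampi(k + 1, n2);
        double c = f[p];
        double h00 = f[ip * s0 + j * s1 + k * s2] - 2 * c +
                     f[im * s0 + j * s1 + k * s2];
        double h11 = f[i * s0 + jp * s1 + k * s2] - 2 * c +
                     f[i * s0 + jm * s1 + k * s2];
        double h22 = f[i * s0 + j * s1 + kp * s2] - 2 * c +
                     f[i * s0 + j * s1 + km * s2];
        double h01 = (f[ip * s0 + jp * s1 + k * s2] -
                      f[ip * s0 + jm * s1 + k * s2] -
                      f[im * s0 + jp * s1 + k * s2] +
                      f[im * s0 + jm * s1 + k * s2]) / 4.0;
        double h02 = (f[ip * s0 + j * s1 + kp * s2] -
                      f[ip * s0 + j * s1 + km * s2] -
                      f[im * s0 + j * s1 + kp * s2] +
                      f[im * s0 + j * s1 + km * s2]) / 4.0;
        double h12 = (f[i * s0 + jp * s1 + kp * s2] -
                      f[i * s0 + jp * s1 + km * s2] -
                      f[i * s0 + jm * s1 + kp * s2] +
                      f[i * s0 + jm * s1 + km * s2]) / 4.0;
        double e[3];
        eig3_sym(h00 * scale_factor, h01 * scale_factor, h02 * scale_factor,
                 h11 * scale_factor, h12 * scale_factor, h22 * scale_factor,
                 e);
        l1[p] = e[0]; l2[p] = e[1]; l3[p] = e[2];
      }
  l1.attr("dim") = dim;
  l2.attr("dim") = dim;
  l3.attr("dim") = dim;
  return List::create(Named("l1") = l1, Named("l2") = l2, Named("l3") = l3);
}
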