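#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Iso-surface area by marching tetrahedra: each grid cell (cube of 8
// voxel-center samples) is split into 6 tetrahedra around the main
// diagonal; the level set is linearly interpolated along tetrahedron
// edges. Returns total triangle area in voxel units^2.

struct P3 { double x, y, z; };

static inline P3 lerp(const P3 &a, const P3 &b, double fa, double fb,
                      double level) {
  double t = (level - fa) / (fb - fa);
  P3 p;
  p.x = a.x + t * (b.x - a.x);
  p.y = a.y + t * (b.y - a.y);
  p.z = a.z + t * (b.z - a.z);
  return p;
}

static inline double tri_area(const P3 &a, const P3 &b, const P3 &c) {
  double ux = b.x - a.x, uy = b.y - a.y, uz = b.z - a.z;
  double vx = c.x - a.x, vy = c.y - a.y, vz = c.z - a.z;
  double cx = uy * vz - uz * vy;
  double cy = uz * vx - ux * vz;
  double cz = ux * vy - uy * vx;
  return 0.5 * std::sqrt(cx * cx + cy * cy + cz * cz);
}

static double tet_area(const P3 v[4], const double f[4], double level) {
  bool above[4];
  int nab = 0;
  for (int i = 0; i < 4; ++i) {
    above[i] = f[i] > level;
    if (above[i]) ++nab;
  }
  if (nab == 0 || nab == 4) return 0.0;
  int a[4], b[4], na = 0, nb = 0;
  for (int i = 0; i < 4; ++i) {
    if (above[i]) a[na++] = i; else b[nb++] = i;
  }
  if (nab == 1 || nab == 3) {
    // single isolated vertex (above or below): one triangle
    int s = (nab == 1) ? a[0] : b[0];
    int o[3], no = 0;
    for (int i = 0; i < 4; ++i) if (i != s) o[no++] = i;
    P3 p0 = lerp(v[s], v[o[0]], f[s], f[o[0]], level);
    P3 p1 = lerp(v[s], v[o[1]], f[s], f[o[1]], level);
    P3 p2 = lerp(v[s], v[o[2]], f[s], f[o[2]], level);
    return tri_area(p0, p1, p2);
  }
  // 2 above / 2 below: quad split into two triangles
  P3 q0 = lerp(v[a[0]], v[b[0]], f[a[0]], f[b[0]], level);
  P3 q1 = lerp(v[a[0]], v[b[1]], f[a[0]], f[b[1]], level);
  P3 q2 = lerp(v[a[1]], v[b[1]], f[a[1]], f[b[1]], level);
  P3 q3 = lerp(v[a[1]], v[b[0]], f[a[1]], f[b[0]], level);
  return tri_area(q0, q1, q2) + tri_area(q0, q2, q3);
}

// 6-tetrahedron decomposition of the unit cube around diagonal 0-6.
static const int TETS[6][4] = {
  {0, 1, 2, 6}, {0, 2, 3, 6}, {0, 3, 7, 6},
  {0, 7, 4, 6}, {0, 4, 5, 6}, {0, 5, 1, 6}
};
// cube corner offsets (x, y, z)
static const int CRN[8][3] = {
  {0, 0, 0}, {1, 0, 0}, {1, 1, 0}, {0, 1, 0},
  {0, 0, 1}, {1, 0, 1}, {1, 1, 1}, {0, 1, 1}
};

// [[Rcpp::export]]
double isosurface_area_cpp(NumericVector field, IntegerVector dim,
                           double level) {
  int n0 = dim[0], n1 = dim[1], n2 = dim[2];
  double total = 0.0;
  double fc[8];
  P3 pc[8];
  for (int k = 0; k + 1 < n2; ++k)
    for (int j = 0; j + 1 < n1; ++j)
      for (int i = 0; i + 1 < n0; ++i) {
        bool anyAbove = false, anyBelow = false;
        for (int c = 0; c < 8; ++c) {
          int ii = i + CRN[c][0], jj = j + CRN[c][1], kk = k + CRN[c][2];
          fc[c] = field[ii + (long)n0 * (jj + (long)n1 * kk)];
          pc[c].x = ii; pc[c].y = jj; pc[c].z = kk;
          if (fc[c] > level) anyAbove = true; else anyBelow = true;
        }
        if (!anyAbove || !anyBelow) continue;
        for (int t = 0; t < 6; ++t) {
          P3 tv[4];
          double tf[4];
          for (int c = 0; c < 4; ++c) {
            tv[c] = pc[TETS[t][c]];
            tf[c] = fc[TETS[t][c]];
          }
          total += tet_area(tv, tf, level);
        }
      }
  return total;
}
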