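#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Triangle vs axis-aligned box overlap (separating axis test,
// Akenine-Moller): 3 box axes, the triangle plane, and 9 edge cross
// products. Touching contact counts as overlap (closed boxes).

static inline void cross3(const double a[3], const double b[3], double out[3]) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}

static bool axis_separates(const double axis[3], const double v0[3],
                           const double v1[3], const double v2[3],
                           const double half[3]) {
  double p0 = axis[0] * v0[0] + axis[1] * v0[1] + axis[2] * v0[2];
  double p1 = axis[0] * v1[0] + axis[1] * v1[1] + axis[2] * v1[2];
  double p2 = axis[0] * v2[0] + axis[1] * v2[1] + axis[2] * v2[2];
  double mn = std::min(p0, std::min(p1, p2));
  double mx = std::max(p0, std::max(p1, p2));
  double r = half[0] * std::fabs(axis[0]) + half[1] * std::fabs(axis[1]) +
             half[2] * std::fabs(axis[2]);
  return mn > r || mx < -r;
}

static bool tri_box_overlap(const double center[3], const double half[3],
                            const double tv[3][3]) {
  double v0[3], v1[3], v2[3];
  for (int i = 0; i < 3; ++i) {
    v0[i] = tv[0][i] - center[i];
    v1[i] = tv[1][i] - center[i];
    v2[i] = tv[2][i] - center[i];
  }
  // box axes
  for (int i = 0; i < 3; ++i) {
    double mn = std::min(v0[i], std::min(v1[i], v2[i]));
    double mx = std::max(v0[i], std::max(v1[i], v2[i]));
    if (mn > half[i] || mx < -half[i]) return false;
  }
  double e0[3], e1[3], e2[3];
  for (int i = 0; i < 3; ++i) {
    e0[i] = v1[i] - v0[i];
    e1[i] = v2[i] - v1[i];
    e2[i] = v0[i] - v2[i];
  }
  // triangle plane
  double n[3];
  cross3(e0, e1, n);
  if (axis_separates(n, v0, v1, v2, half)) return false;
  // 9 cross-product axes
  const double ax[3][3] = {{1, 0, 0}, {0, 1, 0}, {0, 0, 1}};
  const double *edges[3] = {e0, e1, e2};
  for (int a = 0; a < 3; ++a) {
    for (int e = 0; e < 3; ++e) {
      double axis[3];
      cross3(ax[a], edges[e], axis);
      if (std::fabs(axis[0]) + std::fabs(axis[1]) + std::fabs(axis[2]) < 1e-300)
        continue;  // degenerate axis: edge parallel to box axis
      if (axis_separates(axis, v0, v1, v2, half)) return false;
    }
  }
  return true;
}

// Conservative surface voxelization. Candidate voxels per triangle come
// from its bounding box; an axis extent that ends exactly on a voxel
// boundary assigns the boundary plane to the lower voxel (half-open
// voxels), with the grid's minimum face clamped inward.
// [[Rcpp::export(name = ".voxelize_surface_cpp")]]
LogicalVector voxelize_surface_cpp(NumericMatrix verts, IntegerMatrix faces,
                                   NumericVector origin, double s, int res) {
  LogicalVector occ(res * res * res);
  const double half_full[3] = {s / 2, s / 2, s / 2};
  for (int f = 0; f < faces.nrow(); ++f) {
    double tv[3][3];
    for (int k = 0; k < 3; ++k) {
      int vi = faces(f, k) - 1;
      for (int d = 0; d < 3; ++d) tv[k][d] = verts(vi, d);
    }
    int lo[3], hi[3];
    for (int d = 0; d < 3; ++d) {
      double tmin = std::min(tv[0][d], std::min(tv[1][d], tv[2][d]));
      double tmax = std::max(tv[0][d], std::max(tv[1][d], tv[2][d]));
      double flo = (tmin - origin[d]) / s;
      double fhi = (tmax - origin[d]) / s;
      int ilo, ihi;
      if (fhi > flo) {
        ilo = (int)std::floor(flo);
        ihi = (int)std::ceil(fhi) - 1;
      } else {  // degenerate axis: exact boundary belongs to the lower voxel
        ilo = ihi = (int)std::ceil(flo) - 1;
      }
      lo[d] = std::max(0, std::min(res - 1, ilo));
      hi[d] = std::max(0, std::min(res - 1, ihi));
      if (tmax < origin[d] || tmin > origin[d] + res * s) {
        lo[d] = 1; hi[d] = 0;  // fully outside the grid on this axis
      }
    }
    for (int i = lo[0]; i <= hi[0]; ++i) {
      for (int j = lo[1]; j <= hi[1]; ++j) {
        for (int k = lo[2]; k <= hi[2]; ++k) {
          int idx = i + res * (j + res * k);
          if (occ[idx]) continue;
          double center[3] = {origin[0] + (i + 0.5) * s,
                              origin[1] + (j + 0.5) * s,
                              origin[2] + (k + 0.5) * s};
          if (tri_box_overlap(center, half_full, tv)) occ[idx] = true;
        }
      }
    }
  }
  return occ;
}
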