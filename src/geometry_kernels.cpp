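#include <Rcpp.h>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

// Physical coordinates: voxel (i,j,k), 1-based, has centre
// ((i-0.5)*sx, (j-0.5)*sy, (k-0.5)*sz) micrometres.

static inline double segDist2(double px, double py, double pz,
                              double ax, double ay, double az,
                              double bx, double by, double bz) {
  double vx = bx - ax, vy = by - ay, vz = bz - az;
  double wx = px - ax, wy = py - ay, wz = pz - az;
  double vv = vx * vx + vy * vy + vz * vz;
  double t = (vv > 0) ? (wx * vx + wy * vy + wz * vz) / vv : 0.0;
  t = std::max(0.0, std::min(1.0, t));
  double dx = wx - t * vx, dy = wy - t * vy, dz = wz - t * vz;
  return dx * dx + dy * dy + dz * dz;
}

// Rasterize capsules (segments with radius): voxels whose centres lie
// within `radius` of any segment are set TRUE in-place on `mask`.
// [[Rcpp::export]]
LogicalVector cpp_paint_capsules(LogicalVector mask, IntegerVector dim,
                                 NumericVector spacing,
                                 NumericMatrix segA, NumericMatrix segB,
                                 double radius) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  LogicalVector out = clone(mask);
  const double r2 = radius * radius;
  for (int s = 0; s < segA.nrow(); s++) {
    double ax = segA(s, 0), ay = segA(s, 1), az = segA(s, 2);
    double bx = segB(s, 0), by = segB(s, 1), bz = segB(s, 2);
    int x0 = std::max(0, (int)std::floor((std::min(ax, bx) - radius) / sx));
    int x1 = std::min(nx - 1, (int)std::ceil((std::max(ax, bx) + radius) / sx));
    int y0 = std::max(0, (int)std::floor((std::min(ay, by) - radius) / sy));
    int y1 = std::min(ny - 1, (int)std::ceil((std::max(ay, by) + radius) / sy));
    int z0 = std::max(0, (int)std::floor((std::min(az, bz) - radius) / sz));
    int z1 = std::min(nz - 1, (int)std::ceil((std::max(az, bz) + radius) / sz));
    for (int z = z0; z <= z1; z++) {
      double pz = (z + 0.5) * sz;
      for (int y = y0; y <= y1; y++) {
        double py = (y + 0.5) * sy;
        for (int x = x0; x <= x1; x++) {
          R_xlen_t i = x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
          if (out[i]) continue;
          double px = (x + 0.5) * sx;
          if (segDist2(px, py, pz, ax, ay, az, bx, by, bz) <= r2)
            out[i] = true;
        }
      }
    }
  }
  return out;
}

// Minimum distance from each query point to a set of segments (um).
// [[Rcpp::export]]
NumericVector cpp_min_dist_segments(NumericMatrix pts, NumericMatrix segA,
                                    NumericMatrix segB) {
  const int np = pts.nrow(), ns = segA.nrow();
  NumericVector out(np);
  for (int p = 0; p < np; p++) {
    double best = R_PosInf;
    for (int s = 0; s < ns; s++) {
      double d2 = segDist2(pts(p, 0), pts(p, 1), pts(p, 2),
                           segA(s, 0), segA(s, 1), segA(s, 2),
                           segB(s, 0), segB(s, 1), segB(s, 2));
      if (d2 < best) best = d2;
    }
    out[p] = std::sqrt(best);
  }
  return out;
}
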