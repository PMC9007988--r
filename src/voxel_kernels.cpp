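#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Voxel grids arrive as R logical/integer 3D arrays in column-major order:
// linear index = x + nx*(y + ny*z), x fastest. Out-of-grid is background.

static inline int idx3(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// ---------------------------------------------------------------------------
// Exact Euclidean distance transform (Felzenszwalb & Huttenlocher squared
// EDT, separable), anisotropic voxel spacings in micrometres. Seeds are the
// TRUE voxels; returns distance (um) from every voxel centre to the nearest
// seed centre. INF where no seed exists.
// ---------------------------------------------------------------------------

static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 int n, double s) {
  std::vector<int> v(n);
  std::vector<double> zz(n + 1);
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  zz[0] = -INF;
  zz[1] = INF;
  for (int q = 1; q < n; q++) {
    if (f[q] == INF && f[v[k]] == INF) { // skip empty columns
      continue;
    }
    double sq = s * q, sv = s * v[k];
    double sden = 2.0 * sq - 2.0 * sv;
    double num = (f[q] + sq * sq) - (f[v[k]] + sv * sv);
    double ss = (sden > 0) ? num / sden : INF;
    while (k > 0 && ss <= zz[k]) {
      k--;
      sv = s * v[k];
      sden = 2.0 * sq - 2.0 * sv;
      num = (f[q] + sq * sq) - (f[v[k]] + sv * sv);
      ss = (sden > 0) ? num / sden : INF;
    }
    k++;
    v[k] = q;
    zz[k] = ss;
    zz[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (zz[k + 1] < s * q) k++;
    double diff = s * (q - v[k]);
    d[q] = (f[v[k]] == INF) ? INF : diff * diff + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt(LogicalVector seeds, IntegerVector dim,
                      NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double INF = std::numeric_limits<double>::infinity();
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> g(n);
  for (R_xlen_t i = 0; i < n; i++) g[i] = seeds[i] ? 0.0 : INF;

  // pass along x
  {
    std::vector<double> f(nx), d(nx);
    for (int z = 0; z < nz; z++)
      for (int y = 0; y < ny; y++) {
        for (int x = 0; x < nx; x++) f[x] = g[idx3(x, y, z, nx, ny)];
        dt1d(f, d, nx, spacing[0]);
        for (int x = 0; x < nx; x++) g[idx3(x, y, z, nx, ny)] = d[x];
      }
  }
  // pass along y
  {
    std::vector<double> f(ny), d(ny);
    for (int z = 0; z < nz; z++)
      for (int x = 0; x < nx; x++) {
        for (int y = 0; y < ny; y++) f[y] = g[idx3(x, y, z, nx, ny)];
        dt1d(f, d, ny, spacing[1]);
        for (int y = 0; y < ny; y++) g[idx3(x, y, z, nx, ny)] = d[y];
      }
  }
  // pass along z
  {
    std::vector<double> f(nz), d(nz);
    for (int y = 0; y < ny; y++)
      for (int x = 0; x < nx; x++) {
        for (int z = 0; z < nz; z++) f[z] = g[idx3(x, y, z, nx, ny)];
        dt1d(f, d, nz, spacing[2]);
        for (int z = 0; z < nz; z++) g[idx3(x, y, z, nx, ny)] = d[z];
      }
  }
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; i++)
    out[i] = (g[i] == INF) ? R_PosInf : std::sqrt(g[i]);
  return out;
}

// ---------------------------------------------------------------------------
// Simple-point test on the 26-neighbourhood (topology-preservation check):
// p is simple iff (a) the foreground of N26*(p) has exactly one 26-connected
// component, and (b) the background of N18(p) has exactly one 6-connected
// component containing a 6-neighbour of p (components computed inside N18).
// Both counts are obtained by direct flood fill over the 3x3x3 block, so no
// lookup tables are required.
// ---------------------------------------------------------------------------

static const int D6[6][3] = {
  {1, 0, 0}, {-1, 0, 0}, {0, 1, 0}, {0, -1, 0}, {0, 0, 1}, {0, 0, -1}
};

// nb[27]: foreground occupancy of 3x3x3 block, local index (dx+1)+3*((dy+1)+3*(dz+1))
static inline int lidx(int dx, int dy, int dz) {
  return (dx + 1) + 3 * ((dy + 1) + 3 * (dz + 1));
}

static bool isSimple(const bool nb[27]) {
  // (a) 26-components of foreground in N26* (exclude centre 13)
  bool seen[27] = {false};
  int ncomp_fg = 0;
  for (int i = 0; i < 27; i++) {
    if (i == 13 || !nb[i] || seen[i]) continue;
    ncomp_fg++;
    if (ncomp_fg > 1) return false;
    std::queue<int> q;
    q.push(i);
    seen[i] = true;
    while (!q.empty()) {
      int c = q.front(); q.pop();
      int cx = c % 3, cy = (c / 3) % 3, cz = c / 9;
      for (int dz = -1; dz <= 1; dz++)
        for (int dy = -1; dy <= 1; dy++)
          for (int dx = -1; dx <= 1; dx++) {
            int x = cx + dx, y = cy + dy, z = cz + dz;
            if (x < 0 || x > 2 || y < 0 || y > 2 || z < 0 || z > 2) continue;
            int j = x + 3 * (y + 3 * z);
            if (j == 13 || j == c || seen[j] || !nb[j]) continue;
            seen[j] = true;
            q.push(j);
          }
    }
  }
  if (ncomp_fg != 1) return false;

  // (b) 6-components of background within N18 seeded at 6-neighbours of p
  bool inN18[27] = {false};
  for (int dz = -1; dz <= 1; dz++)
    for (int dy = -1; dy <= 1; dy++)
      for (int dx = -1; dx <= 1; dx++) {
        int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (m == 1 || m == 2) inN18[lidx(dx, dy, dz)] = true;
      }
  bool seenb[27] = {false};
  int ncomp_bg = 0;
  for (int s = 0; s < 6; s++) {
    int i = lidx(D6[s][0], D6[s][1], D6[s][2]);
    if (nb[i] || seenb[i]) continue;
    ncomp_bg++;
    if (ncomp_bg > 1) return false;
    std::queue<int> q;
    q.push(i);
    seenb[i] = true;
    while (!q.empty()) {
      int c = q.front(); q.pop();
      int cx = c % 3, cy = (c / 3) % 3, cz = c / 9;
      for (int s2 = 0; s2 < 6; s2++) {
        int x = cx + D6[s2][0], y = cy + D6[s2][1], z = cz + D6[s2][2];
        if (x < 0 || x > 2 || y < 0 || y > 2 || z < 0 || z > 2) continue;
        int j = x + 3 * (y + 3 * z);
        if (!inN18[j] || seenb[j] || nb[j]) continue;
        seenb[j] = true;
        q.push(j);
      }
    }
  }
  return ncomp_bg == 1;
}

static inline bool getvox(const std::vector<char>& m, int x, int y, int z,
                          int nx, int ny, int nz) {
  if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz) return false;
  return m[idx3(x, y, z, nx, ny)] != 0;
}

static void fillnb(const std::vector<char>& m, int x, int y, int z,
                   int nx, int ny, int nz, bool nb[27]) {
  for (int dz = -1; dz <= 1; dz++)
    for (int dy = -1; dy <= 1; dy++)
      for (int dx = -1; dx <= 1; dx++)
        nb[lidx(dx, dy, dz)] = getvox(m, x + dx, y + dy, z + dz, nx, ny, nz);
}

static int count26(const bool nb[27]) {
  int c = 0;
  for (int i = 0; i < 27; i++) if (i != 13 && nb[i]) c++;
  return c;
}

// Curve thinning: 6 directional sub-iterations per round; a voxel is deleted
// when it is a border point in the sweep direction, simple, and not a curve
// endpoint (>=2 foreground 26-neighbours). Sequential deletion inside a
// sub-iteration keeps the simple-point guarantee exact.
// [[Rcpp::export]]
LogicalVector cpp_thin(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<char> m(n);
  for (R_xlen_t i = 0; i < n; i++) m[i] = mask[i] ? 1 : 0;

  bool nb[27];
  bool changed = true;
  while (changed) {
    changed = false;
    for (int dir = 0; dir < 6; dir++) {
      // collect candidates border in this direction, then delete sequentially
      std::vector<int> cand;
      for (int z = 0; z < nz; z++)
        for (int y = 0; y < ny; y++)
          for (int x = 0; x < nx; x++) {
            if (!m[idx3(x, y, z, nx, ny)]) continue;
            if (getvox(m, x + D6[dir][0], y + D6[dir][1], z + D6[dir][2],
                       nx, ny, nz)) continue;
            cand.push_back(idx3(x, y, z, nx, ny));
          }
      for (size_t c = 0; c < cand.size(); c++) {
        int i = cand[c];
        if (!m[i]) continue;
        int x = i % nx, y = (i / nx) % ny, z = i / (nx * ny);
        fillnb(m, x, y, z, nx, ny, nz, nb);
        if (count26(nb) < 2) continue;   // endpoint: keep
        if (!isSimple(nb)) continue;
        m[i] = 0;
        changed = true;
      }
    }
  }
  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; i++) out[i] = m[i] != 0;
  return out;
}

// ---------------------------------------------------------------------------
// 26-connected component labelling (BFS). Returns 0 for background,
// 1..k for components.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
IntegerVector cpp_label26(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  int next = 0;
  std::queue<int> q;
  for (R_xlen_t s = 0; s < n; s++) {
    if (!mask[s] || lab[s]) continue;
    next++;
    lab[s] = next;
    q.push((int)s);
    while (!q.empty()) {
      int c = q.front(); q.pop();
      int cx = c % nx, cy = (c / nx) % ny, cz = c / (nx * ny);
      for (int dz = -1; dz <= 1; dz++)
        for (int dy = -1; dy <= 1; dy++)
          for (int dx = -1; dx <= 1; dx++) {
            if (!dx && !dy && !dz) continue;
            int x = cx + dx, y = cy + dy, z = cz + dz;
            if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz)
              continue;
            int j = idx3(x, y, z, nx, ny);
            if (!mask[j] || lab[j]) continue;
            lab[j] = next;
            q.push(j);
          }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Exposed-face count per voxel (6-connectivity; out-of-grid counts as
// background). Background voxels get 0.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
IntegerVector cpp_exposed_faces(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector out(n, 0);
  for (int z = 0; z < nz; z++)
    for (int y = 0; y < ny; y++)
      for (int x = 0; x < nx; x++) {
        int i = idx3(x, y, z, nx, ny);
        if (!mask[i]) continue;
        int c = 0;
        for (int s = 0; s < 6; s++) {
          int xx = x + D6[s][0], yy = y + D6[s][1], zz = z + D6[s][2];
          bool bg = (xx < 0 || xx >= nx || yy < 0 || yy >= ny ||
                     zz < 0 || zz >= nz) ||
                    !mask[idx3(xx, yy, zz, nx, ny)];
          if (bg) c++;
        }
        out[i] = c;
      }
  return out;
}
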