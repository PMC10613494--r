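#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Linear index helpers: all voxel indices here are 0-based C order for the
// first array dimension varying fastest (R column-major layout).
static inline R_xlen_t lin(int x, int y, int z, int nx, int ny) {
  return (R_xlen_t)x + (R_xlen_t)nx * ((R_xlen_t)y + (R_xlen_t)ny * (R_xlen_t)z);
}

// Breadth-first flood fill over voxels flagged eligible, starting from seed
// voxels, using face (6) or face+edge+corner (26) adjacency.
// [[Rcpp::export]]
LogicalVector cpp_flood_fill(LogicalVector eligible, IntegerVector dims,
                             IntegerVector seeds0, int connectivity) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  LogicalVector out(eligible.size(), false);
  std::queue<R_xlen_t> q;
  for (int i = 0; i < seeds0.size(); ++i) {
    R_xlen_t s = seeds0[i];
    if (s < 0 || s >= eligible.size()) stop("seed index out of range");
    if (eligible[s] && !out[s]) { out[s] = true; q.push(s); }
  }
  while (!q.empty()) {
    R_xlen_t v = q.front(); q.pop();
    int x = (int)(v % nx);
    int y = (int)((v / nx) % ny);
    int z = (int)(v / ((R_xlen_t)nx * ny));
    for (int dz = -1; dz <= 1; ++dz) {
      for (int dy = -1; dy <= 1; ++dy) {
        for (int dx = -1; dx <= 1; ++dx) {
          int ad = std::abs(dx) + std::abs(dy) + std::abs(dz);
          if (ad == 0) continue;
          if (connectivity == 6 && ad != 1) continue;
          int xx = x + dx, yy = y + dy, zz = z + dz;
          if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz) continue;
          R_xlen_t w = lin(xx, yy, zz, nx, ny);
          if (eligible[w] && !out[w]) { out[w] = true; q.push(w); }
        }
      }
    }
  }
  return out;
}

// Label connected components of a binary volume; labels 1..k, 0 background.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  IntegerVector lab(mask.size(), 0);
  int next = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t i = 0; i < mask.size(); ++i) {
    if (!mask[i] || lab[i]) continue;
    lab[i] = ++next;
    q.push(i);
    while (!q.empty()) {
      R_xlen_t v = q.front(); q.pop();
      int x = (int)(v % nx);
      int y = (int)((v / nx) % ny);
      int z = (int)(v / ((R_xlen_t)nx * ny));
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            int ad = std::abs(dx) + std::abs(dy) + std::abs(dz);
            if (ad == 0) continue;
            if (connectivity == 6 && ad != 1) continue;
            int xx = x + dx, yy = y + dy, zz = z + dz;
            if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz) continue;
            R_xlen_t w = lin(xx, yy, zz, nx, ny);
            if (mask[w] && !lab[w]) { lab[w] = next; q.push(w); }
          }
    }
  }
  return lab;
}

// For each foreground voxel count how many of the supplied integer offsets
// land on a foreground voxel; out-of-volume neighbours count as background.
// Counts are returned for every voxel (also background ones) so callers can
// build dilations as well as erosions/medians.
// [[Rcpp::export]]
IntegerVector cpp_count_neighbors(LogicalVector mask, IntegerVector dims,
                                  IntegerMatrix offsets) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int no = offsets.nrow();
  IntegerVector cnt(mask.size(), 0);
  for (int o = 0; o < no; ++o) {
    int dx = offsets(o, 0), dy = offsets(o, 1), dz = offsets(o, 2);
    for (int z = 0; z < nz; ++z) {
      int zz = z + dz;
      if (zz < 0 || zz >= nz) continue;
      for (int y = 0; y < ny; ++y) {
        int yy = y + dy;
        if (yy < 0 || yy >= ny) continue;
        int x0 = std::max(0, -dx), x1 = std::min(nx, nx - dx);
        R_xlen_t base = lin(0, y, z, nx, ny);
        R_xlen_t nbase = lin(dx, yy, zz, nx, ny);
        for (int x = x0; x < x1; ++x)
          if (mask[nbase + x]) cnt[base + x] += 1;
      }
    }
  }
  return cnt;
}

// Trilinear interpolation at fractional 0-based voxel coordinates.
// Points outside the valid cube get `fill` (use NA_REAL to mark and drop).
// [[Rcpp::export]]
NumericVector cpp_trilinear(NumericVector values, IntegerVector dims,
                            NumericMatrix pts, double fill) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = pts.nrow();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    double px = pts(i, 0), py = pts(i, 1), pz = pts(i, 2);
    if (!(px >= 0 && py >= 0 && pz >= 0 &&
          px <= nx - 1 && py <= ny - 1 && pz <= nz - 1)) {
      out[i] = fill;
      continue;
    }
    int x0 = (int)std::floor(px), y0 = (int)std::floor(py), z0 = (int)std::floor(pz);
    if (x0 == nx - 1) x0--;
    if (y0 == ny - 1) y0--;
    if (z0 == nz - 1) z0--;
    if (nx == 1) x0 = 0;
    if (ny == 1) y0 = 0;
    if (nz == 1) z0 = 0;
    double fx = px - x0, fy = py - y0, fz = pz - z0;
    int x1 = std::min(x0 + 1, nx - 1), y1 = std::min(y0 + 1, ny - 1), z1 = std::min(z0 + 1, nz - 1);
    double c000 = values[lin(x0, y0, z0, nx, ny)];
    double c100 = values[lin(x1, y0, z0, nx, ny)];
    double c010 = values[lin(x0, y1, z0, nx, ny)];
    double c110 = values[lin(x1, y1, z0, nx, ny)];
    double c001 = values[lin(x0, y0, z1, nx, ny)];
    double c101 = values[lin(x1, y0, z1, nx, ny)];
    double c011 = values[lin(x0, y1, z1, nx, ny)];
    double c111 = values[lin(x1, y1, z1, nx, ny)];
    double c00 = c000 * (1 - fx) + c100 * fx;
    double c10 = c010 * (1 - fx) + c110 * fx;
    double c01 = c001 * (1 - fx) + c101 * fx;
    double c11 = c011 * (1 - fx) + c111 * fx;
    double c0 = c00 * (1 - fy) + c10 * fy;
    double c1 = c01 * (1 - fy) + c11 * fy;
    out[i] = c0 * (1 - fz) + c1 * fz;
  }
  return out;
}

// Separable Gaussian smoothing with per-axis sigma in voxels. Kernels are
// truncated at 3 sigma and renormalised at the volume edges so a constant
// field stays exactly constant.
static void smooth_axis(std::vector<double> &v, int nx, int ny, int nz,
                        int axis, double sigma) {
  if (sigma <= 0) return;
  int rad = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * rad + 1);
  for (int i = -rad; i <= rad; ++i)
    k[i + rad] = std::exp(-0.5 * (double)i * i / (sigma * sigma));
  int n[3] = {nx, ny, nz};
  R_xlen_t stride[3] = {1, (R_xlen_t)nx, (R_xlen_t)nx * ny};
  int len = n[axis];
  R_xlen_t st = stride[axis];
  int a1 = (axis + 1) % 3, a2 = (axis + 2) % 3;
  std::vector<double> line(len);
  for (int j2 = 0; j2 < n[a2]; ++j2) {
    for (int j1 = 0; j1 < n[a1]; ++j1) {
      R_xlen_t base = (R_xlen_t)j1 * stride[a1] + (R_xlen_t)j2 * stride[a2];
      for (int i = 0; i < len; ++i) line[i] = v[base + (R_xlen_t)i * st];
      for (int i = 0; i < len; ++i) {
        double s = 0, wsum = 0;
        int lo = std::max(0, i - rad), hi = std::min(len - 1, i + rad);
        for (int j = lo; j <= hi; ++j) {
          double w = k[j - i + rad];
          s += w * line[j];
          wsum += w;
        }
        v[base + (R_xlen_t)i * st] = s / wsum;
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_gauss_smooth(NumericVector values, IntegerVector dims,
                               NumericVector sigma_vox) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<double> v(values.begin(), values.end());
  for (int a = 0; a < 3; ++a) smooth_axis(v, nx, ny, nz, a, sigma_vox[a]);
  return NumericVector(v.begin(), v.end());
}

// For each point in A, the minimum Euclidean distance to any point in B.
// Plain O(|A||B|) scan; surface sets at desk scale keep this cheap.
// [[Rcpp::export]]
NumericVector cpp_min_dists(NumericMatrix a, NumericMatrix b) {
  R_xlen_t na = a.nrow(), nb = b.nrow();
  NumericVector out(na);
  for (R_xlen_t i = 0; i < na; ++i) {
    double ax = a(i, 0), ay = a(i, 1), az = a(i, 2);
    double best = R_PosInf;
    for (R_xlen_t j = 0; j < nb; ++j) {
      double dx = ax - b(j, 0), dy = ay - b(j, 1), dz = az - b(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// Nearest-neighbour lookup of a logical volume at fractional 0-based voxel
// coordinates, rounding halves away from zero; out of bounds -> false.
// [[Rcpp::export]]
LogicalVector cpp_nn_mask_lookup(LogicalVector mask, IntegerVector dims,
                                 NumericMatrix pts) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = pts.nrow();
  LogicalVector out(n, false);
  for (R_xlen_t i = 0; i < n; ++i) {
    double c[3] = {pts(i, 0), pts(i, 1), pts(i, 2)};
    int idx[3];
    bool ok = true;
    int nn[3] = {nx, ny, nz};
    for (int a = 0; a < 3; ++a) {
      double x = c[a];
      double r = (x >= 0) ? std::floor(x + 0.5) : std::ceil(x - 0.5);
      if (r < 0 || r > nn[a] - 1) { ok = false; break; }
      idx[a] = (int)r;
    }
    if (ok) out[i] = mask[lin(idx[0], idx[1], idx[2], nx, ny)];
  }
  return out;
}
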