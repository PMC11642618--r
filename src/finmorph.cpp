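#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
#include <limits>
using namespace Rcpp;

// ---- 1D squared distance transform (lower envelope of parabolas) ----
static void dt1d(const std::vector<double>& f, int n, std::vector<double>& d) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; q++) {
    double s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      k--;
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Squared Euclidean distance (voxel units) from each voxel to the nearest
// background voxel center. The grid is padded by one background layer, so
// voxels on the boundary see background just outside the grid.
// [[Rcpp::export]]
NumericVector sq_edt_cpp(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int px = nx + 2, py = ny + 2, pz = nz + 2;
  const double INF = 1e30;
  std::vector<double> g((size_t)px * py * pz, 0.0);
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++) {
        if (mask[i + nx * (j + (size_t)ny * k)])
          g[(i + 1) + (size_t)px * ((j + 1) + (size_t)py * (k + 1))] = INF;
      }
  // pass along x
  {
    std::vector<double> f(px), d(px);
    for (int k = 0; k < pz; k++)
      for (int j = 0; j < py; j++) {
        size_t base = (size_t)px * (j + (size_t)py * k);
        for (int i = 0; i < px; i++) f[i] = g[i + base];
        dt1d(f, px, d);
        for (int i = 0; i < px; i++) g[i + base] = d[i];
      }
  }
  // pass along y
  {
    std::vector<double> f(py), d(py);
    for (int k = 0; k < pz; k++)
      for (int i = 0; i < px; i++) {
        for (int j = 0; j < py; j++) f[j] = g[i + (size_t)px * (j + (size_t)py * k)];
        dt1d(f, py, d);
        for (int j = 0; j < py; j++) g[i + (size_t)px * (j + (size_t)py * k)] = d[j];
      }
  }
  // pass along z
  {
    std::vector<double> f(pz), d(pz);
    for (int j = 0; j < py; j++)
      for (int i = 0; i < px; i++) {
        for (int k = 0; k < pz; k++) f[k] = g[i + (size_t)px * (j + (size_t)py * k)];
        dt1d(f, pz, d);
        for (int k = 0; k < pz; k++) g[i + (size_t)px * (j + (size_t)py * k)] = d[k];
      }
  }
  NumericVector out((size_t)nx * ny * nz);
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++)
        out[i + nx * (j + (size_t)ny * k)] =
          g[(i + 1) + (size_t)px * ((j + 1) + (size_t)py * (k + 1))];
  return out;
}

// Distance-ridge local thickness, in voxel units: r(q) = distance to the
// nearest background voxel center, thickness(p) = 2 * max{ r(q) : bone q
// with |p-q| <= r(q) } - 0.5. Squared distances are integers, so all
// coverage comparisons are exact. The half-voxel diameter correction
// centers the estimator: the true boundary lies midway between bone and
// background centers, and lattice quantization of the ridge splits the
// remaining half voxel either way.
// [[Rcpp::export]]
NumericVector local_thickness_cpp(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector sq = sq_edt_cpp(mask, dims);
  size_t n = (size_t)nx * ny * nz;
  NumericVector thick(n);
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++) {
        size_t q = i + nx * (j + (size_t)ny * k);
        if (!mask[q]) continue;
        double r2 = sq[q];
        double r = std::sqrt(r2);
        int ir = (int)std::floor(r);
        int i0 = std::max(0, i - ir), i1 = std::min(nx - 1, i + ir);
        int j0 = std::max(0, j - ir), j1 = std::min(ny - 1, j + ir);
        int k0 = std::max(0, k - ir), k1 = std::min(nz - 1, k + ir);
        double diam = 2.0 * r;
        for (int kk = k0; kk <= k1; kk++)
          for (int jj = j0; jj <= j1; jj++)
            for (int ii = i0; ii <= i1; ii++) {
              double dd = (double)(ii - i) * (ii - i) +
                          (double)(jj - j) * (jj - j) +
                          (double)(kk - k) * (kk - k);
              if (dd <= r2) {
                size_t p = ii + nx * (jj + (size_t)ny * kk);
                if (mask[p] && thick[p] < diam) thick[p] = diam;
              }
            }
      }
  for (size_t s = 0; s < n; s++)
    if (mask[s] && thick[s] > 0.5) thick[s] -= 0.5;
  return thick;
}

// 26-connected component labelling; labels 1..k in scan order, 0 background.
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t n = (size_t)nx * ny * nz;
  IntegerVector lab(n);
  int next = 0;
  std::vector<size_t> queue;
  for (size_t s = 0; s < n; s++) {
    if (!mask[s] || lab[s]) continue;
    next++;
    lab[s] = next;
    queue.clear();
    queue.push_back(s);
    while (!queue.empty()) {
      size_t cur = queue.back();
      queue.pop_back();
      int i = cur % nx;
      int j = (cur / nx) % ny;
      int k = cur / ((size_t)nx * ny);
      for (int dk = -1; dk <= 1; dk++)
        for (int dj = -1; dj <= 1; dj++)
          for (int di = -1; di <= 1; di++) {
            if (!di && !dj && !dk) continue;
            int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
              continue;
            size_t t = ii + nx * (jj + (size_t)ny * kk);
            if (mask[t] && !lab[t]) {
              lab[t] = next;
              queue.push_back(t);
            }
          }
    }
  }
  return lab;
}

static inline double seg_dist2(double px, double py, double pz,
                               double x1, double y1, double z1,
                               double x2, double y2, double z2) {
  double vx = x2 - x1, vy = y2 - y1, vz = z2 - z1;
  double wx = px - x1, wy = py - y1, wz = pz - z1;
  double vv = vx * vx + vy * vy + vz * vz;
  double t = vv > 0 ? (wx * vx + wy * vy + wz * vz) / vv : 0.0;
  if (t < 0) t = 0;
  if (t > 1) t = 1;
  double dx = wx - t * vx, dy = wy - t * vy, dz = wz - t * vz;
  return dx * dx + dy * dy + dz * dz;
}

// Occupancy rasterizer for the synthetic vertebra: a hollow tube along axis 0
// with tapered endplate flare (both radii shift outward linearly, reaching
// flare_offset at the tube ends over the last flare_len) plus capsule
// struts. Coordinates in um, voxel centers at index*h. Returns per-voxel
// occupied fraction over ss^3 samples.
// tube = (cx, cy, cz, half_len, r_out, r_in, flare_offset, flare_len)
// capsules: rows (x1,y1,z1,x2,y2,z2,radius)
// [[Rcpp::export]]
NumericVector rasterize_vertebra_cpp(IntegerVector dims, double h, int ss,
                                     NumericVector tube,
                                     NumericMatrix capsules) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double cx = tube[0], cy = tube[1], cz = tube[2];
  const double half_len = tube[3], r_out = tube[4], r_in = tube[5];
  const double flare_off = tube[6], flare_len = tube[7];
  const int nc = capsules.nrow();
  NumericVector out((size_t)nx * ny * nz);
  const double inv = 1.0 / ss;
  const int ns = ss * ss * ss;
  std::vector<double> off(ss);
  for (int a = 0; a < ss; a++) off[a] = ((a + 0.5) * inv - 0.5) * h;
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++) {
        int hit = 0;
        for (int ak = 0; ak < ss; ak++)
          for (int aj = 0; aj < ss; aj++)
            for (int ai = 0; ai < ss; ai++) {
              double x = i * h + off[ai];
              double y = j * h + off[aj];
              double z = k * h + off[ak];
              bool inside = false;
              double ax = std::fabs(x - cx);
              if (ax <= half_len) {
                double ro = r_out, ri = r_in;
                if (flare_len > 0 && half_len - ax < flare_len) {
                  double u = (ax - (half_len - flare_len)) / flare_len;
                  ro += flare_off * u;
                  ri += flare_off * u;
                }
                double rho2 = (y - cy) * (y - cy) + (z - cz) * (z - cz);
                if (rho2 <= ro * ro && rho2 >= ri * ri) inside = true;
              }
              for (int c = 0; !inside && c < nc; c++) {
                double rr = capsules(c, 6);
                if (seg_dist2(x, y, z, capsules(c, 0), capsules(c, 1),
                              capsules(c, 2), capsules(c, 3), capsules(c, 4),
                              capsules(c, 5)) <= rr * rr)
                  inside = true;
              }
              if (inside) hit++;
            }
        out[i + nx * (j + (size_t)ny * k)] = (double)hit / ns;
      }
  return out;
}
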