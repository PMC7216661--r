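#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Volumes are R arrays with dim = c(nz, ny, nx); linear index
// z + nz * (y + ny * x), all zero-based here.

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// 3-D median filter with cubic k x k x k neighbourhood, edge replication
// (border voxels reuse the nearest in-volume voxel).
// [[Rcpp::export]]
NumericVector median3d_cpp(NumericVector vol, IntegerVector dim, int k) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const int r = (k - 1) / 2;
  const int kk = k * k * k;
  NumericVector out(vol.size());
  std::vector<double> buf(kk);
  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) {
      for (int z = 0; z < nz; ++z) {
        int m = 0;
        for (int dx = -r; dx <= r; ++dx) {
          const int xx = clampi(x + dx, 0, nx - 1);
          for (int dy = -r; dy <= r; ++dy) {
            const int yy = clampi(y + dy, 0, ny - 1);
            const R_xlen_t base = (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
            for (int dz = -r; dz <= r; ++dz) {
              const int zz = clampi(z + dz, 0, nz - 1);
              buf[m++] = vol[base + zz];
            }
          }
        }
        std::nth_element(buf.begin(), buf.begin() + kk / 2, buf.begin() + kk);
        double med = buf[kk / 2];
        if (kk % 2 == 0) { // even k never used in practice but keep exact
          double lo = *std::max_element(buf.begin(), buf.begin() + kk / 2);
          med = 0.5 * (lo + med);
        }
        out[z + (R_xlen_t)nz * (y + (R_xlen_t)ny * x)] = med;
      }
    }
  }
  return out;
}

// k x k box (mean) blur of one slice (ny x nx matrix), edge replication,
// via an integral image over the replicated padding.
// [[Rcpp::export]]
NumericMatrix box_blur_cpp(NumericMatrix slice, int k) {
  const int ny = slice.nrow(), nx = slice.ncol();
  const int r = (k - 1) / 2;
  const int py = ny + 2 * r, px = nx + 2 * r;
  // integral image with one extra leading row/col of zeros
  std::vector<double> I((py + 1) * (size_t)(px + 1), 0.0);
  for (int j = 0; j < px; ++j) {
    const int sj = clampi(j - r, 0, nx - 1);
    for (int i = 0; i < py; ++i) {
      const int si = clampi(i - r, 0, ny - 1);
      I[(i + 1) + (size_t)(py + 1) * (j + 1)] =
        slice(si, sj) +
        I[i + (size_t)(py + 1) * (j + 1)] +
        I[(i + 1) + (size_t)(py + 1) * j] -
        I[i + (size_t)(py + 1) * j];
    }
  }
  NumericMatrix out(ny, nx);
  const double area = (double)k * (double)k;
  for (int j = 0; j < nx; ++j) {
    for (int i = 0; i < ny; ++i) {
      // window in padded coords: rows i .. i+2r, cols j .. j+2r
      const int i0 = i, i1 = i + 2 * r + 1;
      const int j0 = j, j1 = j + 2 * r + 1;
      out(i, j) = (I[i1 + (size_t)(py + 1) * j1] - I[i0 + (size_t)(py + 1) * j1] -
                   I[i1 + (size_t)(py + 1) * j0] + I[i0 + (size_t)(py + 1) * j0]) / area;
    }
  }
  return out;
}

// 3-D connected-component labelling of a binary mask under 6/18/26
// connectivity. Returns integer labels (0 = background), label ids are
// assigned in raster-scan order of each component's first voxel.
// [[Rcpp::export]]
IntegerVector label3d_cpp(LogicalVector mask, IntegerVector dim, int connectivity) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  std::vector<int> off_z, off_y, off_x;
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz) {
        const int d = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (d == 0) continue;
        if ((connectivity == 6 && d > 1) || (connectivity == 18 && d > 2)) continue;
        off_z.push_back(dz); off_y.push_back(dy); off_x.push_back(dx);
      }
  const int noff = (int)off_z.size();
  IntegerVector labels(mask.size(), 0);
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t idx = 0; idx < mask.size(); ++idx) {
    if (!mask[idx] || labels[idx] != 0) continue;
    ++next;
    labels[idx] = next;
    stack.clear();
    stack.push_back(idx);
    while (!stack.empty()) {
      const R_xlen_t cur = stack.back();
      stack.pop_back();
      const int z = (int)(cur % nz);
      const int y = (int)((cur / nz) % ny);
      const int x = (int)(cur / ((R_xlen_t)nz * ny));
      for (int o = 0; o < noff; ++o) {
        const int zz = z + off_z[o], yy = y + off_y[o], xx = x + off_x[o];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
        const R_xlen_t nidx = zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
        if (mask[nidx] && labels[nidx] == 0) {
          labels[nidx] = next;
          stack.push_back(nidx);
        }
      }
    }
  }
  return labels;
}

static inline double seg_dist2(double px, double py, double pz,
                               double ax, double ay, double az,
                               double bx, double by, double bz) {
  const double vx = bx - ax, vy = by - ay, vz = bz - az;
  const double wx = px - ax, wy = py - ay, wz = pz - az;
  const double vv = vx * vx + vy * vy + vz * vz;
  double t = vv > 0 ? (wx * vx + wy * vy + wz * vz) / vv : 0.0;
  if (t < 0) t = 0; else if (t > 1) t = 1;
  const double dx = wx - t * vx, dy = wy - t * vy, dz = wz - t * vz;
  return dx * dx + dy * dy + dz * dz;
}

// Volume fraction of each voxel occupied by a union of capsules
// (tube segments with hemispherical caps). Segments are rows
// (x0, y0, z0, x1, y1, z1, radius) in voxel units; voxel (z, y, x)
// spans [x, x+1) etc. Fractions are estimated on an ss^3 subvoxel grid.
// [[Rcpp::export]]
NumericVector tube_fractions_cpp(NumericMatrix segments, IntegerVector dim, int ss) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t nsub = (R_xlen_t)nz * ny * nx * (R_xlen_t)ss * ss * ss;
  if (nsub > (R_xlen_t)2e9) stop("supersampled grid too large");
  const int sz = nz * ss, sy = ny * ss, sx = nx * ss;
  std::vector<unsigned char> hit((size_t)nsub, 0);
  for (int s = 0; s < segments.nrow(); ++s) {
    const double ax = segments(s, 0), ay = segments(s, 1), az = segments(s, 2);
    const double bx = segments(s, 3), by = segments(s, 4), bz = segments(s, 5);
    const double r = segments(s, 6);
    const double r2 = r * r;
    const int x0 = clampi((int)std::floor((std::min(ax, bx) - r) * ss), 0, sx - 1);
    const int x1 = clampi((int)std::ceil((std::max(ax, bx) + r) * ss), 0, sx - 1);
    const int y0 = clampi((int)std::floor((std::min(ay, by) - r) * ss), 0, sy - 1);
    const int y1 = clampi((int)std::ceil((std::max(ay, by) + r) * ss), 0, sy - 1);
    const int z0 = clampi((int)std::floor((std::min(az, bz) - r) * ss), 0, sz - 1);
    const int z1 = clampi((int)std::ceil((std::max(az, bz) + r) * ss), 0, sz - 1);
    for (int xi = x0; xi <= x1; ++xi) {
      const double pxc = (xi + 0.5) / ss;
      for (int yi = y0; yi <= y1; ++yi) {
        const double pyc = (yi + 0.5) / ss;
        for (int zi = z0; zi <= z1; ++zi) {
          const double pzc = (zi + 0.5) / ss;
          if (seg_dist2(pxc, pyc, pzc, ax, ay, az, bx, by, bz) <= r2) {
            hit[(size_t)zi + (size_t)sz * ((size_t)yi + (size_t)sy * xi)] = 1;
          }
        }
      }
    }
  }
  NumericVector frac((R_xlen_t)nz * ny * nx);
  const double inv = 1.0 / ((double)ss * ss * ss);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        int cnt = 0;
        for (int dx = 0; dx < ss; ++dx)
          for (int dy = 0; dy < ss; ++dy)
            for (int dz = 0; dz < ss; ++dz)
              cnt += hit[(size_t)(z * ss + dz) +
                         (size_t)sz * ((size_t)(y * ss + dy) + (size_t)sy * (x * ss + dx))];
        frac[z + (R_xlen_t)nz * (y + (R_xlen_t)ny * x)] = cnt * inv;
      }
  return frac;
}
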