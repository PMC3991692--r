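// 3D image kernels for lamina cribrosa microarchitecture analysis.
// All physical quantities are in micrometres; voxel spacing may be anisotropic.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
#include <limits>
using namespace Rcpp;

static inline size_t idx3(int i, int j, int k, int nx, int ny) {
  return (size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * (size_t)k);
}

// ---------------------------------------------------------------------------
// Exact squared Euclidean distance transform (Felzenszwalb & Huttenlocher),
// generalised to anisotropic spacing: cost along an axis is (w * di)^2.
// Input f: squared distances so far (INF on foreground, 0 on background).
// ---------------------------------------------------------------------------
// Foreground cells carry the sentinel LCM_BIG instead of infinity; any finite
// true distance beats it and the final boundary cap removes leftovers.
static const double LCM_BIG = 1e30;

static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 int n, double w) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  const double INF = std::numeric_limits<double>::infinity();
  double w2 = w * w;
  int k = 0;
  v[0] = 0; z[0] = -INF; z[1] = INF;
  for (int q = 1; q < n; q++) {
    double s;
    while (true) {
      s = ((f[q] + w2 * q * q) - (f[v[k]] + w2 * (double)v[k] * v[k])) /
          (2.0 * w2 * (q - v[k]));
      if (s <= z[k] && k > 0) { k--; } else break;
    }
    if (s <= z[k]) { // k == 0: replace the only parabola
      v[0] = q; z[0] = -INF; z[1] = INF;
    } else {
      k++;
      v[k] = q; z[k] = s; z[k + 1] = INF;
    }
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    double dq = (double)(q - v[k]);
    d[q] = f[v[k]] + w2 * dq * dq;
  }
}

// Squared EDT of `phase` (distance from each foreground voxel to the nearest
// background voxel centre). Voxels outside the array count as background: the
// result is capped by the squared distance to the nearest virtual outside
// voxel centre along each axis.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector phase, IntegerVector dim,
                         NumericVector spacing) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  double dx = spacing[0], dy = spacing[1], dz = spacing[2];
  size_t n = (size_t)nx * ny * nz;
  NumericVector out(n);
  std::vector<double> g(n);
  for (size_t t = 0; t < n; t++) g[t] = phase[t] ? LCM_BIG : 0.0;

  // pass along x
  {
    std::vector<double> f(nx), d(nx);
    for (int k = 0; k < nz; k++)
      for (int j = 0; j < ny; j++) {
        for (int i = 0; i < nx; i++) f[i] = g[idx3(i, j, k, nx, ny)];
        dt1d(f, d, nx, dx);
        for (int i = 0; i < nx; i++) g[idx3(i, j, k, nx, ny)] = d[i];
      }
  }
  // pass along y
  {
    std::vector<double> f(ny), d(ny);
    for (int k = 0; k < nz; k++)
      for (int i = 0; i < nx; i++) {
        for (int j = 0; j < ny; j++) f[j] = g[idx3(i, j, k, nx, ny)];
        dt1d(f, d, ny, dy);
        for (int j = 0; j < ny; j++) g[idx3(i, j, k, nx, ny)] = d[j];
      }
  }
  // pass along z
  {
    std::vector<double> f(nz), d(nz);
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++) {
        for (int k = 0; k < nz; k++) f[k] = g[idx3(i, j, k, nx, ny)];
        dt1d(f, d, nz, dz);
        for (int k = 0; k < nz; k++) g[idx3(i, j, k, nx, ny)] = d[k];
      }
  }
  // cap by distance to virtual outside-array background
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++) {
        size_t t = idx3(i, j, k, nx, ny);
        if (!phase[t]) { out[t] = 0.0; continue; }
        double bx = std::min(i + 1, nx - i) * dx;
        double by = std::min(j + 1, ny - j) * dy;
        double bz = std::min(k + 1, nz - k) * dz;
        double cap = std::min(bx * bx, std::min(by * by, bz * bz));
        out[t] = std::min(g[t], cap);
      }
  return out;
}

// ---------------------------------------------------------------------------
// Local thickness (maximal inscribed sphere): for each phase voxel p,
//   thickness(p) = 2 * max{ r_c : c phase voxel, dist(p,c) < r_c },
// where r_c = sqrt(EDT^2(c)). Computed by painting spheres from a reduced
// (distance-ridge) set of centres; the reduction only removes centres whose
// sphere is provably contained in a neighbour's sphere, so the result equals
// the brute-force definition.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
NumericVector cpp_local_thickness(LogicalVector phase, IntegerVector dim,
                                  NumericVector spacing) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  double dx = spacing[0], dy = spacing[1], dz = spacing[2];
  NumericVector r2v = cpp_edt_sq(phase, dim, spacing);
  size_t n = (size_t)nx * ny * nz;
  NumericVector out(n); // holds max r^2, converted to diameter at the end

  // ridge reduction: drop centre c if a 26-neighbour c' satisfies
  // r_{c'} >= r_c + dist(c,c')  (sphere(c) contained in sphere(c'))
  std::vector<char> keep(n, 0);
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++) {
        size_t t = idx3(i, j, k, nx, ny);
        if (!phase[t]) continue;
        double rc = std::sqrt(r2v[t]);
        bool redundant = false;
        for (int dk = -1; dk <= 1 && !redundant; dk++)
          for (int dj = -1; dj <= 1 && !redundant; dj++)
            for (int di = -1; di <= 1 && !redundant; di++) {
              if (!di && !dj && !dk) continue;
              int ii = i + di, jj = j + dj, kk = k + dk;
              if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
                continue;
              size_t u = idx3(ii, jj, kk, nx, ny);
              if (!phase[u]) continue;
              double dd = std::sqrt(di * di * dx * dx + dj * dj * dy * dy +
                                    dk * dk * dz * dz);
              if (std::sqrt(r2v[u]) >= rc + dd + 1e-9) redundant = true;
            }
        if (!redundant) keep[t] = 1;
      }

  // paint spheres (strict containment: d^2 < r^2)
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++) {
        size_t t = idx3(i, j, k, nx, ny);
        if (!keep[t]) continue;
        double r2 = r2v[t];
        double r = std::sqrt(r2);
        int ri = (int)std::floor(r / dx);
        int rj = (int)std::floor(r / dy);
        int rk = (int)std::floor(r / dz);
        int i0 = std::max(0, i - ri), i1 = std::min(nx - 1, i + ri);
        int j0 = std::max(0, j - rj), j1 = std::min(ny - 1, j + rj);
        int k0 = std::max(0, k - rk), k1 = std::min(nz - 1, k + rk);
        for (int kk = k0; kk <= k1; kk++) {
          double zz = (kk - k) * dz; zz *= zz;
          if (zz >= r2) continue;
          for (int jj = j0; jj <= j1; jj++) {
            double yy = (jj - j) * dy; yy = yy * yy + zz;
            if (yy >= r2) continue;
            for (int ii = i0; ii <= i1; ii++) {
              double xx = (ii - i) * dx; xx = xx * xx + yy;
              if (xx < r2) {
                size_t u = idx3(ii, jj, kk, nx, ny);
                if (r2 > out[u]) out[u] = r2;
              }
            }
          }
        }
      }

  for (size_t t = 0; t < n; t++)
    out[t] = phase[t] ? 2.0 * std::sqrt(out[t]) : 0.0;
  return out;
}

// ---------------------------------------------------------------------------
// 3D median filter over a physical ball of radius_um (ellipsoidal voxel
// neighbourhood on anisotropic grids); window clipped at the borders.
// Returns the floor-median (an existing sample value) of each clipped window.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
NumericVector cpp_median3d(NumericVector vol, IntegerVector dim,
                           NumericVector spacing, double radius_um) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  double dx = spacing[0], dy = spacing[1], dz = spacing[2];
  int rx = (int)std::floor(radius_um / dx);
  int ry = (int)std::floor(radius_um / dy);
  int rz = (int)std::floor(radius_um / dz);
  double r2 = radius_um * radius_um;
  // precompute in-ball offsets
  std::vector<int> ox, oy, oz;
  for (int dk = -rz; dk <= rz; dk++)
    for (int dj = -ry; dj <= ry; dj++)
      for (int di = -rx; di <= rx; di++) {
        double dd = di * di * dx * dx + dj * dj * dy * dy + dk * dk * dz * dz;
        if (dd <= r2) { ox.push_back(di); oy.push_back(dj); oz.push_back(dk); }
      }
  size_t noff = ox.size();
  NumericVector out((size_t)nx * ny * nz);
  std::vector<double> buf;
  buf.reserve(noff);
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++) {
        buf.clear();
        for (size_t t = 0; t < noff; t++) {
          int ii = i + ox[t], jj = j + oy[t], kk = k + oz[t];
          if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
            continue;
          buf.push_back(vol[idx3(ii, jj, kk, nx, ny)]);
        }
        size_t m = (buf.size() - 1) / 2;
        std::nth_element(buf.begin(), buf.begin() + m, buf.end());
        out[idx3(i, j, k, nx, ny)] = buf[m];
      }
  return out;
}

// ---------------------------------------------------------------------------
// Separable box sum with border clipping: out[p] = sum of vol over the
// (2rx+1)x(2ry+1)x(2rz+1) window intersected with the array.
// ---------------------------------------------------------------------------
static void boxsum1d(std::vector<double>& g, int nx, int ny, int nz,
                     int axis, int r) {
  if (r <= 0) return;
  int n = (axis == 0) ? nx : (axis == 1) ? ny : nz;
  std::vector<double> line(n), cum(n + 1);
  int outer1, outer2;
  if (axis == 0) { outer1 = ny; outer2 = nz; }
  else if (axis == 1) { outer1 = nx; outer2 = nz; }
  else { outer1 = nx; outer2 = ny; }
  for (int b = 0; b < outer2; b++)
    for (int a = 0; a < outer1; a++) {
      for (int q = 0; q < n; q++) {
        size_t t = (axis == 0) ? idx3(q, a, b, nx, ny)
                 : (axis == 1) ? idx3(a, q, b, nx, ny)
                               : idx3(a, b, q, nx, ny);
        line[q] = g[t];
      }
      cum[0] = 0.0;
      for (int q = 0; q < n; q++) cum[q + 1] = cum[q] + line[q];
      for (int q = 0; q < n; q++) {
        int lo = std::max(0, q - r), hi = std::min(n - 1, q + r);
        double s = cum[hi + 1] - cum[lo];
        size_t t = (axis == 0) ? idx3(q, a, b, nx, ny)
                 : (axis == 1) ? idx3(a, q, b, nx, ny)
                               : idx3(a, b, q, nx, ny);
        g[t] = s;
      }
    }
}

// [[Rcpp::export]]
NumericVector cpp_box_sum(NumericVector vol, IntegerVector dim,
                          IntegerVector radius) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  std::vector<double> g(n);
  for (size_t t = 0; t < n; t++) g[t] = vol[t];
  boxsum1d(g, nx, ny, nz, 0, radius[0]);
  boxsum1d(g, nx, ny, nz, 1, radius[1]);
  boxsum1d(g, nx, ny, nz, 2, radius[2]);
  NumericVector out(n);
  for (size_t t = 0; t < n; t++) out[t] = g[t];
  return out;
}

// ---------------------------------------------------------------------------
// Connected-component labelling, 26-connectivity in 3D (pass nz = 1 with
// conn8 semantics for 2D slices: the dk loop simply never moves).
// Labels are 1..n_components in scan order; background = 0.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  IntegerVector lab(n);
  std::vector<size_t> stack;
  int next = 0;
  for (size_t s = 0; s < n; s++) {
    if (!mask[s] || lab[s]) continue;
    next++;
    lab[s] = next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      size_t t = stack.back(); stack.pop_back();
      int i = (int)(t % nx);
      int j = (int)((t / nx) % ny);
      int k = (int)(t / ((size_t)nx * ny));
      for (int dk = -1; dk <= 1; dk++)
        for (int dj = -1; dj <= 1; dj++)
          for (int di = -1; di <= 1; di++) {
            if (!di && !dj && !dk) continue;
            int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
              continue;
            size_t u = idx3(ii, jj, kk, nx, ny);
            if (mask[u] && !lab[u]) { lab[u] = next; stack.push_back(u); }
          }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

// Keys cubic convolution kernel (Catmull-Rom, a = -0.5)
static inline double cubw(double t) {
  t = std::fabs(t);
  if (t < 1.0) return 1.5 * t * t * t - 2.5 * t * t + 1.0;
  if (t < 2.0) return -0.5 * t * t * t + 2.5 * t * t - 4.0 * t + 2.0;
  return 0.0;
}

// ---------------------------------------------------------------------------
// Rigid resampling: rotation (degrees) about the slow scanning axis (axis 2)
// through the physical volume centre, followed by a translation given in
// voxels. method 0 = nearest neighbour, 1 = trilinear, 2 = tricubic
// (Catmull-Rom; near-flat frequency response, for smooth fields). Inverse
// mapping; out-of-volume samples get `fill`.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
NumericVector cpp_rigid_resample(NumericVector vol, IntegerVector dim,
                                 NumericVector spacing, double angle_deg,
                                 NumericVector shift_vox, int method,
                                 double fill, int clamp_edges) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  double dx = spacing[0], dy = spacing[1], dz = spacing[2];
  double th = angle_deg * M_PI / 180.0;
  double c = std::cos(th), s = std::sin(th);
  double cx = 0.5 * (nx - 1), cy = 0.5 * (ny - 1), cz = 0.5 * (nz - 1);
  double tx = shift_vox[0], ty = shift_vox[1], tz = shift_vox[2];
  NumericVector out((size_t)nx * ny * nz);
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++) {
        // physical coords relative to centre, after removing the shift
        double px = (i - tx - cx) * dx;
        double py = (j - ty - cy) * dy;
        double pz = (k - tz - cz) * dz;
        // inverse rotation in the (fast, axial) plane
        double qx =  c * px + s * pz;
        double qz = -s * px + c * pz;
        double si = qx / dx + cx, sj = py / dy + cy, sk = qz / dz + cz;
        if (clamp_edges) {
          // tissue continues beyond the scanned cube: extend edge values
          si = std::min((double)(nx - 1), std::max(0.0, si));
          sj = std::min((double)(ny - 1), std::max(0.0, sj));
          sk = std::min((double)(nz - 1), std::max(0.0, sk));
        }
        double val = fill;
        if (method == 2) {
          int i0 = (int)std::floor(si), j0 = (int)std::floor(sj),
              k0 = (int)std::floor(sk);
          if (i0 >= 1 && j0 >= 1 && k0 >= 1 &&
              i0 + 2 < nx && j0 + 2 < ny && k0 + 2 < nz) {
            double fx = si - i0, fy = sj - j0, fz = sk - k0;
            double wx[4], wy[4], wz[4];
            for (int t = 0; t < 4; t++) {
              wx[t] = cubw(fx - (t - 1));
              wy[t] = cubw(fy - (t - 1));
              wz[t] = cubw(fz - (t - 1));
            }
            double v = 0.0;
            for (int dk = 0; dk < 4; dk++)
              for (int dj = 0; dj < 4; dj++) {
                double wjk = wy[dj] * wz[dk];
                for (int di = 0; di < 4; di++)
                  v += wx[di] * wjk *
                       vol[idx3(i0 + di - 1, j0 + dj - 1, k0 + dk - 1, nx, ny)];
              }
            val = v;
          } else if (i0 >= 0 && j0 >= 0 && k0 >= 0 &&
                     i0 + 1 < nx && j0 + 1 < ny && k0 + 1 < nz) {
            // fall back to trilinear in the one-voxel border band
            double fx = si - i0, fy = sj - j0, fz = sk - k0;
            double v = 0.0;
            for (int dk = 0; dk <= 1; dk++)
              for (int dj = 0; dj <= 1; dj++)
                for (int di = 0; di <= 1; di++) {
                  double w = (di ? fx : 1 - fx) * (dj ? fy : 1 - fy) *
                             (dk ? fz : 1 - fz);
                  v += w * vol[idx3(i0 + di, j0 + dj, k0 + dk, nx, ny)];
                }
            val = v;
          }
        } else if (method == 0) {
          int ii = (int)std::lround(si), jj = (int)std::lround(sj),
              kk = (int)std::lround(sk);
          if (ii >= 0 && jj >= 0 && kk >= 0 && ii < nx && jj < ny && kk < nz)
            val = vol[idx3(ii, jj, kk, nx, ny)];
        } else {
          int i0 = (int)std::floor(si), j0 = (int)std::floor(sj),
              k0 = (int)std::floor(sk);
          if (i0 >= 0 && j0 >= 0 && k0 >= 0 &&
              i0 + 1 < nx && j0 + 1 < ny && k0 + 1 < nz) {
            double fx = si - i0, fy = sj - j0, fz = sk - k0;
            double v = 0.0;
            for (int dk = 0; dk <= 1; dk++)
              for (int dj = 0; dj <= 1; dj++)
                for (int di = 0; di <= 1; di++) {
                  double w = (di ? fx : 1 - fx) * (dj ? fy : 1 - fy) *
                             (dk ? fz : 1 - fz);
                  v += w * vol[idx3(i0 + di, j0 + dj, k0 + dk, nx, ny)];
                }
            val = v;
          } else if (i0 >= -1 && j0 >= -1 && k0 >= -1 &&
                     i0 < nx && j0 < ny && k0 < nz) {
            // border cell: clamp the missing corner to the nearest sample
            int ii = std::min(nx - 1, std::max(0, (int)std::lround(si)));
            int jj = std::min(ny - 1, std::max(0, (int)std::lround(sj)));
            int kk = std::min(nz - 1, std::max(0, (int)std::lround(sk)));
            val = vol[idx3(ii, jj, kk, nx, ny)];
          }
        }
        out[idx3(i, j, k, nx, ny)] = val;
      }
  out.attr("dim") = dim;
  return out;
}
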