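#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

// Trilinear interpolation of a 3D array at continuous 0-based index
// coordinates. Points outside the grid return `fill`.
static inline double tri_at(const double* v, int nx, int ny, int nz,
                            double x, double y, double z, double fill) {
  if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1)
    return fill;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  if (x0 == nx - 1) x0--;
  if (y0 == ny - 1) y0--;
  if (z0 == nz - 1) z0--;
  double fx = x - x0, fy = y - y0, fz = z - z0;
  const int sx = 1, sy = nx, sz = nx * ny;
  const double* p = v + x0 * sx + y0 * sy + z0 * sz;
  double c00 = p[0] * (1 - fx) + p[sx] * fx;
  double c10 = p[sy] * (1 - fx) + p[sy + sx] * fx;
  double c01 = p[sz] * (1 - fx) + p[sz + sx] * fx;
  double c11 = p[sz + sy] * (1 - fx) + p[sz + sy + sx] * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// [[Rcpp::export(name = ".trilinear_cpp")]]
NumericVector trilinear_cpp(NumericVector vol, IntegerVector dim,
                            NumericMatrix idx, double fill) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int n = idx.nrow();
  NumericVector out(n);
  const double* v = REAL(vol);
  for (int i = 0; i < n; i++)
    out[i] = tri_at(v, nx, ny, nz, idx(i, 0), idx(i, 1), idx(i, 2), fill);
  return out;
}

// Nearest-neighbour interpolation at continuous 0-based index coordinates.
// [[Rcpp::export(name = ".nearest_cpp")]]
NumericVector nearest_cpp(NumericVector vol, IntegerVector dim,
                          NumericMatrix idx, double fill) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int n = idx.nrow();
  NumericVector out(n);
  const double* v = REAL(vol);
  for (int i = 0; i < n; i++) {
    int x = (int)std::lround(idx(i, 0));
    int y = (int)std::lround(idx(i, 1));
    int z = (int)std::lround(idx(i, 2));
    if (x < 0 || y < 0 || z < 0 || x >= nx || y >= ny || z >= nz)
      out[i] = fill;
    else
      out[i] = v[x + nx * (y + (R_xlen_t)ny * z)];
  }
  return out;
}

// Fixed-step ray marching with trilinear sampling. Rays are given in
// continuous 0-based index space of the volume: `orig` (n x 3) starting
// points and one shared direction `dir` (index-space step of length 1 in
// world units already folded in by the caller). Each ray accumulates
// sum(mu_sample) * step_world over nsteps samples; samples outside the
// volume contribute 0.
// [[Rcpp::export(name = ".ray_march_cpp")]]
NumericVector ray_march_cpp(NumericVector vol, IntegerVector dim,
                            NumericMatrix orig, NumericVector dir,
                            int nsteps, double step_world) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int n = orig.nrow();
  NumericVector out(n);
  const double* v = REAL(vol);
  double dx = dir[0], dy = dir[1], dz = dir[2];
  for (int i = 0; i < n; i++) {
    double x = orig(i, 0), y = orig(i, 1), z = orig(i, 2);
    double acc = 0.0;
    for (int s = 0; s < nsteps; s++) {
      acc += tri_at(v, nx, ny, nz, x, y, z, 0.0);
      x += dx; y += dy; z += dz;
    }
    out[i] = acc * step_world;
  }
  return out;
}

// For each row of A, the Euclidean distance to its nearest neighbour in B,
// via a uniform-grid spatial hash over B. Exact: the search ring expands
// until the best distance is certified against the next ring's lower bound.
// [[Rcpp::export(name = ".nn_min_dist_cpp")]]
NumericVector nn_min_dist_cpp(NumericMatrix A, NumericMatrix B) {
  int n = A.nrow(), m = B.nrow();
  NumericVector out(n);
  if (m == 0) { std::fill(out.begin(), out.end(), NA_REAL); return out; }
  double lo[3], hi[3];
  for (int d = 0; d < 3; d++) {
    lo[d] = hi[d] = B(0, d);
    for (int j = 1; j < m; j++) {
      if (B(j, d) < lo[d]) lo[d] = B(j, d);
      if (B(j, d) > hi[d]) hi[d] = B(j, d);
    }
  }
  // target ~2 points per cell
  double vol = 1.0;
  for (int d = 0; d < 3; d++) vol *= std::max(hi[d] - lo[d], 1e-9);
  double cell = std::cbrt(vol * 2.0 / m);
  if (!(cell > 0) || !std::isfinite(cell)) cell = 1.0;
  int ncell[3];
  for (int d = 0; d < 3; d++) {
    ncell[d] = std::max(1, (int)std::floor((hi[d] - lo[d]) / cell) + 1);
    ncell[d] = std::min(ncell[d], 128);
  }
  double csz[3];
  for (int d = 0; d < 3; d++)
    csz[d] = std::max((hi[d] - lo[d]) / ncell[d], 1e-12);
  R_xlen_t ntot = (R_xlen_t)ncell[0] * ncell[1] * ncell[2];
  std::vector<std::vector<int> > buckets(ntot);
  auto cidx = [&](double x, int d) {
    int c = (int)std::floor((x - lo[d]) / csz[d]);
    if (c < 0) c = 0;
    if (c >= ncell[d]) c = ncell[d] - 1;
    return c;
  };
  for (int j = 0; j < m; j++) {
    int cx = cidx(B(j, 0), 0), cy = cidx(B(j, 1), 1), cz = cidx(B(j, 2), 2);
    buckets[cx + (R_xlen_t)ncell[0] * (cy + (R_xlen_t)ncell[1] * cz)].push_back(j);
  }
  double cmin = std::min(std::min(csz[0], csz[1]), csz[2]);
  int rmax = std::max(std::max(ncell[0], ncell[1]), ncell[2]);
  for (int i = 0; i < n; i++) {
    double px = A(i, 0), py = A(i, 1), pz = A(i, 2);
    int cx = cidx(px, 0), cy = cidx(py, 1), cz = cidx(pz, 2);
    double best = std::numeric_limits<double>::infinity();
    for (int r = 0; r <= rmax; r++) {
      // certification: any point in a ring at radius r is at least
      // (r - 1) * cmin away (p may sit anywhere inside its own cell)
      if (r > 0 && best <= (double)(r - 1) * cmin) break;
      bool any = false;
      for (int ax = std::max(0, cx - r); ax <= std::min(ncell[0] - 1, cx + r); ax++)
        for (int ay = std::max(0, cy - r); ay <= std::min(ncell[1] - 1, cy + r); ay++)
          for (int az = std::max(0, cz - r); az <= std::min(ncell[2] - 1, cz + r); az++) {
            if (std::max(std::abs(ax - cx),
                         std::max(std::abs(ay - cy), std::abs(az - cz))) != r)
              continue;  // shell only
            any = true;
            const std::vector<int>& bk =
              buckets[ax + (R_xlen_t)ncell[0] * (ay + (R_xlen_t)ncell[1] * az)];
            for (size_t t = 0; t < bk.size(); t++) {
              int j = bk[t];
              double ddx = px - B(j, 0), ddy = py - B(j, 1), ddz = pz - B(j, 2);
              double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
              if (d2 < best * best) best = std::sqrt(d2);
            }
          }
      if (!any && r > rmax) break;
    }
    out[i] = best;
  }
  return out;
}

// Bilinear sampling of a 2D image at continuous 0-based index coordinates.
// [[Rcpp::export(name = ".bilinear_cpp")]]
NumericVector bilinear_cpp(NumericMatrix img, NumericVector xs,
                           NumericVector ys, double fill) {
  int nx = img.nrow(), ny = img.ncol();
  int n = xs.size();
  NumericVector out(n);
  for (int i = 0; i < n; i++) {
    double x = xs[i], y = ys[i];
    if (x < 0 || y < 0 || x > nx - 1 || y > ny - 1) { out[i] = fill; continue; }
    int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
    if (x0 == nx - 1) x0--;
    if (y0 == ny - 1) y0--;
    double fx = x - x0, fy = y - y0;
    out[i] = img(x0, y0) * (1 - fx) * (1 - fy) + img(x0 + 1, y0) * fx * (1 - fy) +
             img(x0, y0 + 1) * (1 - fx) * fy + img(x0 + 1, y0 + 1) * fx * fy;
  }
  return out;
}

// Fused in-place Adam update: p, m, v are modified directly (single pass,
// no temporaries) — the R-level optimizer state owns these arrays.
// [[Rcpp::export(name = ".adam_update_cpp")]]
void adam_update_cpp(NumericVector p, NumericVector g, NumericVector m,
                     NumericVector v, double lr, double beta1, double beta2,
                     double eps, double bc1, double bc2) {
  R_xlen_t n = p.size();
  double* pp = REAL(p);
  const double* pg = REAL(g);
  double* pm = REAL(m);
  double* pv = REAL(v);
  for (R_xlen_t i = 0; i < n; i++) {
    double gi = pg[i];
    pm[i] = beta1 * pm[i] + (1 - beta1) * gi;
    pv[i] = beta2 * pv[i] + (1 - beta2) * gi * gi;
    pp[i] -= lr * (pm[i] / bc1) / (std::sqrt(pv[i] / bc2) + eps);
  }
}
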