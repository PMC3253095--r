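#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Trilinear interpolation at continuous 1-based voxel coords.
static inline double interp_tri(const double *v, int nx, int ny, int nz,
                                double x, double y, double z) {
  int ix = (int)std::floor(x), iy = (int)std::floor(y), iz = (int)std::floor(z);
  double fx = x - ix, fy = y - iy, fz = z - iz;
  // clamp the 2-cell neighbourhood
  int x0 = std::min(std::max(ix, 1), nx), x1 = std::min(x0 + 1, nx);
  int y0 = std::min(std::max(iy, 1), ny), y1 = std::min(y0 + 1, ny);
  int z0 = std::min(std::max(iz, 1), nz), z1 = std::min(z0 + 1, nz);
  if (ix < 1) fx = 0.0;
  if (iy < 1) fy = 0.0;
  if (iz < 1) fz = 0.0;
  size_t sxy = (size_t)nx * ny;
#define V(a, b, c) v[(size_t)((a)-1) + (size_t)nx * ((b)-1) + sxy * ((c)-1)]
  double c00 = V(x0, y0, z0) * (1 - fx) + V(x1, y0, z0) * fx;
  double c10 = V(x0, y1, z0) * (1 - fx) + V(x1, y1, z0) * fx;
  double c01 = V(x0, y0, z1) * (1 - fx) + V(x1, y0, z1) * fx;
  double c11 = V(x0, y1, z1) * (1 - fx) + V(x1, y1, z1) * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// Catmull-Rom weights for fractional offset t
static inline void cr_w(double t, double w[4]) {
  double t2 = t * t, t3 = t2 * t;
  w[0] = 0.5 * (-t3 + 2 * t2 - t);
  w[1] = 0.5 * (3 * t3 - 5 * t2 + 2);
  w[2] = 0.5 * (-3 * t3 + 4 * t2 + t);
  w[3] = 0.5 * (t3 - t2);
}

static inline int clampi(int i, int lo, int hi) {
  return i < lo ? lo : (i > hi ? hi : i);
}

// Cubic (Catmull-Rom spline) interpolation; neighbours clamped at borders.
static inline double interp_cr(const double *v, int nx, int ny, int nz,
                               double x, double y, double z) {
  int ix = (int)std::floor(x), iy = (int)std::floor(y), iz = (int)std::floor(z);
  double wx[4], wy[4], wz[4];
  cr_w(x - ix, wx);
  cr_w(y - iy, wy);
  cr_w(z - iz, wz);
  size_t sxy = (size_t)nx * ny;
  double acc = 0.0;
  for (int c = 0; c < 4; ++c) {
    int zz = clampi(iz - 1 + c, 1, nz);
    double accy = 0.0;
    for (int b = 0; b < 4; ++b) {
      int yy = clampi(iy - 1 + b, 1, ny);
      const double *row = v + (size_t)nx * (yy - 1) + sxy * (zz - 1);
      double accx = 0.0;
      for (int a = 0; a < 4; ++a) {
        int xx = clampi(ix - 1 + a, 1, nx);
        accx += wx[a] * row[xx - 1];
      }
      accy += wy[b] * accx;
    }
    acc += wz[c] * accy;
  }
  return acc;
}

// Resample `vol` on its own grid through the affine map q = A p + b, where
// p is the output voxel position in centre-origin mm coordinates and q is
// the input-space sampling position (same convention). `order` 1 = trilinear,
// 3 = cubic Catmull-Rom. Points outside the field of view get `background`.
// [[Rcpp::export]]
NumericVector c_resample_affine(NumericVector vol, IntegerVector dim,
                                NumericMatrix A, NumericVector b,
                                NumericVector vox, int order,
                                double background) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  double cx = 0.5 * (nx + 1), cy = 0.5 * (ny + 1), cz = 0.5 * (nz + 1);
  double vx = vox[0], vy = vox[1], vz = vox[2];
  NumericVector out((size_t)nx * ny * nz);
  const double *v = vol.begin();
  double *o = out.begin();
  size_t idx = 0;
  for (int k = 1; k <= nz; ++k) {
    double pz = (k - cz) * vz;
    for (int j = 1; j <= ny; ++j) {
      double py = (j - cy) * vy;
      for (int i = 1; i <= nx; ++i, ++idx) {
        double px = (i - cx) * vx;
        double qx = A(0, 0) * px + A(0, 1) * py + A(0, 2) * pz + b[0];
        double qy = A(1, 0) * px + A(1, 1) * py + A(1, 2) * pz + b[1];
        double qz = A(2, 0) * px + A(2, 1) * py + A(2, 2) * pz + b[2];
        double xi = qx / vx + cx, yi = qy / vy + cy, zi = qz / vz + cz;
        if (xi < 1 || xi > nx || yi < 1 || yi > ny || zi < 1 || zi > nz) {
          o[idx] = background;
        } else if (order == 1) {
          o[idx] = interp_tri(v, nx, ny, nz, xi, yi, zi);
        } else {
          o[idx] = interp_cr(v, nx, ny, nz, xi, yi, zi);
        }
      }
    }
  }
  out.attr("dim") = dim;
  return out;
}

// Mean squared difference between `ref` and `vol` resampled through the
// map, scored over a fixed interior margin of the output grid. The scored
// voxel set is independent of the transform parameters (a parameter-
// dependent set would let the optimiser push high-error edge voxels out of
// view); within it, out-of-field samples honestly compare `background`
// against the reference.
// [[Rcpp::export]]
double c_msd_affine(NumericVector vol, NumericVector ref, IntegerVector dim,
                    NumericMatrix A, NumericVector b, NumericVector vox,
                    double background, int order, IntegerVector margin) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int mx = margin[0], my = margin[1], mz = margin[2];
  double cx = 0.5 * (nx + 1), cy = 0.5 * (ny + 1), cz = 0.5 * (nz + 1);
  double vx = vox[0], vy = vox[1], vz = vox[2];
  const double *v = vol.begin();
  const double *r = ref.begin();
  size_t sxy = (size_t)nx * ny;
  double acc = 0.0;
  size_t n_scored = 0;
  for (int k = 1 + mz; k <= nz - mz; ++k) {
    double pz = (k - cz) * vz;
    for (int j = 1 + my; j <= ny - my; ++j) {
      double py = (j - cy) * vy;
      for (int i = 1 + mx; i <= nx - mx; ++i) {
        double px = (i - cx) * vx;
        double qx = A(0, 0) * px + A(0, 1) * py + A(0, 2) * pz + b[0];
        double qy = A(1, 0) * px + A(1, 1) * py + A(1, 2) * pz + b[1];
        double qz = A(2, 0) * px + A(2, 1) * py + A(2, 2) * pz + b[2];
        double xi = qx / vx + cx, yi = qy / vy + cy, zi = qz / vz + cz;
        double val;
        if (xi < 1 || xi > nx || yi < 1 || yi > ny || zi < 1 || zi > nz)
          val = background;
        else
          val = (order == 1) ? interp_tri(v, nx, ny, nz, xi, yi, zi)
                             : interp_cr(v, nx, ny, nz, xi, yi, zi);
        double d = val - r[(size_t)(i - 1) + (size_t)nx * (j - 1) +
                           sxy * (k - 1)];
        acc += d * d;
        ++n_scored;
      }
    }
  }
  if (n_scored == 0) return R_PosInf;
  return acc / (double)n_scored;
}

// 6-connected component labelling of a 3D logical array.
// Background (FALSE) voxels get label 0.
// [[Rcpp::export]]
IntegerVector c_label3d(LogicalVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz, sxy = (size_t)nx * ny;
  IntegerVector lab(n, 0);
  int next = 0;
  std::queue<size_t> q;
  for (size_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    q.push(s);
    while (!q.empty()) {
      size_t c = q.front();
      q.pop();
      int k = (int)(c / sxy);
      size_t rem = c % sxy;
      int j = (int)(rem / nx);
      int i = (int)(rem % nx);
      const int di[6] = {-1, 1, 0, 0, 0, 0};
      const int dj[6] = {0, 0, -1, 1, 0, 0};
      const int dk[6] = {0, 0, 0, 0, -1, 1};
      for (int m = 0; m < 6; ++m) {
        int ii = i + di[m], jj = j + dj[m], kk = k + dk[m];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
          continue;
        size_t t = (size_t)ii + (size_t)nx * jj + sxy * kk;
        if (mask[t] && lab[t] == 0) {
          lab[t] = next;
          q.push(t);
        }
      }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}
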