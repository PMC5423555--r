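#include <Rcpp.h>
using namespace Rcpp;

// Interpolating samplers for 3-D volumes on 0-based continuous voxel
// coordinates.  All resampling in the package funnels through here.
//
// Conventions:
//  - arr carries a dim attribute (nx, ny, nz), column-major as in R.
//  - fov may be length 0 (treated as all-ones).
//  - A sample is valid when its full linear support lies inside the grid
//    and the (tri-linearly interpolated) FOV density at the point is ~1,
//    so no out-of-FOV value can leak into a voxel reported as valid.
//  - Invalid samples return 0.

static inline double at(const NumericVector &a, int nx, int ny,
                        int i, int j, int k) {
  return a[i + nx * (j + (R_xlen_t)ny * k)];
}

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Keys cubic convolution kernel, a = -0.5 (interpolating, reproduces
// linear ramps exactly away from borders).
static inline void keys_weights(double t, double w[4]) {
  const double a = -0.5;
  double t2 = t * t, t3 = t2 * t;
  w[0] = a * (t3 - 2.0 * t2 + t);
  w[1] = (a + 2.0) * t3 - (a + 3.0) * t2 + 1.0;
  w[2] = -(a + 2.0) * t3 + (2.0 * a + 3.0) * t2 - a * t;
  w[3] = a * (t2 - t3);
}

// [[Rcpp::export]]
List cpp_sample(NumericVector arr, NumericVector fov, NumericMatrix coords,
                int method) {
  IntegerVector d = arr.attr("dim");
  const int nx = d[0], ny = d[1], nz = d[2];
  const R_xlen_t n = coords.nrow();
  const bool hasFov = fov.size() > 0;
  NumericVector out(n);
  LogicalVector valid(n);

  for (R_xlen_t p = 0; p < n; ++p) {
    const double x = coords(p, 0), y = coords(p, 1), z = coords(p, 2);
    if (!R_finite(x) || !R_finite(y) || !R_finite(z)) { valid[p] = false; continue; }

    if (method == 0) {                      // nearest neighbour
      const int i = (int)std::floor(x + 0.5);
      const int j = (int)std::floor(y + 0.5);
      const int k = (int)std::floor(z + 0.5);
      if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) {
        valid[p] = false; continue;
      }
      // the value is reported even when the FOV flags it invalid, so an
      // identity resampling is a bit-exact copy; validity travels in the
      // 'valid' vector
      out[p] = at(arr, nx, ny, i, j, k);
      valid[p] = !(hasFov && at(fov, nx, ny, i, j, k) < 0.5);
      continue;
    }

    // linear / cubic share the unit-cell validity rule
    const int i0 = (int)std::floor(x), j0 = (int)std::floor(y),
              k0 = (int)std::floor(z);
    if (i0 < 0 || j0 < 0 || k0 < 0 ||
        i0 + 1 >= nx || j0 + 1 >= ny || k0 + 1 >= nz) {
      // allow sampling exactly on the upper boundary
      if (x < 0 || y < 0 || z < 0 ||
          x > nx - 1.0 || y > ny - 1.0 || z > nz - 1.0) {
        valid[p] = false; continue;
      }
    }
    const int i1 = std::min(i0 + 1, nx - 1), j1 = std::min(j0 + 1, ny - 1),
              k1 = std::min(k0 + 1, nz - 1);
    const int ia = clampi(i0, 0, nx - 1), ja = clampi(j0, 0, ny - 1),
              ka = clampi(k0, 0, nz - 1);
    const double fx = x - i0, fy = y - j0, fz = z - k0;

    bool fovOk = true;
    if (hasFov) {
      double fv =
        at(fov,nx,ny,ia,ja,ka)*(1-fx)*(1-fy)*(1-fz) +
        at(fov,nx,ny,i1,ja,ka)*fx*(1-fy)*(1-fz) +
        at(fov,nx,ny,ia,j1,ka)*(1-fx)*fy*(1-fz) +
        at(fov,nx,ny,i1,j1,ka)*fx*fy*(1-fz) +
        at(fov,nx,ny,ia,ja,k1)*(1-fx)*(1-fy)*fz +
        at(fov,nx,ny,i1,ja,k1)*fx*(1-fy)*fz +
        at(fov,nx,ny,ia,j1,k1)*(1-fx)*fy*fz +
        at(fov,nx,ny,i1,j1,k1)*fx*fy*fz;
      fovOk = fv >= 0.999;
    }

    if (method == 1) {                      // tri-linear
      out[p] =
        at(arr,nx,ny,ia,ja,ka)*(1-fx)*(1-fy)*(1-fz) +
        at(arr,nx,ny,i1,ja,ka)*fx*(1-fy)*(1-fz) +
        at(arr,nx,ny,ia,j1,ka)*(1-fx)*fy*(1-fz) +
        at(arr,nx,ny,i1,j1,ka)*fx*fy*(1-fz) +
        at(arr,nx,ny,ia,ja,k1)*(1-fx)*(1-fy)*fz +
        at(arr,nx,ny,i1,ja,k1)*fx*(1-fy)*fz +
        at(arr,nx,ny,ia,j1,k1)*(1-fx)*fy*fz +
        at(arr,nx,ny,i1,j1,k1)*fx*fy*fz;
      valid[p] = fovOk;
    } else {                                // cubic (Keys), edge-clamped
      double wx[4], wy[4], wz[4];
      keys_weights(fx, wx); keys_weights(fy, wy); keys_weights(fz, wz);
      double acc = 0.0;
      for (int c = 0; c < 4; ++c) {
        const int kk = clampi(k0 - 1 + c, 0, nz - 1);
        double accy = 0.0;
        for (int b = 0; b < 4; ++b) {
          const int jj = clampi(j0 - 1 + b, 0, ny - 1);
          double accx = 0.0;
          for (int a = 0; a < 4; ++a) {
            const int ii = clampi(i0 - 1 + a, 0, nx - 1);
            accx += wx[a] * at(arr, nx, ny, ii, jj, kk);
          }
          accy += wy[b] * accx;
        }
        acc += wz[c] * accy;
      }
      out[p] = acc;
      valid[p] = fovOk;
    }
  }
  return List::create(_["values"] = out, _["valid"] = valid);
}

// Tri-linear sampling of a 3-vector field stored as three arrays; used for
// image-gradient pulls inside the registration inner loop.
// [[Rcpp::export]]
List cpp_sample3(NumericVector ax, NumericVector ay, NumericVector az,
                 NumericMatrix coords) {
  IntegerVector d = ax.attr("dim");
  const int nx = d[0], ny = d[1], nz = d[2];
  const R_xlen_t n = coords.nrow();
  NumericVector gx(n), gy(n), gz(n);
  for (R_xlen_t p = 0; p < n; ++p) {
    const double x = coords(p, 0), y = coords(p, 1), z = coords(p, 2);
    if (!R_finite(x) || x < 0 || y < 0 || z < 0 ||
        x > nx - 1.0 || y > ny - 1.0 || z > nz - 1.0) continue;
    const int i0 = clampi((int)std::floor(x), 0, nx - 1);
    const int j0 = clampi((int)std::floor(y), 0, ny - 1);
    const int k0 = clampi((int)std::floor(z), 0, nz - 1);
    const int i1 = std::min(i0 + 1, nx - 1), j1 = std::min(j0 + 1, ny - 1),
              k1 = std::min(k0 + 1, nz - 1);
    const double fx = x - i0, fy = y - j0, fz = z - k0;
    double w[8] = {
      (1-fx)*(1-fy)*(1-fz), fx*(1-fy)*(1-fz), (1-fx)*fy*(1-fz), fx*fy*(1-fz),
      (1-fx)*(1-fy)*fz,     fx*(1-fy)*fz,     (1-fx)*fy*fz,     fx*fy*fz };
    int ii[8] = {i0,i1,i0,i1,i0,i1,i0,i1};
    int jj[8] = {j0,j0,j1,j1,j0,j0,j1,j1};
    int kk[8] = {k0,k0,k0,k0,k1,k1,k1,k1};
    double sx = 0, sy = 0, sz = 0;
    for (int q = 0; q < 8; ++q) {
      sx += w[q] * at(ax, nx, ny, ii[q], jj[q], kk[q]);
      sy += w[q] * at(ay, nx, ny, ii[q], jj[q], kk[q]);
      sz += w[q] * at(az, nx, ny, ii[q], jj[q], kk[q]);
    }
    gx[p] = sx; gy[p] = sy; gz[p] = sz;
  }
  return List::create(_["x"] = gx, _["y"] = gy, _["z"] = gz);
}

// Separable zero-padded convolution with a symmetric 1-D kernel applied
// along all three axes.  O(n^3 * kernel length) — the workhorse behind
// every Gaussian windowing step.
// [[Rcpp::export]]
NumericVector cpp_conv_sep(NumericVector arr, NumericVector kernel) {
  IntegerVector d = arr.attr("dim");
  const int nx = d[0], ny = d[1], nz = d[2];
  const int klen = kernel.size();
  const int r = (klen - 1) / 2;
  std::vector<double> a(arr.begin(), arr.end());
  std::vector<double> b(a.size());
  const double *kp = kernel.begin();

  // axis 0
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      const R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
      for (int i = 0; i < nx; ++i) {
        double acc = 0.0;
        const int lo = std::max(0, i - r), hi = std::min(nx - 1, i + r);
        for (int p = lo; p <= hi; ++p) acc += kp[p - i + r] * a[base + p];
        b[base + i] = acc;
      }
    }
  std::swap(a, b);
  // axis 1
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      const R_xlen_t base = i + (R_xlen_t)nx * ny * k;
      for (int j = 0; j < ny; ++j) {
        double acc = 0.0;
        const int lo = std::max(0, j - r), hi = std::min(ny - 1, j + r);
        for (int p = lo; p <= hi; ++p)
          acc += kp[p - j + r] * a[base + (R_xlen_t)nx * p];
        b[base + (R_xlen_t)nx * j] = acc;
      }
    }
  std::swap(a, b);
  // axis 2
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      const R_xlen_t base = i + (R_xlen_t)nx * j;
      for (int k = 0; k < nz; ++k) {
        double acc = 0.0;
        const int lo = std::max(0, k - r), hi = std::min(nz - 1, k + r);
        for (int p = lo; p <= hi; ++p) acc += kp[p - k + r] * a[base + nxy * p];
        b[base + nxy * k] = acc;
      }
    }
  NumericVector out(b.begin(), b.end());
  out.attr("dim") = d;
  return out;
}
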