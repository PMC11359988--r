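#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Column-major 3D+channel indexing helpers. Volumes are R arrays with
// dim = (nx, ny, nz) or (nx, ny, nz, nc); flat index = x + nx*(y + ny*(z + nz*c)).

static inline R_xlen_t vidx(int x, int y, int z, int c, int nx, int ny, int nz) {
  return (R_xlen_t)x + (R_xlen_t)nx * ((R_xlen_t)y + (R_xlen_t)ny * ((R_xlen_t)z + (R_xlen_t)nz * c));
}

// im2col for 3D convolution with zero padding.
// x: (nx, ny, nz, cin); returns (k1*k2*k3*cin) x (ox*oy*oz) matrix whose
// row index matches R's column-major flattening of a (k1,k2,k3,cin) weight.
// [[Rcpp::export]]
NumericMatrix cpp_im2col3d(NumericVector x, IntegerVector xdim,
                           IntegerVector k, IntegerVector stride,
                           IntegerVector pad) {
  const int nx = xdim[0], ny = xdim[1], nz = xdim[2], cin = xdim[3];
  const int k1 = k[0], k2 = k[1], k3 = k[2];
  const int s1 = stride[0], s2 = stride[1], s3 = stride[2];
  const int p1 = pad[0], p2 = pad[1], p3 = pad[2];
  const int ox = (nx + 2 * p1 - k1) / s1 + 1;
  const int oy = (ny + 2 * p2 - k2) / s2 + 1;
  const int oz = (nz + 2 * p3 - k3) / s3 + 1;
  const int nrow = k1 * k2 * k3 * cin;
  NumericMatrix out(nrow, (R_xlen_t)ox * oy * oz);
  for (int ozz = 0; ozz < oz; ++ozz) {
    for (int oyy = 0; oyy < oy; ++oyy) {
      for (int oxx = 0; oxx < ox; ++oxx) {
        const R_xlen_t col = (R_xlen_t)oxx + (R_xlen_t)ox * (oyy + (R_xlen_t)oy * ozz);
        double* dst = &out(0, col);
        for (int c = 0; c < cin; ++c) {
          for (int kz = 0; kz < k3; ++kz) {
            const int z = ozz * s3 - p3 + kz;
            for (int ky = 0; ky < k2; ++ky) {
              const int y = oyy * s2 - p2 + ky;
              for (int kx = 0; kx < k1; ++kx) {
                const int xx = oxx * s1 - p1 + kx;
                const int row = kx + k1 * (ky + k2 * (kz + k3 * c));
                if (xx >= 0 && xx < nx && y >= 0 && y < ny && z >= 0 && z < nz)
                  dst[row] = x[vidx(xx, y, z, c, nx, ny, nz)];
              }
            }
          }
        }
      }
    }
  }
  return out;
}

// Scatter-add inverse of im2col: accumulates column gradients back to the
// input gradient array.
// [[Rcpp::export]]
NumericVector cpp_col2im3d(NumericMatrix cols, IntegerVector xdim,
                           IntegerVector k, IntegerVector stride,
                           IntegerVector pad) {
  const int nx = xdim[0], ny = xdim[1], nz = xdim[2], cin = xdim[3];
  const int k1 = k[0], k2 = k[1], k3 = k[2];
  const int s1 = stride[0], s2 = stride[1], s3 = stride[2];
  const int p1 = pad[0], p2 = pad[1], p3 = pad[2];
  const int ox = (nx + 2 * p1 - k1) / s1 + 1;
  const int oy = (ny + 2 * p2 - k2) / s2 + 1;
  const int oz = (nz + 2 * p3 - k3) / s3 + 1;
  NumericVector gx((R_xlen_t)nx * ny * nz * cin);
  for (int ozz = 0; ozz < oz; ++ozz) {
    for (int oyy = 0; oyy < oy; ++oyy) {
      for (int oxx = 0; oxx < ox; ++oxx) {
        const R_xlen_t col = (R_xlen_t)oxx + (R_xlen_t)ox * (oyy + (R_xlen_t)oy * ozz);
        const double* src = &cols(0, col);
        for (int c = 0; c < cin; ++c) {
          for (int kz = 0; kz < k3; ++kz) {
            const int z = ozz * s3 - p3 + kz;
            for (int ky = 0; ky < k2; ++ky) {
              const int y = oyy * s2 - p2 + ky;
              for (int kx = 0; kx < k1; ++kx) {
                const int xx = oxx * s1 - p1 + kx;
                if (xx >= 0 && xx < nx && y >= 0 && y < ny && z >= 0 && z < nz) {
                  const int row = kx + k1 * (ky + k2 * (kz + k3 * c));
                  gx[vidx(xx, y, z, c, nx, ny, nz)] += src[row];
                }
              }
            }
          }
        }
      }
    }
  }
  gx.attr("dim") = xdim;
  return gx;
}

// Trilinear sampling of a (nx,ny,nz,nc) array at continuous voxel coordinates
// (0-based). coords: n x 3 matrix. Points outside [0, n-1] on any axis return
// `fill`. Returns n x nc matrix.
// [[Rcpp::export]]
NumericMatrix cpp_sample_trilinear(NumericVector x, IntegerVector xdim,
                                   NumericMatrix coords, double fill) {
  const int nx = xdim[0], ny = xdim[1], nz = xdim[2], nc = xdim[3];
  const R_xlen_t n = coords.nrow();
  NumericMatrix out(n, nc);
  for (R_xlen_t i = 0; i < n; ++i) {
    const double cx = coords(i, 0), cy = coords(i, 1), cz = coords(i, 2);
    if (cx < 0 || cy < 0 || cz < 0 || cx > nx - 1 || cy > ny - 1 || cz > nz - 1 ||
        !std::isfinite(cx) || !std::isfinite(cy) || !std::isfinite(cz)) {
      for (int c = 0; c < nc; ++c) out(i, c) = fill;
      continue;
    }
    int x0 = (int)std::floor(cx), y0 = (int)std::floor(cy), z0 = (int)std::floor(cz);
    if (x0 == nx - 1) x0--; if (y0 == ny - 1) y0--; if (z0 == nz - 1) z0--;
    if (nx == 1) x0 = 0; if (ny == 1) y0 = 0; if (nz == 1) z0 = 0;
    const int x1 = std::min(x0 + 1, nx - 1), y1 = std::min(y0 + 1, ny - 1),
              z1 = std::min(z0 + 1, nz - 1);
    const double fx = cx - x0, fy = cy - y0, fz = cz - z0;
    for (int c = 0; c < nc; ++c) {
      const double v000 = x[vidx(x0, y0, z0, c, nx, ny, nz)];
      const double v100 = x[vidx(x1, y0, z0, c, nx, ny, nz)];
      const double v010 = x[vidx(x0, y1, z0, c, nx, ny, nz)];
      const double v110 = x[vidx(x1, y1, z0, c, nx, ny, nz)];
      const double v001 = x[vidx(x0, y0, z1, c, nx, ny, nz)];
      const double v101 = x[vidx(x1, y0, z1, c, nx, ny, nz)];
      const double v011 = x[vidx(x0, y1, z1, c, nx, ny, nz)];
      const double v111 = x[vidx(x1, y1, z1, c, nx, ny, nz)];
      const double c00 = v000 * (1 - fx) + v100 * fx;
      const double c10 = v010 * (1 - fx) + v110 * fx;
      const double c01 = v001 * (1 - fx) + v101 * fx;
      const double c11 = v011 * (1 - fx) + v111 * fx;
      const double c0 = c00 * (1 - fy) + c10 * fy;
      const double c1 = c01 * (1 - fy) + c11 * fy;
      out(i, c) = c0 * (1 - fz) + c1 * fz;
    }
  }
  return out;
}

// Gradient of trilinear samples w.r.t. the sampling coordinates (voxel units),
// contracted with the upstream gradient gout (n x nc). Returns n x 3.
// Out-of-bounds points get zero gradient (sample is the constant fill there).
// [[Rcpp::export]]
NumericMatrix cpp_sample_trilinear_grad(NumericVector x, IntegerVector xdim,
                                        NumericMatrix coords,
                                        NumericMatrix gout) {
  const int nx = xdim[0], ny = xdim[1], nz = xdim[2], nc = xdim[3];
  const R_xlen_t n = coords.nrow();
  NumericMatrix g(n, 3);
  for (R_xlen_t i = 0; i < n; ++i) {
    const double cx = coords(i, 0), cy = coords(i, 1), cz = coords(i, 2);
    if (cx < 0 || cy < 0 || cz < 0 || cx > nx - 1 || cy > ny - 1 || cz > nz - 1 ||
        !std::isfinite(cx) || !std::isfinite(cy) || !std::isfinite(cz))
      continue;
    int x0 = (int)std::floor(cx), y0 = (int)std::floor(cy), z0 = (int)std::floor(cz);
    if (x0 == nx - 1) x0--; if (y0 == ny - 1) y0--; if (z0 == nz - 1) z0--;
    if (nx == 1) x0 = 0; if (ny == 1) y0 = 0; if (nz == 1) z0 = 0;
    const int x1 = std::min(x0 + 1, nx - 1), y1 = std::min(y0 + 1, ny - 1),
              z1 = std::min(z0 + 1, nz - 1);
    const double fx = cx - x0, fy = cy - y0, fz = cz - z0;
    double gx = 0, gy = 0, gz = 0;
    for (int c = 0; c < nc; ++c) {
      const double v000 = x[vidx(x0, y0, z0, c, nx, ny, nz)];
      const double v100 = x[vidx(x1, y0, z0, c, nx, ny, nz)];
      const double v010 = x[vidx(x0, y1, z0, c, nx, ny, nz)];
      const double v110 = x[vidx(x1, y1, z0, c, nx, ny, nz)];
      const double v001 = x[vidx(x0, y0, z1, c, nx, ny, nz)];
      const double v101 = x[vidx(x1, y0, z1, c, nx, ny, nz)];
      const double v011 = x[vidx(x0, y1, z1, c, nx, ny, nz)];
      const double v111 = x[vidx(x1, y1, z1, c, nx, ny, nz)];
      const double go = gout(i, c);
      // d/dfx
      gx += go * (((v100 - v000) * (1 - fy) + (v110 - v010) * fy) * (1 - fz) +
                  ((v101 - v001) * (1 - fy) + (v111 - v011) * fy) * fz);
      // d/dfy
      gy += go * (((v010 * (1 - fx) + v110 * fx) - (v000 * (1 - fx) + v100 * fx)) * (1 - fz) +
                  ((v011 * (1 - fx) + v111 * fx) - (v001 * (1 - fx) + v101 * fx)) * fz);
      // d/dfz
      const double c0 = (v000 * (1 - fx) + v100 * fx) * (1 - fy) + (v010 * (1 - fx) + v110 * fx) * fy;
      const double c1 = (v001 * (1 - fx) + v101 * fx) * (1 - fy) + (v011 * (1 - fx) + v111 * fx) * fy;
      gz += go * (c1 - c0);
    }
    g(i, 0) = gx; g(i, 1) = gy; g(i, 2) = gz;
  }
  return g;
}

// Nearest-neighbour sampling (labels). Out-of-bounds -> fill.
// [[Rcpp::export]]
NumericVector cpp_sample_nearest(NumericVector x, IntegerVector xdim,
                                 NumericMatrix coords, double fill) {
  const int nx = xdim[0], ny = xdim[1], nz = xdim[2];
  const R_xlen_t n = coords.nrow();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const double cx = coords(i, 0), cy = coords(i, 1), cz = coords(i, 2);
    if (cx < -0.5 || cy < -0.5 || cz < -0.5 ||
        cx > nx - 0.5 || cy > ny - 0.5 || cz > nz - 0.5 ||
        !std::isfinite(cx) || !std::isfinite(cy) || !std::isfinite(cz)) {
      out[i] = fill;
      continue;
    }
    int x0 = (int)std::lround(cx), y0 = (int)std::lround(cy), z0 = (int)std::lround(cz);
    x0 = std::max(0, std::min(x0, nx - 1));
    y0 = std::max(0, std::min(y0, ny - 1));
    z0 = std::max(0, std::min(z0, nz - 1));
    out[i] = x[vidx(x0, y0, z0, 0, nx, ny, nz)];
  }
  return out;
}

// Separable Gaussian blur with reflected borders; sigma in voxels per axis.
// [[Rcpp::export]]
NumericVector cpp_gaussian_blur3d(NumericVector x, IntegerVector xdim,
                                  NumericVector sigma) {
  const int nx = xdim[0], ny = xdim[1], nz = xdim[2];
  std::vector<double> a(x.begin(), x.end()), b(a.size());
  const int dims[3] = {nx, ny, nz};
  const R_xlen_t strides[3] = {1, (R_xlen_t)nx, (R_xlen_t)nx * ny};
  for (int ax = 0; ax < 3; ++ax) {
    const double s = sigma[ax];
    if (s <= 0) continue;
    const int r = std::max(1, (int)std::ceil(3.0 * s));
    std::vector<double> w(2 * r + 1);
    double wsum = 0;
    for (int i = -r; i <= r; ++i) { w[i + r] = std::exp(-0.5 * i * i / (s * s)); wsum += w[i + r]; }
    for (auto& v : w) v /= wsum;
    const int nA = dims[ax];
    const R_xlen_t sA = strides[ax];
    // iterate over all lines along axis ax
    for (int z = 0; z < (ax == 2 ? 1 : nz); ++z) {
      for (int y = 0; y < (ax == 1 ? 1 : ny); ++y) {
        for (int xx = 0; xx < (ax == 0 ? 1 : nx); ++xx) {
          const R_xlen_t base = (R_xlen_t)xx + (R_xlen_t)nx * ((R_xlen_t)y + (R_xlen_t)ny * z);
          for (int i = 0; i < nA; ++i) {
            double acc = 0;
            for (int j = -r; j <= r; ++j) {
              // mirror boundary with period 2*nA (safe for any radius)
              const int m = 2 * nA;
              int idx = ((i + j) % m + m) % m;
              if (idx >= nA) idx = m - idx - 1;
              acc += w[j + r] * a[base + (R_xlen_t)idx * sA];
            }
            b[base + (R_xlen_t)i * sA] = acc;
          }
        }
      }
    }
    std::swap(a, b);
  }
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = IntegerVector::create(nx, ny, nz);
  return out;
}

// ---- direct 3D convolution (no im2col intermediates) -----------------------
// x: (nx,ny,nz,cin), W: (k1,k2,k3,cin,cout), column-major R arrays.
// Loop order puts the contiguous x axis innermost so the compiler vectorizes.

static inline void conv_axis_range(int n_in, int n_out, int k_off, int s, int p,
                                   int& o_lo, int& o_hi) {
  // valid output indices o with 0 <= o*s - p + k_off < n_in
  const int num = p - k_off;
  o_lo = num <= 0 ? 0 : (num + s - 1) / s;
  const int hi = n_in - 1 + p - k_off;
  o_hi = hi < 0 ? -1 : std::min(n_out - 1, hi / s);
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_fwd(NumericVector x, IntegerVector xdim,
                             NumericVector W, IntegerVector wdim,
                             IntegerVector stride, IntegerVector pad,
                             NumericVector bias) {
  const int nx = xdim[0], ny = xdim[1], nz = xdim[2], cin = xdim[3];
  const int k1 = wdim[0], k2 = wdim[1], k3 = wdim[2], cout = wdim[4];
  const int s1 = stride[0], s2 = stride[1], s3 = stride[2];
  const int p1 = pad[0], p2 = pad[1], p3 = pad[2];
  const int ox = (nx + 2 * p1 - k1) / s1 + 1;
  const int oy = (ny + 2 * p2 - k2) / s2 + 1;
  const int oz = (nz + 2 * p3 - k3) / s3 + 1;
  NumericVector y((R_xlen_t)ox * oy * oz * cout);
  const double* xp = x.begin();
  const double* wp = W.begin();
  double* yp = y.begin();
  // bias init
  for (int co = 0; co < cout; ++co) {
    double* ycp = yp + (R_xlen_t)ox * oy * oz * co;
    const double b = bias[co];
    for (R_xlen_t i = 0; i < (R_xlen_t)ox * oy * oz; ++i) ycp[i] = b;
  }
  int ox_lo, ox_hi, oy_lo, oy_hi, oz_lo, oz_hi;
  for (int co = 0; co < cout; ++co) {
    for (int ci = 0; ci < cin; ++ci) {
      const double* xcp = xp + (R_xlen_t)nx * ny * nz * ci;
      double* ycp = yp + (R_xlen_t)ox * oy * oz * co;
      for (int kz = 0; kz < k3; ++kz) {
        conv_axis_range(nz, oz, kz, s3, p3, oz_lo, oz_hi);
        for (int ky = 0; ky < k2; ++ky) {
          conv_axis_range(ny, oy, ky, s2, p2, oy_lo, oy_hi);
          for (int kx = 0; kx < k1; ++kx) {
            conv_axis_range(nx, ox, kx, s1, p1, ox_lo, ox_hi);
            const double w = wp[kx + k1 * (ky + k2 * (kz + k3 * (ci + (R_xlen_t)cin * co)))];
            if (w == 0.0) continue;
            for (int ozz = oz_lo; ozz <= oz_hi; ++ozz) {
              const int iz = ozz * s3 - p3 + kz;
              for (int oyy = oy_lo; oyy <= oy_hi; ++oyy) {
                const int iy = oyy * s2 - p2 + ky;
                const double* xrow = xcp + (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz);
                double* yrow = ycp + (R_xlen_t)ox * (oyy + (R_xlen_t)oy * ozz);
                if (s1 == 1) {
                  const int base = -p1 + kx;
                  for (int o = ox_lo; o <= ox_hi; ++o) yrow[o] += w * xrow[o + base];
                } else {
                  for (int o = ox_lo; o <= ox_hi; ++o) yrow[o] += w * xrow[o * s1 - p1 + kx];
                }
              }
            }
          }
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(ox, oy, oz, cout);
  return y;
}

// gradient w.r.t. the input
// [[Rcpp::export]]
NumericVector cpp_conv3d_gx(NumericVector gy, IntegerVector xdim,
                            NumericVector W, IntegerVector wdim,
                            IntegerVector stride, IntegerVector pad) {
  const int nx = xdim[0], ny = xdim[1], nz = xdim[2], cin = xdim[3];
  const int k1 = wdim[0], k2 = wdim[1], k3 = wdim[2], cout = wdim[4];
  const int s1 = stride[0], s2 = stride[1], s3 = stride[2];
  const int p1 = pad[0], p2 = pad[1], p3 = pad[2];
  const int ox = (nx + 2 * p1 - k1) / s1 + 1;
  const int oy = (ny + 2 * p2 - k2) / s2 + 1;
  const int oz = (nz + 2 * p3 - k3) / s3 + 1;
  NumericVector gx((R_xlen_t)nx * ny * nz * cin);
  const double* gp = gy.begin();
  const double* wp = W.begin();
  double* xp = gx.begin();
  int ox_lo, ox_hi, oy_lo, oy_hi, oz_lo, oz_hi;
  for (int co = 0; co < cout; ++co) {
    for (int ci = 0; ci < cin; ++ci) {
      double* xcp = xp + (R_xlen_t)nx * ny * nz * ci;
      const double* gcp = gp + (R_xlen_t)ox * oy * oz * co;
      for (int kz = 0; kz < k3; ++kz) {
        conv_axis_range(nz, oz, kz, s3, p3, oz_lo, oz_hi);
        for (int ky = 0; ky < k2; ++ky) {
          conv_axis_range(ny, oy, ky, s2, p2, oy_lo, oy_hi);
          for (int kx = 0; kx < k1; ++kx) {
            conv_axis_range(nx, ox, kx, s1, p1, ox_lo, ox_hi);
            const double w = wp[kx + k1 * (ky + k2 * (kz + k3 * (ci + (R_xlen_t)cin * co)))];
            if (w == 0.0) continue;
            for (int ozz = oz_lo; ozz <= oz_hi; ++ozz) {
              const int iz = ozz * s3 - p3 + kz;
              for (int oyy = oy_lo; oyy <= oy_hi; ++oyy) {
                const int iy = oyy * s2 - p2 + ky;
                double* xrow = xcp + (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz);
                const double* grow = gcp + (R_xlen_t)ox * (oyy + (R_xlen_t)oy * ozz);
                if (s1 == 1) {
                  const int base = -p1 + kx;
                  for (int o = ox_lo; o <= ox_hi; ++o) xrow[o + base] += w * grow[o];
                } else {
                  for (int o = ox_lo; o <= ox_hi; ++o) xrow[o * s1 - p1 + kx] += w * grow[o];
                }
              }
            }
          }
        }
      }
    }
  }
  gx.attr("dim") = xdim;
  return gx;
}

// gradient w.r.t. the weights (bias gradient is colSums of gy in R)
// [[Rcpp::export]]
NumericVector cpp_conv3d_gw(NumericVector x, IntegerVector xdim,
                            NumericVector gy, IntegerVector wdim,
                            IntegerVector stride, IntegerVector pad) {
  const int nx = xdim[0], ny = xdim[1], nz = xdim[2], cin = xdim[3];
  const int k1 = wdim[0], k2 = wdim[1], k3 = wdim[2], cout = wdim[4];
  const int s1 = stride[0], s2 = stride[1], s3 = stride[2];
  const int p1 = pad[0], p2 = pad[1], p3 = pad[2];
  const int ox = (nx + 2 * p1 - k1) / s1 + 1;
  const int oy = (ny + 2 * p2 - k2) / s2 + 1;
  const int oz = (nz + 2 * p3 - k3) / s3 + 1;
  NumericVector gw((R_xlen_t)k1 * k2 * k3 * cin * cout);
  const double* xp = x.begin();
  const double* gp = gy.begin();
  double* wp = gw.begin();
  int ox_lo, ox_hi, oy_lo, oy_hi, oz_lo, oz_hi;
  for (int co = 0; co < cout; ++co) {
    for (int ci = 0; ci < cin; ++ci) {
      const double* xcp = xp + (R_xlen_t)nx * ny * nz * ci;
      const double* gcp = gp + (R_xlen_t)ox * oy * oz * co;
      for (int kz = 0; kz < k3; ++kz) {
        conv_axis_range(nz, oz, kz, s3, p3, oz_lo, oz_hi);
        for (int ky = 0; ky < k2; ++ky) {
          conv_axis_range(ny, oy, ky, s2, p2, oy_lo, oy_hi);
          for (int kx = 0; kx < k1; ++kx) {
            conv_axis_range(nx, ox, kx, s1, p1, ox_lo, ox_hi);
            double acc = 0.0;
            for (int ozz = oz_lo; ozz <= oz_hi; ++ozz) {
              const int iz = ozz * s3 - p3 + kz;
              for (int oyy = oy_lo; oyy <= oy_hi; ++oyy) {
                const int iy = oyy * s2 - p2 + ky;
                const double* xrow = xcp + (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz);
                const double* grow = gcp + (R_xlen_t)ox * (oyy + (R_xlen_t)oy * ozz);
                if (s1 == 1) {
                  const int base = -p1 + kx;
                  for (int o = ox_lo; o <= ox_hi; ++o) acc += grow[o] * xrow[o + base];
                } else {
                  for (int o = ox_lo; o <= ox_hi; ++o) acc += grow[o] * xrow[o * s1 - p1 + kx];
                }
              }
            }
            wp[kx + k1 * (ky + k2 * (kz + k3 * (ci + (R_xlen_t)cin * co)))] = acc;
          }
        }
      }
    }
  }
  gw.attr("dim") = wdim;
  return gw;
}
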