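#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Catmull-Rom cubic kernel weights for fractional offset t in [0,1)
static inline void cubicWeights(double t, double w[4]) {
  double t2 = t * t, t3 = t2 * t;
  w[0] = 0.5 * (-t3 + 2.0 * t2 - t);
  w[1] = 0.5 * (3.0 * t3 - 5.0 * t2 + 2.0);
  w[2] = 0.5 * (-3.0 * t3 + 4.0 * t2 + t);
  w[3] = 0.5 * (t3 - t2);
}

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Backward-warp resampling of a 3D volume.
// mat: 4x4 homogeneous matrix mapping reference-world -> source-world (mm).
// Grids are axis-aligned: world = origin + index * spacing (0-based index).
// interp: 0 nearest, 1 trilinear, 3 cubic. Out-of-field -> fill.
// [[Rcpp::export(name = ".resampleCpp")]]
List resampleCpp(NumericVector src, IntegerVector sdim,
                 NumericVector sspacing, NumericVector sorigin,
                 IntegerVector rdim, NumericVector rspacing,
                 NumericVector rorigin, NumericMatrix mat,
                 int interp, double fill) {
  const int sx = sdim[0], sy = sdim[1], sz = sdim[2];
  const int rx = rdim[0], ry = rdim[1], rz = rdim[2];
  const double *S = src.begin();
  NumericVector out((double)rx * ry * rz);
  LogicalVector inside((double)rx * ry * rz);
  const double m00 = mat(0,0), m01 = mat(0,1), m02 = mat(0,2), m03 = mat(0,3);
  const double m10 = mat(1,0), m11 = mat(1,1), m12 = mat(1,2), m13 = mat(1,3);
  const double m20 = mat(2,0), m21 = mat(2,1), m22 = mat(2,2), m23 = mat(2,3);
  const size_t sxy = (size_t)sx * sy;
  size_t o = 0;
  for (int k = 0; k < rz; ++k) {
    double wz = rorigin[2] + k * rspacing[2];
    for (int j = 0; j < ry; ++j) {
      double wy = rorigin[1] + j * rspacing[1];
      for (int i = 0; i < rx; ++i, ++o) {
        double wx = rorigin[0] + i * rspacing[0];
        // source continuous index
        double px = (m00 * wx + m01 * wy + m02 * wz + m03 - sorigin[0]) / sspacing[0];
        double py = (m10 * wx + m11 * wy + m12 * wz + m13 - sorigin[1]) / sspacing[1];
        double pz = (m20 * wx + m21 * wy + m22 * wz + m23 - sorigin[2]) / sspacing[2];
        if (px < 0.0 || px > sx - 1.0 || py < 0.0 || py > sy - 1.0 ||
            pz < 0.0 || pz > sz - 1.0) {
          out[o] = fill; inside[o] = false; continue;
        }
        inside[o] = true;
        // snap near-integer coordinates to an exact lookup: keeps the
        // identity and integer shifts bit-exact under any interpolation
        if (interp != 0 &&
            std::fabs(px - std::nearbyint(px)) < 1e-9 &&
            std::fabs(py - std::nearbyint(py)) < 1e-9 &&
            std::fabs(pz - std::nearbyint(pz)) < 1e-9) {
          int ix = (int)std::nearbyint(px), iy = (int)std::nearbyint(py),
              iz = (int)std::nearbyint(pz);
          out[o] = S[(size_t)iz * sxy + (size_t)iy * sx + ix];
          continue;
        }
        if (interp == 0) {
          int ix = (int)std::lround(px), iy = (int)std::lround(py),
              iz = (int)std::lround(pz);
          out[o] = S[(size_t)iz * sxy + (size_t)iy * sx + ix];
        } else if (interp == 1) {
          int x0 = (int)std::floor(px), y0 = (int)std::floor(py),
              z0 = (int)std::floor(pz);
          if (x0 > sx - 2) x0 = sx - 2;
          if (y0 > sy - 2) y0 = sy - 2;
          if (z0 > sz - 2) z0 = sz - 2;
          double fx = px - x0, fy = py - y0, fz = pz - z0;
          const double *p0 = S + (size_t)z0 * sxy + (size_t)y0 * sx + x0;
          double c00 = p0[0] + fx * (p0[1] - p0[0]);
          double c10 = p0[sx] + fx * (p0[sx + 1] - p0[sx]);
          const double *p1 = p0 + sxy;
          double c01 = p1[0] + fx * (p1[1] - p1[0]);
          double c11 = p1[sx] + fx * (p1[sx + 1] - p1[sx]);
          double c0 = c00 + fy * (c10 - c00);
          double c1 = c01 + fy * (c11 - c01);
          out[o] = c0 + fz * (c1 - c0);
        } else {
          int x0 = (int)std::floor(px), y0 = (int)std::floor(py),
              z0 = (int)std::floor(pz);
          double wxv[4], wyv[4], wzv[4];
          cubicWeights(px - x0, wxv);
          cubicWeights(py - y0, wyv);
          cubicWeights(pz - z0, wzv);
          double acc = 0.0;
          for (int dz = -1; dz <= 2; ++dz) {
            int zz = clampi(z0 + dz, 0, sz - 1);
            double az = wzv[dz + 1];
            for (int dy = -1; dy <= 2; ++dy) {
              int yy = clampi(y0 + dy, 0, sy - 1);
              double ay = wyv[dy + 1] * az;
              const double *row = S + (size_t)zz * sxy + (size_t)yy * sx;
              for (int dx = -1; dx <= 2; ++dx) {
                int xx = clampi(x0 + dx, 0, sx - 1);
                acc += ay * wxv[dx + 1] * row[xx];
              }
            }
          }
          out[o] = acc;
        }
      }
    }
  }
  return List::create(_["data"] = out, _["inside"] = inside);
}

// Separable Gaussian smoothing with replicate boundaries.
// sigma per axis in voxel units; kernel truncated at 3 sigma.
// [[Rcpp::export(name = ".gaussSmoothCpp")]]
NumericVector gaussSmoothCpp(NumericVector vol, IntegerVector dims,
                             NumericVector sigma) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<double> buf(vol.begin(), vol.end());
  std::vector<double> tmp(buf.size());
  const int strides[3] = {1, nx, nx * ny};
  const int sizes[3] = {nx, ny, nz};
  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma[ax];
    if (s <= 0) continue;
    int rad = (int)std::ceil(3.0 * s);
    std::vector<double> k(2 * rad + 1);
    double ksum = 0.0;
    for (int d = -rad; d <= rad; ++d) {
      k[d + rad] = std::exp(-0.5 * d * d / (s * s));
      ksum += k[d + rad];
    }
    for (auto &v : k) v /= ksum;
    int n = sizes[ax], stride = strides[ax];
    int nlines = nx * ny * nz / n;
    // iterate over all lines along axis ax
    for (int line = 0; line < nlines; ++line) {
      // compute base offset of this line
      int rem = line, base = 0;
      for (int a = 0; a < 3; ++a) {
        if (a == ax) continue;
        int idx = rem % sizes[a];
        rem /= sizes[a];
        base += idx * strides[a];
      }
      for (int i = 0; i < n; ++i) {
        double acc = 0.0;
        for (int d = -rad; d <= rad; ++d) {
          int j = clampi(i + d, 0, n - 1);
          acc += k[d + rad] * buf[base + (size_t)j * stride];
        }
        tmp[base + (size_t)i * stride] = acc;
      }
    }
    buf.swap(tmp);
  }
  return NumericVector(buf.begin(), buf.end());
}
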