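#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Voxel-centre world coordinate convention: axis k with n voxels and spacing s
// has voxel i (1-based in R, 0-based here) centred at (i - (n-1)/2) * s, so the
// grid centre is world origin.  All rigid motion is about this centre.

static inline double bilin(const NumericMatrix &img, double x, double y,
                           int nx, int ny, double fill) {
  // x, y in 0-based voxel units
  if (x < 0 || y < 0 || x > nx - 1 || y > ny - 1) return fill;
  int i0 = (int)std::floor(x), j0 = (int)std::floor(y);
  if (i0 == nx - 1) i0--;
  if (j0 == ny - 1) j0--;
  double fx = x - i0, fy = y - j0;
  return img(i0, j0) * (1 - fx) * (1 - fy) + img(i0 + 1, j0) * fx * (1 - fy) +
         img(i0, j0 + 1) * (1 - fx) * fy + img(i0 + 1, j0 + 1) * fx * fy;
}

// [[Rcpp::export(name = ".resample_rigid2d")]]
NumericMatrix resample_rigid2d(NumericMatrix img, double sx, double sy,
                               double tx, double ty, double rot_deg,
                               double fill) {
  // Output voxel at world p takes input value at R^{-1}(p - t): the image
  // content is moved by (R, t) about the grid centre.
  int nx = img.nrow(), ny = img.ncol();
  NumericMatrix out(nx, ny);
  double th = rot_deg * M_PI / 180.0;
  double c = std::cos(th), s = std::sin(th);
  double cx = (nx - 1) / 2.0, cy = (ny - 1) / 2.0;
  for (int j = 0; j < ny; j++) {
    double wy = (j - cy) * sy - ty;
    for (int i = 0; i < nx; i++) {
      double wx = (i - cx) * sx - tx;
      // inverse rotation
      double ux = c * wx + s * wy;
      double uy = -s * wx + c * wy;
      out(i, j) = bilin(img, ux / sx + cx, uy / sy + cy, nx, ny, fill);
    }
  }
  return out;
}

static inline double trilin(const NumericVector &img, double x, double y,
                            double z, int nx, int ny, int nz, double fill) {
  if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1)
    return fill;
  int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
  if (i0 == nx - 1) i0--;
  if (j0 == ny - 1) j0--;
  if (k0 == nz - 1) k0--;
  double fx = x - i0, fy = y - j0, fz = z - k0;
  double v = 0.0;
  for (int dk = 0; dk < 2; dk++) {
    double wz = dk ? fz : 1 - fz;
    for (int dj = 0; dj < 2; dj++) {
      double wy = dj ? fy : 1 - fy;
      for (int di = 0; di < 2; di++) {
        double wx = di ? fx : 1 - fx;
        v += img[(i0 + di) + nx * ((j0 + dj) + ny * (k0 + dk))] * wx * wy * wz;
      }
    }
  }
  return v;
}

// [[Rcpp::export(name = ".resample_rigid3d")]]
NumericVector resample_rigid3d(NumericVector img, IntegerVector dim,
                               NumericVector spacing, NumericMatrix Rm,
                               NumericVector t, double fill) {
  // Rm is the 3x3 rotation of the forward motion; output(p) = img(R^T (p - t)).
  int nx = dim[0], ny = dim[1], nz = dim[2];
  double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  double cx = (nx - 1) / 2.0, cy = (ny - 1) / 2.0, cz = (nz - 1) / 2.0;
  NumericVector out(nx * ny * nz);
  for (int k = 0; k < nz; k++) {
    double wz = (k - cz) * sz - t[2];
    for (int j = 0; j < ny; j++) {
      double wy = (j - cy) * sy - t[1];
      for (int i = 0; i < nx; i++) {
        double wx = (i - cx) * sx - t[0];
        double ux = Rm(0, 0) * wx + Rm(1, 0) * wy + Rm(2, 0) * wz;
        double uy = Rm(0, 1) * wx + Rm(1, 1) * wy + Rm(2, 1) * wz;
        double uz = Rm(0, 2) * wx + Rm(1, 2) * wy + Rm(2, 2) * wz;
        out[i + nx * (j + ny * k)] =
            trilin(img, ux / sx + cx, uy / sy + cy, uz / sz + cz, nx, ny, nz,
                   fill);
      }
    }
  }
  out.attr("dim") = dim;
  return out;
}

// Parallel-beam 2-D line-integral projector.  Ray for (angle th, radial r):
//   p(t) = r * (cos th, sin th) + t * (-sin th, cos th),  t in [-L, L].
// Integrals are in mm (step * sum of samples); bilinear sampling inside the
// grid, zero outside.  bp2d is the exact adjoint (bilinear splatting).

// [[Rcpp::export(name = ".fp2d")]]
NumericMatrix fp2d(NumericMatrix img, double sx, double sy,
                   NumericVector angles, int n_rad, double dr, double step) {
  int nx = img.nrow(), ny = img.ncol(), na = angles.size();
  double cx = (nx - 1) / 2.0, cy = (ny - 1) / 2.0;
  double L = 0.5 * std::sqrt(nx * sx * nx * sx + ny * sy * ny * sy) + step;
  int nstep = (int)std::ceil(2.0 * L / step);
  NumericMatrix sino(n_rad, na);
  double r0 = -(n_rad - 1) / 2.0 * dr;
  for (int a = 0; a < na; a++) {
    double c = std::cos(angles[a]), s = std::sin(angles[a]);
    for (int ir = 0; ir < n_rad; ir++) {
      double r = r0 + ir * dr;
      double px = r * c - L * (-s), py = r * s - L * c; // t = -L start
      // march: p = r*(c,s) + t*(-s,c)
      double acc = 0.0;
      for (int m = 0; m <= nstep; m++) {
        double t = -L + m * step;
        double wx = r * c - t * s;
        double wy = r * s + t * c;
        double gx = wx / sx + cx, gy = wy / sy + cy;
        if (gx >= 0 && gy >= 0 && gx <= nx - 1 && gy <= ny - 1)
          acc += bilin(img, gx, gy, nx, ny, 0.0);
      }
      (void)px; (void)py;
      sino(ir, a) = acc * step;
    }
  }
  return sino;
}

// [[Rcpp::export(name = ".bp2d")]]
NumericMatrix bp2d(NumericMatrix sino, double sx, double sy,
                   NumericVector angles, int nx, int ny, double dr,
                   double step) {
  int n_rad = sino.nrow(), na = angles.size();
  double cx = (nx - 1) / 2.0, cy = (ny - 1) / 2.0;
  double L = 0.5 * std::sqrt(nx * sx * nx * sx + ny * sy * ny * sy) + step;
  int nstep = (int)std::ceil(2.0 * L / step);
  NumericMatrix out(nx, ny);
  double r0 = -(n_rad - 1) / 2.0 * dr;
  for (int a = 0; a < na; a++) {
    double c = std::cos(angles[a]), s = std::sin(angles[a]);
    for (int ir = 0; ir < n_rad; ir++) {
      double v = sino(ir, a) * step;
      if (v == 0.0) continue;
      double r = r0 + ir * dr;
      for (int m = 0; m <= nstep; m++) {
        double t = -L + m * step;
        double gx = (r * c - t * s) / sx + cx;
        double gy = (r * s + t * c) / sy + cy;
        if (gx < 0 || gy < 0 || gx > nx - 1 || gy > ny - 1) continue;
        int i0 = (int)std::floor(gx), j0 = (int)std::floor(gy);
        if (i0 == nx - 1) i0--;
        if (j0 == ny - 1) j0--;
        double fx = gx - i0, fy = gy - j0;
        out(i0, j0) += v * (1 - fx) * (1 - fy);
        out(i0 + 1, j0) += v * fx * (1 - fy);
        out(i0, j0 + 1) += v * (1 - fx) * fy;
        out(i0 + 1, j0 + 1) += v * fx * fy;
      }
    }
  }
  return out;
}
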