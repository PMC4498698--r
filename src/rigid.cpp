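#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Trilinear sampling with edge clamping; coordinates are 0-based voxel indices.
static inline double sample3(const double *v, const int nx, const int ny,
                             const int nz, double x, double y, double z) {
  if (x < 0.0) x = 0.0;
  if (y < 0.0) y = 0.0;
  if (z < 0.0) z = 0.0;
  if (x > nx - 1.0) x = nx - 1.0;
  if (y > ny - 1.0) y = ny - 1.0;
  if (z > nz - 1.0) z = nz - 1.0;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  int x1 = x0 + 1 < nx ? x0 + 1 : x0;
  int y1 = y0 + 1 < ny ? y0 + 1 : y0;
  int z1 = z0 + 1 < nz ? z0 + 1 : z0;
  double fx = x - x0, fy = y - y0, fz = z - z0;
  const int sxy = nx * ny;
#define V(i, j, k) v[(i) + (j) * nx + (k) * sxy]
  double c00 = V(x0, y0, z0) * (1 - fx) + V(x1, y0, z0) * fx;
  double c10 = V(x0, y1, z0) * (1 - fx) + V(x1, y1, z0) * fx;
  double c01 = V(x0, y0, z1) * (1 - fx) + V(x1, y0, z1) * fx;
  double c11 = V(x0, y1, z1) * (1 - fx) + V(x1, y1, z1) * fx;
#undef V
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// Rotation matrix Rz(rz) * Ry(ry) * Rx(rx); angles in degrees.
static void rotmat(const double *p, double R[9]) {
  const double d2r = M_PI / 180.0;
  double cx = std::cos(p[3] * d2r), sx = std::sin(p[3] * d2r);
  double cy = std::cos(p[4] * d2r), sy = std::sin(p[4] * d2r);
  double cz = std::cos(p[5] * d2r), sz = std::sin(p[5] * d2r);
  R[0] = cz * cy;  R[1] = cz * sy * sx - sz * cx;  R[2] = cz * sy * cx + sz * sx;
  R[3] = sz * cy;  R[4] = sz * sy * sx + cz * cx;  R[5] = sz * sy * cx - cz * sx;
  R[6] = -sy;      R[7] = cy * sx;                 R[8] = cy * cx;
}

// params = (tx, ty, tz) mm and (rx, ry, rz) degrees: the rigid motion applied
// to the object, about the volume centre.  out(x) = in(R^T ((x - c) - t) + c).
// [[Rcpp::export(name = ".rigidApply")]]
NumericVector rigid_apply(NumericVector vol, IntegerVector dim,
                          NumericVector params, NumericVector voxmm) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out(nx * ny * nz);
  double R[9];
  rotmat(params.begin(), R);
  const double cx = 0.5 * (nx - 1) * voxmm[0];
  const double cy = 0.5 * (ny - 1) * voxmm[1];
  const double cz = 0.5 * (nz - 1) * voxmm[2];
  const double *v = vol.begin();
  double *o = out.begin();
  int idx = 0;
  for (int k = 0; k < nz; ++k) {
    double pz = k * voxmm[2] - cz - params[2];
    for (int j = 0; j < ny; ++j) {
      double py = j * voxmm[1] - cy - params[1];
      for (int i = 0; i < nx; ++i, ++idx) {
        double px = i * voxmm[0] - cx - params[0];
        // inverse rotation = transpose
        double qx = R[0] * px + R[3] * py + R[6] * pz + cx;
        double qy = R[1] * px + R[4] * py + R[7] * pz + cy;
        double qz = R[2] * px + R[5] * py + R[8] * pz + cz;
        o[idx] = sample3(v, nx, ny, nz, qx / voxmm[0], qy / voxmm[1],
                         qz / voxmm[2]);
      }
    }
  }
  return out;
}

// Sum of squared differences between rigid_apply(vol, params) and ref,
// without materialising the transformed volume (registration objective).
// [[Rcpp::export(name = ".rigidSSD")]]
double rigid_ssd(NumericVector vol, NumericVector ref, IntegerVector dim,
                 NumericVector params, NumericVector voxmm) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  double R[9];
  rotmat(params.begin(), R);
  const double cx = 0.5 * (nx - 1) * voxmm[0];
  const double cy = 0.5 * (ny - 1) * voxmm[1];
  const double cz = 0.5 * (nz - 1) * voxmm[2];
  const double *v = vol.begin();
  const double *r = ref.begin();
  double ssd = 0.0;
  int idx = 0;
  for (int k = 0; k < nz; ++k) {
    double pz = k * voxmm[2] - cz - params[2];
    for (int j = 0; j < ny; ++j) {
      double py = j * voxmm[1] - cy - params[1];
      for (int i = 0; i < nx; ++i, ++idx) {
        double px = i * voxmm[0] - cx - params[0];
        double qx = R[0] * px + R[3] * py + R[6] * pz + cx;
        double qy = R[1] * px + R[4] * py + R[7] * pz + cy;
        double qz = R[2] * px + R[5] * py + R[8] * pz + cz;
        double d = sample3(v, nx, ny, nz, qx / voxmm[0], qy / voxmm[1],
                           qz / voxmm[2]) - r[idx];
        ssd += d * d;
      }
    }
  }
  return ssd;
}
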