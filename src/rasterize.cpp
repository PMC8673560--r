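// Voxelization of tapered-capsule unions.
//
// A tree polyline is supplied as pieces (p1, r1) -> (p2, r2); a voxel centre
// belongs to the foreground if its distance to the segment is at most the
// linearly interpolated radius at the closest parameter (a rounded-cone
// approximation of the swept-sphere volume; clamping at the ends yields the
// spherical caps of a capsule).

#include <Rcpp.h>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

//' @noRd
// [[Rcpp::export(name = ".rasterize_cpp")]]
RawVector rasterize_cpp(NumericMatrix pieces, IntegerVector dims,
                        NumericVector spacing, NumericVector origin) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  double ox = origin[0], oy = origin[1], oz = origin[2];
  const size_t N = (size_t)nx * ny * nz;
  RawVector out(N);

  for (int p = 0; p < pieces.nrow(); ++p) {
    double x1 = pieces(p, 0), y1 = pieces(p, 1), z1 = pieces(p, 2), r1 = pieces(p, 3);
    double x2 = pieces(p, 4), y2 = pieces(p, 5), z2 = pieces(p, 6), r2 = pieces(p, 7);
    double rmax = std::max(r1, r2);
    double dx = x2 - x1, dy = y2 - y1, dz = z2 - z1;
    double dd = dx * dx + dy * dy + dz * dz;

    // index bounding box (voxel centre of 0-based index i is origin + i * s)
    int ilo = (int)std::floor((std::min(x1, x2) - rmax - ox) / sx) - 1;
    int ihi = (int)std::ceil((std::max(x1, x2) + rmax - ox) / sx) + 1;
    int jlo = (int)std::floor((std::min(y1, y2) - rmax - oy) / sy) - 1;
    int jhi = (int)std::ceil((std::max(y1, y2) + rmax - oy) / sy) + 1;
    int klo = (int)std::floor((std::min(z1, z2) - rmax - oz) / sz) - 1;
    int khi = (int)std::ceil((std::max(z1, z2) + rmax - oz) / sz) + 1;
    ilo = std::max(ilo, 0); ihi = std::min(ihi, nx - 1);
    jlo = std::max(jlo, 0); jhi = std::min(jhi, ny - 1);
    klo = std::max(klo, 0); khi = std::min(khi, nz - 1);

    for (int k = klo; k <= khi; ++k) {
      double pz = oz + k * sz;
      for (int j = jlo; j <= jhi; ++j) {
        double py = oy + j * sy;
        for (int i = ilo; i <= ihi; ++i) {
          double px = ox + i * sx;
          double wx = px - x1, wy = py - y1, wz = pz - z1;
          double t = 0.0;
          if (dd > 0.0) {
            t = (wx * dx + wy * dy + wz * dz) / dd;
            if (t < 0.0) t = 0.0;
            if (t > 1.0) t = 1.0;
          }
          double rx = wx - t * dx, ry = wy - t * dy, rz = wz - t * dz;
          double rad = r1 + t * (r2 - r1);
          if (rx * rx + ry * ry + rz * rz <= rad * rad) {
            out[(size_t)i + (size_t)nx * (j + (size_t)ny * k)] = 1;
          }
        }
      }
    }
  }
  return out;
}
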