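// Voxel morphometry: surface area by the co-area formula on a Gaussian
// smoothed indicator, foreground counting, connected-component labelling.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// separable Gaussian smoothing (sigma in voxels, zero padding outside),
// implemented as shifted-row/plane accumulation so all memory access is
// contiguous
static void smooth1(std::vector<float>& u, std::vector<float>& tmp,
                    int nx, int ny, int nz, int axis, double sigma) {
  int radius = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> ker(2 * radius + 1);
  double sum = 0.0;
  for (int t = -radius; t <= radius; ++t) {
    ker[t + radius] = std::exp(-0.5 * t * t / (sigma * sigma));
    sum += ker[t + radius];
  }
  for (size_t t = 0; t < ker.size(); ++t) ker[t] /= sum;

  const size_t N = (size_t)nx * ny * nz;
  std::fill(tmp.begin(), tmp.end(), 0.0f);
  const size_t plane = (size_t)nx * ny;
  for (int t = -radius; t <= radius; ++t) {
    float w = (float)ker[t + radius];
    if (axis == 2) {
      for (int z = 0; z < nz; ++z) {
        int zs = z + t;
        if (zs < 0 || zs >= nz) continue;
        float* dst = &tmp[plane * z];
        const float* src = &u[plane * zs];
        for (size_t i = 0; i < plane; ++i) dst[i] += w * src[i];
      }
    } else if (axis == 1) {
      for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y) {
          int ys = y + t;
          if (ys < 0 || ys >= ny) continue;
          float* dst = &tmp[plane * z + (size_t)nx * y];
          const float* src = &u[plane * z + (size_t)nx * ys];
          for (int x = 0; x < nx; ++x) dst[x] += w * src[x];
        }
    } else {
      for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y) {
          size_t off = plane * z + (size_t)nx * y;
          float* dst = &tmp[off];
          const float* src = &u[off];
          int x0 = std::max(0, -t), x1 = nx - std::max(0, t);
          for (int x = x0; x < x1; ++x) dst[x] += w * src[x + t];
        }
    }
  }
  u.swap(tmp);
  (void)N;
}

//' @noRd
// [[Rcpp::export(name = ".surface_area_cpp")]]
double surface_area_cpp(RawVector mask, IntegerVector dims,
                        NumericVector spacing, double sigma_vox) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const size_t N = (size_t)nx * ny * nz;
  std::vector<float> u(N);
  for (size_t i = 0; i < N; ++i) u[i] = mask[i] != 0 ? 1.0f : 0.0f;
  if (sigma_vox > 0) {
    std::vector<float> tmp(N);
    smooth1(u, tmp, nx, ny, nz, 0, sigma_vox);
    smooth1(u, tmp, nx, ny, nz, 1, sigma_vox);
    smooth1(u, tmp, nx, ny, nz, 2, sigma_vox);
  }
  double vol = sx * sy * sz;
  double area = 0.0;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        size_t i = (size_t)x + (size_t)nx * (y + (size_t)ny * z);
        double xm = x > 0 ? u[i - 1] : 0.0, xp = x < nx - 1 ? u[i + 1] : 0.0;
        double ym = y > 0 ? u[i - nx] : 0.0, yp = y < ny - 1 ? u[i + nx] : 0.0;
        size_t pz = (size_t)nx * ny;
        double zm = z > 0 ? u[i - pz] : 0.0, zp = z < nz - 1 ? u[i + pz] : 0.0;
        double gx = (xp - xm) / (2.0 * sx);
        double gy = (yp - ym) / (2.0 * sy);
        double gz = (zp - zm) / (2.0 * sz);
        area += std::sqrt(gx * gx + gy * gy + gz * gz) * vol;
      }
  return area;
}

//' @noRd
// [[Rcpp::export(name = ".count_foreground_cpp")]]
double count_foreground_cpp(RawVector mask) {
  double n = 0;
  for (R_xlen_t i = 0; i < mask.size(); ++i)
    if (mask[i] != 0) n += 1;
  return n;
}

// Euler characteristic V - E + F - C of the cubical complex spanned by the
// occupied voxels. For a connected solid without cavities, chi = 1 - H
// where H is the number of handles (genus), so chi == 1 certifies a
// topological tree.
//' @noRd
// [[Rcpp::export(name = ".euler_characteristic_cpp")]]
double euler_characteristic_cpp(RawVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  // padded copy: border of background so all stencils are interior
  int px = nx + 2, py = ny + 2, pz = nz + 2;
  std::vector<uint8_t> m((size_t)px * py * pz, 0);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      const Rbyte* src = &mask[(size_t)nx * (y + (size_t)ny * z)];
      uint8_t* dst = &m[(size_t)1 + (size_t)px * ((y + 1) + (size_t)py * (z + 1))];
      for (int x = 0; x < nx; ++x) dst[x] = src[x] != 0;
    }
  const size_t sx = 1, sy = (size_t)px, sz = (size_t)px * py;
  long long C = 0, F = 0, E = 0, V = 0;
  for (int z = 1; z <= nz + 1; ++z)
    for (int y = 1; y <= ny + 1; ++y) {
      size_t base = (size_t)px * (y + (size_t)py * z);
      for (int x = 1; x <= nx + 1; ++x) {
        size_t i = base + x;
        uint8_t c000 = m[i];
        uint8_t cX = m[i - sx], cY = m[i - sy], cZ = m[i - sz];
        uint8_t cXY = m[i - sx - sy], cXZ = m[i - sx - sz], cYZ = m[i - sy - sz];
        uint8_t cXYZ = m[i - sx - sy - sz];
        C += c000;
        // faces at the low side of cube (x, y, z)
        F += (c000 | cX) + (c000 | cY) + (c000 | cZ);
        // edges at the low corner
        E += (c000 | cY | cZ | cYZ) + (c000 | cX | cZ | cXZ) +
             (c000 | cX | cY | cXY);
        // vertex at the low corner
        V += (c000 | cX | cY | cZ | cXY | cXZ | cYZ | cXYZ);
      }
    }
  return (double)V - (double)E + (double)F - (double)C;
}

// Fill enclosed background cavities: flood-fill the background from the
// volume border with 6-connectivity; anything not reached is interior.
//' @noRd
// [[Rcpp::export(name = ".fill_cavities_cpp")]]
RawVector fill_cavities_cpp(RawVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t N = (size_t)nx * ny * nz;
  // padded state grid (sentinel-free neighbour arithmetic):
  // 0 = unvisited background, 1 = foreground, 2 = outside, 3 = pad wall
  int px = nx + 2, py = ny + 2, pz = nz + 2;
  const size_t PN = (size_t)px * py * pz;
  std::vector<uint8_t> st(PN, 0);
  const long long step[6] = {1, -1, px, -px, (long long)px * py,
                             -(long long)px * py};
  // walls
  for (int z = 0; z < pz; ++z)
    for (int y = 0; y < py; ++y)
      for (int x = 0; x < px; ++x)
        if (x == 0 || y == 0 || z == 0 || x == px - 1 || y == py - 1 || z == pz - 1)
          st[(size_t)x + (size_t)px * (y + (size_t)py * z)] = 3;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      const Rbyte* src = &mask[(size_t)nx * (y + (size_t)ny * z)];
      uint8_t* dst = &st[(size_t)1 + (size_t)px * ((y + 1) + (size_t)py * (z + 1))];
      for (int x = 0; x < nx; ++x)
        if (src[x] != 0) dst[x] = 1;
    }
  // flood the outside from the faces adjacent to the pad wall
  std::vector<long long> stack;
  stack.reserve(1 << 20);
  for (int z = 1; z <= nz; ++z)
    for (int y = 1; y <= ny; ++y)
      for (int x = 1; x <= nx; ++x) {
        if (x != 1 && y != 1 && z != 1 && x != nx && y != ny && z != nz) continue;
        size_t i = (size_t)x + (size_t)px * (y + (size_t)py * z);
        if (st[i] == 0) {
          st[i] = 2;
          stack.push_back((long long)i);
        }
      }
  // span fill: expand each seed along x, then seed run starts above,
  // below, in front and behind the span
  const long long dy4[4] = {px, -px, (long long)px * py, -(long long)px * py};
  while (!stack.empty()) {
    long long i = stack.back();
    stack.pop_back();
    long long l = i, r = i;
    while (st[l - 1] == 0) st[--l] = 2;
    while (st[r + 1] == 0) st[++r] = 2;
    for (int k = 0; k < 4; ++k) {
      long long d = dy4[k];
      for (long long j = l; j <= r; ++j) {
        if (st[j + d] == 0 && (j == l || st[j - 1 + d] != 0)) {
          st[j + d] = 2;
          stack.push_back(j + d);
        }
      }
    }
  }
  RawVector out(N);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      const uint8_t* src = &st[(size_t)1 + (size_t)px * ((y + 1) + (size_t)py * (z + 1))];
      Rbyte* dst = &out[(size_t)nx * (y + (size_t)ny * z)];
      for (int x = 0; x < nx; ++x)
        dst[x] = (src[x] == 1 || src[x] == 0) ? 1 : 0;
    }
  out.attr("dim") = dims;
  return out;
}

//' @noRd
// [[Rcpp::export(name = ".count_components_cpp")]]
int count_components_cpp(RawVector mask, IntegerVector dims, int connectivity) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t N = (size_t)nx * ny * nz;
  std::vector<uint8_t> seen(N, 0);
  std::vector<long long> stack;
  int ncomp = 0;

  std::vector<int> offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && m != 1) continue;
        offs.push_back(dx); offs.push_back(dy); offs.push_back(dz);
      }

  for (size_t i0 = 0; i0 < N; ++i0) {
    if (mask[i0] == 0 || seen[i0]) continue;
    ++ncomp;
    seen[i0] = 1;
    stack.push_back((long long)i0);
    while (!stack.empty()) {
      size_t i = (size_t)stack.back();
      stack.pop_back();
      int x = (int)(i % nx);
      int y = (int)((i / nx) % ny);
      int z = (int)(i / ((size_t)nx * ny));
      for (size_t k = 0; k < offs.size(); k += 3) {
        int xx = x + offs[k], yy = y + offs[k + 1], zz = z + offs[k + 2];
        if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz) continue;
        size_t j = (size_t)xx + (size_t)nx * (yy + (size_t)ny * zz);
        if (mask[j] != 0 && !seen[j]) {
          seen[j] = 1;
          stack.push_back((long long)j);
        }
      }
    }
  }
  return ncomp;
}
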