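#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Volumes arrive as R arrays with dim = (nz, ny, nx), column-major, so the
// linear index of voxel (z, y, x) (zero-based) is z + nz*(y + ny*x).

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// [[Rcpp::export(name = ".median_filter_3d_cpp")]]
NumericVector median_filter_3d_cpp(NumericVector vol, IntegerVector dim, int radius) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  NumericVector out(vol.size());
  const int w = 2 * radius + 1;
  std::vector<double> nb(static_cast<size_t>(w) * w * w);
  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) {
      for (int z = 0; z < nz; ++z) {
        size_t k = 0;
        // border policy: edge replication via index clamping
        for (int dx = -radius; dx <= radius; ++dx) {
          const int xx = clampi(x + dx, 0, nx - 1);
          for (int dy = -radius; dy <= radius; ++dy) {
            const int yy = clampi(y + dy, 0, ny - 1);
            for (int dz = -radius; dz <= radius; ++dz) {
              const int zz = clampi(z + dz, 0, nz - 1);
              nb[k++] = vol[zz + nz * (yy + static_cast<size_t>(ny) * xx)];
            }
          }
        }
        std::nth_element(nb.begin(), nb.begin() + k / 2, nb.begin() + k);
        out[z + nz * (y + static_cast<size_t>(ny) * x)] = nb[k / 2];
      }
    }
  }
  return out;
}

// 1D squared-distance transform (lower envelope of parabolas),
// Felzenszwalb & Huttenlocher; all f finite (borders are seeded in pass 1).
static void dt1d(const double *f, double *d, int n, int *v, double *zbuf) {
  int k = 0;
  v[0] = 0;
  zbuf[0] = -INFINITY;
  zbuf[1] = INFINITY;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) / (2.0 * q - 2.0 * v[k]);
    while (s <= zbuf[k]) {
      --k;
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) / (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    zbuf[k] = s;
    zbuf[k + 1] = INFINITY;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zbuf[k + 1] < q) ++k;
    const double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Exact squared Euclidean distance from every voxel to the nearest background
// voxel centre; voxels outside the volume count as background (so the first
// pass seeds border distances of i+1 / n-i along z).
// [[Rcpp::export(name = ".edt_sq_3d_cpp")]]
NumericVector edt_sq_3d_cpp(LogicalVector fg, IntegerVector dim) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const size_t n = static_cast<size_t>(nz) * ny * nx;
  NumericVector d2(n);

  // pass 1: 1D distance (not squared yet) to nearest background along z,
  // including virtual background just outside the volume
  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) {
      const size_t base = nz * (y + static_cast<size_t>(ny) * x);
      double prev = 1.0; // virtual background at z = -1
      for (int z = 0; z < nz; ++z) {
        prev = fg[base + z] ? prev : 0.0;
        d2[base + z] = prev;
        prev += 1.0;
      }
      prev = 1.0; // virtual background at z = nz
      for (int z = nz - 1; z >= 0; --z) {
        prev = fg[base + z] ? prev : 0.0;
        if (prev < d2[base + z]) d2[base + z] = prev;
        prev += 1.0;
      }
      for (int z = 0; z < nz; ++z) d2[base + z] *= d2[base + z];
    }
  }

  const int nmax = std::max(std::max(nz, ny), nx);
  std::vector<double> f(nmax), dd(nmax), zb(nmax + 1);
  std::vector<int> v(nmax);

  // pass 2: along y, but account for virtual background beyond the y faces
  for (int x = 0; x < nx; ++x) {
    for (int z = 0; z < nz; ++z) {
      for (int y = 0; y < ny; ++y) f[y] = d2[z + nz * (y + static_cast<size_t>(ny) * x)];
      dt1d(f.data(), dd.data(), ny, v.data(), zb.data());
      for (int y = 0; y < ny; ++y) {
        double bd = std::min(y + 1.0, (double)(ny - y));
        double lim = bd * bd;
        d2[z + nz * (y + static_cast<size_t>(ny) * x)] = std::min(dd[y], lim);
      }
    }
  }
  // pass 3: along x, same virtual-border cap
  for (int y = 0; y < ny; ++y) {
    for (int z = 0; z < nz; ++z) {
      for (int x = 0; x < nx; ++x) f[x] = d2[z + nz * (y + static_cast<size_t>(ny) * x)];
      dt1d(f.data(), dd.data(), nx, v.data(), zb.data());
      for (int x = 0; x < nx; ++x) {
        double bd = std::min(x + 1.0, (double)(nx - x));
        double lim = bd * bd;
        d2[z + nz * (y + static_cast<size_t>(ny) * x)] = std::min(dd[x], lim);
      }
    }
  }
  return d2;
}

// Local thickness (maximal inscribed spheres): per foreground voxel p the
// diameter of the largest sphere containing p that fits in the foreground.
// Sphere at q has radius r(q) = EDT(q) - 0.5; voxel p belongs to it iff
// |p - q| < r + 0.5, i.e. (integer) dist2(p,q) < EDT2(q). Thickness is
// 2*EDT(q) - 1 voxels. Spheres wholly contained in a 26-neighbour's sphere
// are pruned before painting (containment: r_p >= r_q + |p - q|; pruning uses
// a conservative margin so only certainly-redundant spheres are dropped —
// painting a redundant sphere cannot change the maximum).
// [[Rcpp::export(name = ".local_thickness_cpp")]]
NumericVector local_thickness_cpp(LogicalVector fg, IntegerVector dim) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  NumericVector d2 = edt_sq_3d_cpp(fg, dim);
  const size_t n = d2.size();
  NumericVector thick(n);

  std::vector<char> keep(n, 0);
  for (size_t i = 0; i < n; ++i) keep[i] = fg[i] ? 1 : 0;

  const double eps = 1e-9;
  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) {
      for (int z = 0; z < nz; ++z) {
        const size_t i = z + nz * (y + static_cast<size_t>(ny) * x);
        if (!keep[i]) continue;
        const double rq = std::sqrt(d2[i]);
        bool dominated = false;
        for (int dx = -1; dx <= 1 && !dominated; ++dx) {
          const int xx = x + dx; if (xx < 0 || xx >= nx) continue;
          for (int dy = -1; dy <= 1 && !dominated; ++dy) {
            const int yy = y + dy; if (yy < 0 || yy >= ny) continue;
            for (int dz = -1; dz <= 1; ++dz) {
              const int zz = z + dz; if (zz < 0 || zz >= nz) continue;
              if (dx == 0 && dy == 0 && dz == 0) continue;
              const size_t j = zz + nz * (yy + static_cast<size_t>(ny) * xx);
              if (!fg[j]) continue;
              const double dist = std::sqrt((double)(dx * dx + dy * dy + dz * dz));
              if (std::sqrt(d2[j]) - rq - dist >= eps) { dominated = true; break; }
            }
          }
        }
        if (dominated) keep[i] = 0;
      }
    }
  }

  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) {
      for (int z = 0; z < nz; ++z) {
        const size_t i = z + nz * (y + static_cast<size_t>(ny) * x);
        if (!keep[i]) continue;
        const long long r2 = (long long)(d2[i] + 0.5); // exact integer square
        const double diam = 2.0 * std::sqrt(d2[i]) - 1.0;
        const int rad = (int)std::ceil(std::sqrt((double)r2));
        for (int dx = -rad; dx <= rad; ++dx) {
          const int xx = x + dx; if (xx < 0 || xx >= nx) continue;
          for (int dy = -rad; dy <= rad; ++dy) {
            const int yy = y + dy; if (yy < 0 || yy >= ny) continue;
            const long long pxy = (long long)dx * dx + (long long)dy * dy;
            if (pxy >= r2) continue;
            for (int dz = -rad; dz <= rad; ++dz) {
              const int zz = z + dz; if (zz < 0 || zz >= nz) continue;
              if (pxy + (long long)dz * dz >= r2) continue; // strict: |p-q| < r + 0.5
              const size_t j = zz + nz * (yy + static_cast<size_t>(ny) * xx);
              if (fg[j] && diam > thick[j]) thick[j] = diam;
            }
          }
        }
      }
    }
  }
  return thick;
}
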