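#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <queue>
using namespace Rcpp;

// Per-voxel clearance: min over atoms of (distance from voxel center to atom
// center - atom vdW radius), capped at `cap`.  Voxel (i,j,k) center is
// origin + (i,j,k)*edge.  Negative clearance marks van der Waals occupancy.
// [[Rcpp::export]]
NumericVector pore_clearance_cpp(NumericMatrix coords, NumericVector radii,
                                 NumericVector origin, IntegerVector dims,
                                 double edge, double cap) {
  const int nxv = dims[0], nyv = dims[1], nzv = dims[2];
  const size_t N = (size_t)nxv * nyv * nzv;
  NumericVector out(N, cap);
  double *clr = REAL(out);
  const int na = coords.nrow();
  for (int a = 0; a < na; ++a) {
    double ax = coords(a, 0), ay = coords(a, 1), az = coords(a, 2);
    double ra = radii[a];
    double reach = ra + cap;
    int i0 = (int)std::floor((ax - reach - origin[0]) / edge);
    int i1 = (int)std::ceil((ax + reach - origin[0]) / edge);
    int j0 = (int)std::floor((ay - reach - origin[1]) / edge);
    int j1 = (int)std::ceil((ay + reach - origin[1]) / edge);
    int k0 = (int)std::floor((az - reach - origin[2]) / edge);
    int k1 = (int)std::ceil((az + reach - origin[2]) / edge);
    if (i0 < 0) i0 = 0; if (j0 < 0) j0 = 0; if (k0 < 0) k0 = 0;
    if (i1 > nxv - 1) i1 = nxv - 1;
    if (j1 > nyv - 1) j1 = nyv - 1;
    if (k1 > nzv - 1) k1 = nzv - 1;
    for (int k = k0; k <= k1; ++k) {
      double dz = origin[2] + k * edge - az;
      for (int j = j0; j <= j1; ++j) {
        double dy = origin[1] + j * edge - ay;
        double dyz = dy * dy + dz * dz;
        size_t base = ((size_t)k * nyv + j) * nxv;
        for (int i = i0; i <= i1; ++i) {
          double dxx = origin[0] + i * edge - ax;
          double c = std::sqrt(dxx * dxx + dyz) - ra;
          if (c < clr[base + i]) clr[base + i] = c;
        }
      }
    }
  }
  out.attr("dim") = dims;
  return out;
}

// Flood fill over the feasible set {clearance >= probe_radius} from the top
// z-slab (extracellular entry, nz_slab layers) towards the bottom slab.
// connectivity: 6 or 26.  Returns verdict: 2 = pass, 1 = blocked,
// 0 = blocked with no aperture (entry slab entirely infeasible).
// [[Rcpp::export]]
int pore_flood_cpp(NumericVector clearance, IntegerVector dims,
                   double probe_radius, int connectivity, int nz_slab) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t N = (size_t)nx * ny * nz;
  const double *clr = REAL(clearance);
  if (connectivity != 6 && connectivity != 26)
    stop("connectivity must be 6 or 26");
  if (nz_slab < 1 || 2 * nz_slab > nz) stop("invalid entry/exit slab depth");

  std::vector<char> seen(N, 0);
  std::vector<int> stack;
  stack.reserve(1024);
  bool entry_any = false;
  for (int k = nz - nz_slab; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        size_t id = ((size_t)k * ny + j) * nx + i;
        if (clr[id] >= probe_radius) {
          entry_any = true;
          if (!seen[id]) { seen[id] = 1; stack.push_back((int)id); }
        }
      }
  if (!entry_any) return 0;

  while (!stack.empty()) {
    int id = stack.back();
    stack.pop_back();
    int i = id % nx, j = (id / nx) % ny, k = id / (nx * ny);
    if (k < nz_slab) return 2;  // reached the exit slab
    for (int dk = -1; dk <= 1; ++dk)
      for (int dj = -1; dj <= 1; ++dj)
        for (int di = -1; di <= 1; ++di) {
          if (di == 0 && dj == 0 && dk == 0) continue;
          if (connectivity == 6 &&
              std::abs(di) + std::abs(dj) + std::abs(dk) != 1)
            continue;
          int ii = i + di, jj = j + dj, kk = k + dk;
          if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
            continue;
          size_t nid = ((size_t)kk * ny + jj) * nx + ii;
          if (!seen[nid] && clr[nid] >= probe_radius) {
            seen[nid] = 1;
            stack.push_back((int)nid);
          }
        }
  }
  return 1;
}

// Exact Euclidean distance transform (Felzenszwalb-Huttenlocher lower
// envelope, separable in three passes) of a binary occupancy grid.
// Returns per-voxel distance (in the units of `edge`) to the nearest
// occupied voxel center; 0 inside the occupancy.
static void dt1d(const std::vector<double> &f, std::vector<double> &d, int n,
                 std::vector<int> &v, std::vector<double> &z) {
  int kk = 0;
  v[0] = 0;
  z[0] = -1e30;
  z[1] = 1e30;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * q) - (f[v[kk]] + v[kk] * v[kk])) / (2.0 * q - 2.0 * v[kk]);
      if (s <= z[kk]) { --kk; } else break;
    }
    ++kk;
    v[kk] = q;
    z[kk] = s;
    z[kk + 1] = 1e30;
  }
  kk = 0;
  for (int q = 0; q < n; ++q) {
    while (z[kk + 1] < q) ++kk;
    d[q] = (q - v[kk]) * (q - v[kk]) + f[v[kk]];
  }
}

// [[Rcpp::export]]
NumericVector pore_edt_cpp(LogicalVector occ, IntegerVector dims, double edge) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t N = (size_t)nx * ny * nz;
  const double INF = 1e30;
  std::vector<double> g(N);
  for (size_t i = 0; i < N; ++i) g[i] = occ[i] ? 0.0 : INF;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // x pass
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      size_t base = ((size_t)k * ny + j) * nx;
      for (int i = 0; i < nx; ++i) f[i] = g[base + i];
      dt1d(f, d, nx, v, z);
      for (int i = 0; i < nx; ++i) g[base + i] = d[i];
    }
  // y pass
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      for (int j = 0; j < ny; ++j) f[j] = g[((size_t)k * ny + j) * nx + i];
      dt1d(f, d, ny, v, z);
      for (int j = 0; j < ny; ++j) g[((size_t)k * ny + j) * nx + i] = d[j];
    }
  // z pass
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      for (int k = 0; k < nz; ++k) f[k] = g[((size_t)k * ny + j) * nx + i];
      dt1d(f, d, nz, v, z);
      for (int k = 0; k < nz; ++k) g[((size_t)k * ny + j) * nx + i] = d[k];
    }

  NumericVector out(N);
  for (size_t i = 0; i < N; ++i) out[i] = std::sqrt(g[i]) * edge;
  out.attr("dim") = dims;
  return out;
}
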