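#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Flat neuron index convention shared with the R side: for map dims (I,J,K)
// flat = ((i-1)*J + (j-1))*K + (k-1)  [0-based here], i.e. k varies fastest.
// This equals R array order for an array of dim c(K, J, I).

static inline void flat_to_ijk(int f, int J, int K, int &i, int &j, int &k) {
  k = f % K;
  j = (f / K) % J;
  i = f / (K * J);
}

// [[Rcpp::export]]
int cpp_bmu_one(const NumericMatrix &codes, double x, double y, double z) {
  int n = codes.nrow();
  double best = R_PosInf;
  int best_i = 0;
  for (int f = 0; f < n; ++f) {
    double dx = codes(f, 0) - x, dy = codes(f, 1) - y, dz = codes(f, 2) - z;
    double d2 = dx * dx + dy * dy + dz * dz;
    if (d2 < best) { best = d2; best_i = f; }
  }
  return best_i; // 0-based; first (smallest flat) wins ties via strict <
}

// [[Rcpp::export]]
IntegerVector cpp_bmu(const NumericMatrix &codes, const NumericMatrix &pts) {
  int m = pts.nrow();
  IntegerVector out(m);
  for (int p = 0; p < m; ++p)
    out[p] = cpp_bmu_one(codes, pts(p, 0), pts(p, 1), pts(p, 2));
  return out;
}

// One training phase. order: 0-based point indices, length = cycles * n.
// Radius / learning rate decay exponentially with lambda = length(order)/10.
// Gaussian neighborhood in map-index space, applied to every neuron.
// [[Rcpp::export]]
NumericMatrix cpp_som_phase(NumericMatrix codes, int I, int J, int K,
                            const NumericMatrix &pts, const IntegerVector &order,
                            double r0, double rf, double a0, double af) {
  int n_neu = codes.nrow();
  int T = order.size();
  double lambda = (double)T / 10.0;
  std::vector<int> ii(n_neu), jj(n_neu), kk(n_neu);
  for (int f = 0; f < n_neu; ++f) flat_to_ijk(f, J, K, ii[f], jj[f], kk[f]);
  for (int t = 0; t < T; ++t) {
    double decay = std::exp(-(double)t / lambda);
    double r = (r0 - rf) * decay + rf;
    double a = (a0 - af) * decay + af;
    int p = order[t];
    double x = pts(p, 0), y = pts(p, 1), z = pts(p, 2);
    int b = cpp_bmu_one(codes, x, y, z);
    int bi = ii[b], bj = jj[b], bk = kk[b];
    double inv2r2 = 1.0 / (2.0 * r * r);
    for (int f = 0; f < n_neu; ++f) {
      double di = ii[f] - bi, dj = jj[f] - bj, dk = kk[f] - bk;
      double h = a * std::exp(-(di * di + dj * dj + dk * dk) * inv2r2);
      codes(f, 0) += h * (x - codes(f, 0));
      codes(f, 1) += h * (y - codes(f, 1));
      codes(f, 2) += h * (z - codes(f, 2));
    }
  }
  return codes;
}

// Same phase but with a hard radius cutoff instead of applying the Gaussian
// kernel to every neuron (config option; see the methods vignette).
// [[Rcpp::export]]
NumericMatrix cpp_som_phase_cutoff(NumericMatrix codes, int I, int J, int K,
                                   const NumericMatrix &pts,
                                   const IntegerVector &order,
                                   double r0, double rf, double a0, double af) {
  int n_neu = codes.nrow();
  int T = order.size();
  double lambda = (double)T / 10.0;
  std::vector<int> ii(n_neu), jj(n_neu), kk(n_neu);
  for (int f = 0; f < n_neu; ++f) flat_to_ijk(f, J, K, ii[f], jj[f], kk[f]);
  for (int t = 0; t < T; ++t) {
    double decay = std::exp(-(double)t / lambda);
    double r = (r0 - rf) * decay + rf;
    double a = (a0 - af) * decay + af;
    int p = order[t];
    double x = pts(p, 0), y = pts(p, 1), z = pts(p, 2);
    int b = cpp_bmu_one(codes, x, y, z);
    int bi = ii[b], bj = jj[b], bk = kk[b];
    double r2max = r * r;
    double inv2r2 = 1.0 / (2.0 * r * r);
    for (int f = 0; f < n_neu; ++f) {
      double di = ii[f] - bi, dj = jj[f] - bj, dk = kk[f] - bk;
      double d2 = di * di + dj * dj + dk * dk;
      if (d2 > r2max) continue;
      double h = a * std::exp(-d2 * inv2r2);
      codes(f, 0) += h * (x - codes(f, 0));
      codes(f, 1) += h * (y - codes(f, 1));
      codes(f, 2) += h * (z - codes(f, 2));
    }
  }
  return codes;
}

// Connected-component labeling of TRUE cells of a 3D logical field under
// 26-connectivity. dims = c(n1, n2, n3) with the first index fastest
// (plain R array order). Returns 0 for FALSE cells, 1..n component labels
// (label order follows first-encountered cell in array order).
// [[Rcpp::export]]
IntegerVector cpp_label26(const LogicalVector &mask, const IntegerVector &dims) {
  int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  int n = n1 * n2 * n3;
  IntegerVector lab(n, 0);
  std::vector<int> stack;
  int next = 0;
  for (int s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.push_back(s);
    while (!stack.empty()) {
      int c = stack.back(); stack.pop_back();
      int a1 = c % n1, a2 = (c / n1) % n2, a3 = c / (n1 * n2);
      for (int d3 = -1; d3 <= 1; ++d3) {
        int b3 = a3 + d3; if (b3 < 0 || b3 >= n3) continue;
        for (int d2 = -1; d2 <= 1; ++d2) {
          int b2 = a2 + d2; if (b2 < 0 || b2 >= n2) continue;
          for (int d1 = -1; d1 <= 1; ++d1) {
            int b1 = a1 + d1; if (b1 < 0 || b1 >= n1) continue;
            int q = b1 + n1 * (b2 + n2 * b3);
            if (mask[q] && lab[q] == 0) { lab[q] = next; stack.push_back(q); }
          }
        }
      }
    }
  }
  return lab;
}

// Geometric accessibility: a voxel center is accessible iff for every atom
// distance(center, atom) >= vdw(atom) + probe. Computed by stamping blocked
// spheres per atom in a local sub-box. origin is the center of voxel (0,0,0).
// [[Rcpp::export]]
LogicalVector cpp_access_mask(const IntegerVector &dims, const NumericVector &origin,
                              double spacing, const NumericMatrix &xyz,
                              const NumericVector &radii, double probe) {
  int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  LogicalVector acc(n1 * n2 * n3, true);
  int natom = xyz.nrow();
  for (int a = 0; a < natom; ++a) {
    double block = radii[a] + probe;
    double b2 = block * block;
    double ax = xyz(a, 0), ay = xyz(a, 1), az = xyz(a, 2);
    int lo1 = (int)std::ceil((ax - block - origin[0]) / spacing);
    int hi1 = (int)std::floor((ax + block - origin[0]) / spacing);
    int lo2 = (int)std::ceil((ay - block - origin[1]) / spacing);
    int hi2 = (int)std::floor((ay + block - origin[1]) / spacing);
    int lo3 = (int)std::ceil((az - block - origin[2]) / spacing);
    int hi3 = (int)std::floor((az + block - origin[2]) / spacing);
    if (lo1 < 0) lo1 = 0; if (hi1 >= n1) hi1 = n1 - 1;
    if (lo2 < 0) lo2 = 0; if (hi2 >= n2) hi2 = n2 - 1;
    if (lo3 < 0) lo3 = 0; if (hi3 >= n3) hi3 = n3 - 1;
    for (int i3 = lo3; i3 <= hi3; ++i3) {
      double dz = origin[2] + i3 * spacing - az;
      for (int i2 = lo2; i2 <= hi2; ++i2) {
        double dy = origin[1] + i2 * spacing - ay;
        double dzy = dz * dz + dy * dy;
        if (dzy > b2) continue;
        for (int i1 = lo1; i1 <= hi1; ++i1) {
          double dx = origin[0] + i1 * spacing - ax;
          if (dx * dx + dzy < b2)
            acc[i1 + n1 * (i2 + n2 * i3)] = false;
        }
      }
    }
  }
  return acc;
}

// Flood fill of TRUE cells reachable from the grid boundary (26-connectivity).
// [[Rcpp::export]]
LogicalVector cpp_boundary_reach26(const LogicalVector &mask, const IntegerVector &dims) {
  int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  int n = n1 * n2 * n3;
  LogicalVector vis(n, false);
  std::vector<int> stack;
  for (int s = 0; s < n; ++s) {
    int a1 = s % n1, a2 = (s / n1) % n2, a3 = s / (n1 * n2);
    bool boundary = (a1 == 0 || a1 == n1 - 1 || a2 == 0 || a2 == n2 - 1 ||
                     a3 == 0 || a3 == n3 - 1);
    if (boundary && mask[s] && !vis[s]) { vis[s] = true; stack.push_back(s); }
  }
  while (!stack.empty()) {
    int c = stack.back(); stack.pop_back();
    int a1 = c % n1, a2 = (c / n1) % n2, a3 = c / (n1 * n2);
    for (int d3 = -1; d3 <= 1; ++d3) {
      int b3 = a3 + d3; if (b3 < 0 || b3 >= n3) continue;
      for (int d2 = -1; d2 <= 1; ++d2) {
        int b2 = a2 + d2; if (b2 < 0 || b2 >= n2) continue;
        for (int d1 = -1; d1 <= 1; ++d1) {
          int b1 = a1 + d1; if (b1 < 0 || b1 >= n1) continue;
          int q = b1 + n1 * (b2 + n2 * b3);
          if (mask[q] && !vis[q]) { vis[q] = true; stack.push_back(q); }
        }
      }
    }
  }
  return vis;
}

// Minimum distance from each query point to any row of ref (used for
// precision and feature->cluster assignment).
// [[Rcpp::export]]
NumericVector cpp_min_dist(const NumericMatrix &query, const NumericMatrix &ref) {
  int nq = query.nrow(), nr = ref.nrow();
  NumericVector out(nq);
  for (int q = 0; q < nq; ++q) {
    double best = R_PosInf;
    double x = query(q, 0), y = query(q, 1), z = query(q, 2);
    for (int r = 0; r < nr; ++r) {
      double dx = ref(r, 0) - x, dy = ref(r, 1) - y, dz = ref(r, 2) - z;
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[q] = std::sqrt(best);
  }
  return out;
}

// Exact squared Euclidean distance transform (Felzenszwalb & Huttenlocher):
// per voxel, squared distance (in voxel units) to the nearest TRUE cell.
// Used to turn allowed-probe-center masks into probe-sphere coverage.
static void edt1d(std::vector<double> &f, std::vector<double> &d,
                  std::vector<int> &v, std::vector<double> &zbuf, int n) {
  int k = 0;
  v[0] = 0;
  zbuf[0] = -1e30; zbuf[1] = 1e30;
  for (int q = 1; q < n; ++q) {
    if (f[q] >= 1e29) continue;
    double s;
    while (true) {
      if (k < 0) break;
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= zbuf[k]) { --k; } else break;
    }
    if (k < 0) { k = 0; v[0] = q; zbuf[0] = -1e30; zbuf[1] = 1e30; }
    else { ++k; v[k] = q; zbuf[k] = s; zbuf[k + 1] = 1e30; }
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zbuf[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_sq_edt(const LogicalVector &mask, const IntegerVector &dims) {
  int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  int n = n1 * n2 * n3;
  std::vector<double> g(n);
  for (int s = 0; s < n; ++s) g[s] = mask[s] ? 0.0 : 1e30;
  int nmax = std::max(n1, std::max(n2, n3));
  std::vector<double> f(nmax), d(nmax), zbuf(nmax + 1);
  std::vector<int> v(nmax);
  // pass along axis 1
  for (int i3 = 0; i3 < n3; ++i3)
    for (int i2 = 0; i2 < n2; ++i2) {
      int base = n1 * (i2 + n2 * i3);
      bool any = false;
      for (int q = 0; q < n1; ++q) { f[q] = g[base + q]; if (f[q] < 1e29) any = true; }
      if (!any) continue;
      edt1d(f, d, v, zbuf, n1);
      for (int q = 0; q < n1; ++q) g[base + q] = d[q];
    }
  // axis 2
  for (int i3 = 0; i3 < n3; ++i3)
    for (int i1 = 0; i1 < n1; ++i1) {
      bool any = false;
      for (int q = 0; q < n2; ++q) { f[q] = g[i1 + n1 * (q + n2 * i3)]; if (f[q] < 1e29) any = true; }
      if (!any) continue;
      edt1d(f, d, v, zbuf, n2);
      for (int q = 0; q < n2; ++q) g[i1 + n1 * (q + n2 * i3)] = d[q];
    }
  // axis 3
  for (int i2 = 0; i2 < n2; ++i2)
    for (int i1 = 0; i1 < n1; ++i1) {
      bool any = false;
      for (int q = 0; q < n3; ++q) { f[q] = g[i1 + n1 * (i2 + n2 * q)]; if (f[q] < 1e29) any = true; }
      if (!any) continue;
      edt1d(f, d, v, zbuf, n3);
      for (int q = 0; q < n3; ++q) g[i1 + n1 * (i2 + n2 * q)] = d[q];
    }
  return NumericVector(g.begin(), g.end());
}
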