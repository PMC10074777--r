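#include <Rcpp.h>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

// Sparse voxel-set primitives. Voxels are addressed by 0-based linear index
// into an (nx, ny, nz) column-major array: idx = i + nx * (j + ny * k).
// Working on index sets rather than dense arrays keeps the cost proportional
// to the lesion burden, not the brain volume.

static inline long long key3(int i, int j, int k, int nx, int ny) {
  return (long long)i + (long long)nx * ((long long)j + (long long)ny * k);
}

// Label 26-connected components of a sparse voxel set.
// idx0: 0-based linear indices; dims: array extents.
// Returns a 1-based component label per input voxel (labels arbitrary but
// deterministic given input order; callers re-order components).
// [[Rcpp::export(name = ".cc_label26")]]
IntegerVector cc_label26(IntegerVector idx0, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1];
  const R_xlen_t n = idx0.size();
  std::unordered_map<long long, R_xlen_t> pos;
  pos.reserve(n * 2);
  std::vector<int> ii(n), jj(n), kk(n);
  for (R_xlen_t t = 0; t < n; ++t) {
    long long v = (long long)idx0[t];
    int i = (int)(v % nx);
    long long r = v / nx;
    int j = (int)(r % ny);
    int k = (int)(r / ny);
    ii[t] = i; jj[t] = j; kk[t] = k;
    pos[v] = t;
  }
  IntegerVector label(n, 0);
  int next_label = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t t = 0; t < n; ++t) {
    if (label[t] != 0) continue;
    ++next_label;
    label[t] = next_label;
    stack.clear();
    stack.push_back(t);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      const int ci = ii[cur], cj = jj[cur], ck = kk[cur];
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0 && dk == 0) continue;
            auto it = pos.find(key3(ci + di, cj + dj, ck + dk, nx, ny));
            if (it == pos.end()) continue;
            R_xlen_t nb = it->second;
            if (label[nb] == 0) {
              label[nb] = next_label;
              stack.push_back(nb);
            }
          }
    }
  }
  return label;
}

// Flag surface voxels: members with at least one 6-neighbor outside the set
// (voxels on the grid boundary count as surface).
// [[Rcpp::export(name = ".surface6")]]
LogicalVector surface6(IntegerVector idx0, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = idx0.size();
  std::unordered_map<long long, char> in;
  in.reserve(n * 2);
  for (R_xlen_t t = 0; t < n; ++t) in[(long long)idx0[t]] = 1;
  LogicalVector out(n);
  const int di[6] = {1, -1, 0, 0, 0, 0};
  const int dj[6] = {0, 0, 1, -1, 0, 0};
  const int dk[6] = {0, 0, 0, 0, 1, -1};
  for (R_xlen_t t = 0; t < n; ++t) {
    long long v = (long long)idx0[t];
    int i = (int)(v % nx);
    long long r = v / nx;
    int j = (int)(r % ny);
    int k = (int)(r / ny);
    bool surf = false;
    for (int d = 0; d < 6 && !surf; ++d) {
      int pi = i + di[d], pj = j + dj[d], pk = k + dk[d];
      if (pi < 0 || pi >= nx || pj < 0 || pj >= ny || pk < 0 || pk >= nz)
        surf = true;
      else if (in.find(key3(pi, pj, pk, nx, ny)) == in.end())
        surf = true;
    }
    out[t] = surf;
  }
  return out;
}

// Directed nearest-neighbor distances: for each row (point) of `a`, the
// minimum Euclidean distance to any row of `b`. Brute force; surface sets
// in this application are small enough that O(nm) beats tree overhead.
// [[Rcpp::export(name = ".nn_dist")]]
NumericVector nn_dist(NumericMatrix a, NumericMatrix b) {
  const R_xlen_t na = a.nrow(), nb = b.nrow();
  NumericVector out(na);
  std::vector<double> bx(nb), by(nb), bz(nb);
  for (R_xlen_t q = 0; q < nb; ++q) {
    bx[q] = b(q, 0); by[q] = b(q, 1); bz[q] = b(q, 2);
  }
  for (R_xlen_t p = 0; p < na; ++p) {
    const double ax = a(p, 0), ay = a(p, 1), az = a(p, 2);
    double best = R_PosInf;
    for (R_xlen_t q = 0; q < nb; ++q) {
      const double dx = ax - bx[q], dy = ay - by[q], dz = az - bz[q];
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[p] = std::sqrt(best);
  }
  return out;
}
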