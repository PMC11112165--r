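#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <functional>
#include <unordered_map>
#include <limits>
using namespace Rcpp;

// Volumes are R arrays with dim = (z, y, x); first index varies fastest.
static inline R_xlen_t idx3(int z, int y, int x, int Z, int Y) {
  return (R_xlen_t)z + (R_xlen_t)Z * ((R_xlen_t)y + (R_xlen_t)Y * (R_xlen_t)x);
}

// reflect index into [0, n-1]
static inline int reflect(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// Separable Gaussian smoothing with per-axis sigma in voxel units.
// [[Rcpp::export]]
NumericVector cpp_gauss3d(NumericVector vol, IntegerVector dim, NumericVector sigma) {
  int Z = dim[0], Y = dim[1], X = dim[2];
  NumericVector src = clone(vol);
  NumericVector dst(vol.size());
  int strides_n[3] = {Z, Y, X};

  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma[ax];
    if (s <= 0) continue;
    int r = (int)std::ceil(3.0 * s);
    std::vector<double> k(2 * r + 1);
    double ksum = 0;
    for (int i = -r; i <= r; ++i) { k[i + r] = std::exp(-0.5 * i * i / (s * s)); ksum += k[i + r]; }
    for (double &v : k) v /= ksum;

    int n = strides_n[ax];
    for (int z = 0; z < (ax == 0 ? 1 : Z); ++z)
      for (int y = 0; y < (ax == 1 ? 1 : Y); ++y)
        for (int x = 0; x < (ax == 2 ? 1 : X); ++x)
          for (int i = 0; i < n; ++i) {
            double acc = 0;
            for (int j = -r; j <= r; ++j) {
              int ii = reflect(i + j, n);
              R_xlen_t id;
              if (ax == 0) id = idx3(ii, y, x, Z, Y);
              else if (ax == 1) id = idx3(z, ii, x, Z, Y);
              else id = idx3(z, y, ii, Z, Y);
              acc += k[j + r] * src[id];
            }
            R_xlen_t od;
            if (ax == 0) od = idx3(i, y, x, Z, Y);
            else if (ax == 1) od = idx3(z, i, x, Z, Y);
            else od = idx3(z, y, i, Z, Y);
            dst[od] = acc;
          }
    std::copy(dst.begin(), dst.end(), src.begin());
  }
  src.attr("dim") = dim;
  return src;
}

// 6-connected component labelling of a binary mask.
// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dim) {
  int Z = dim[0], Y = dim[1], X = dim[2];
  R_xlen_t N = mask.size();
  std::vector<int> parent(N, -1);
  std::function<int(int)> find = [&](int a) {
    while (parent[a] != a) { parent[a] = parent[parent[a]]; a = parent[a]; }
    return a;
  };
  auto unite = [&](int a, int b) {
    a = find(a); b = find(b);
    if (a != b) parent[b] = a;
  };
  for (int x = 0; x < X; ++x)
    for (int y = 0; y < Y; ++y)
      for (int z = 0; z < Z; ++z) {
        R_xlen_t id = idx3(z, y, x, Z, Y);
        if (!mask[id]) continue;
        parent[id] = (int)id;
        if (z > 0 && mask[idx3(z - 1, y, x, Z, Y)]) unite((int)id, (int)idx3(z - 1, y, x, Z, Y));
        if (y > 0 && mask[idx3(z, y - 1, x, Z, Y)]) unite((int)id, (int)idx3(z, y - 1, x, Z, Y));
        if (x > 0 && mask[idx3(z, y, x - 1, Z, Y)]) unite((int)id, (int)idx3(z, y, x - 1, Z, Y));
      }
  IntegerVector lab(N, 0);
  std::unordered_map<int, int> remap;
  int next = 0;
  for (R_xlen_t i = 0; i < N; ++i) {
    if (parent[i] < 0) continue;
    int root = find((int)i);
    auto it = remap.find(root);
    if (it == remap.end()) { remap[root] = ++next; lab[i] = next; }
    else lab[i] = it->second;
  }
  lab.attr("dim") = dim;
  return lab;
}

// 1D squared distance transform (Felzenszwalb & Huttenlocher), sampled at
// physical spacing `step`.
static void dt1d(const std::vector<double> &f, std::vector<double> &d, double step) {
  int n = (int)f.size();
  std::vector<int> v(n);
  std::vector<double> zb(n + 1);
  int k = 0;
  v[0] = 0; zb[0] = -INFINITY; zb[1] = INFINITY;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      double qq = (double)q * step, vv = (double)v[k] * step;
      s = ((f[q] + qq * qq) - (f[v[k]] + vv * vv)) / (2 * qq - 2 * vv);
      if (s <= zb[k]) { --k; } else break;
    }
    ++k; v[k] = q; zb[k] = s; zb[k + 1] = INFINITY;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double qq = (double)q * step;
    while (zb[k + 1] < qq) ++k;
    double vv = (double)v[k] * step;
    d[q] = (qq - vv) * (qq - vv) + f[v[k]];
  }
}

// Anisotropic Euclidean distance transform: distance (um) from each foreground
// voxel to the nearest background voxel. spacing = um per axis (z, y, x).
// [[Rcpp::export]]
NumericVector cpp_edt3d(LogicalVector mask, IntegerVector dim, NumericVector spacing) {
  int Z = dim[0], Y = dim[1], X = dim[2];
  R_xlen_t N = mask.size();
  const double BIG = 1e20;
  NumericVector d(N);
  for (R_xlen_t i = 0; i < N; ++i) d[i] = mask[i] ? BIG : 0.0;

  std::vector<double> f, out;
  // axis z
  f.resize(Z); out.resize(Z);
  for (int x = 0; x < X; ++x)
    for (int y = 0; y < Y; ++y) {
      for (int z = 0; z < Z; ++z) f[z] = d[idx3(z, y, x, Z, Y)];
      dt1d(f, out, spacing[0]);
      for (int z = 0; z < Z; ++z) d[idx3(z, y, x, Z, Y)] = out[z];
    }
  // axis y
  f.resize(Y); out.resize(Y);
  for (int x = 0; x < X; ++x)
    for (int z = 0; z < Z; ++z) {
      for (int y = 0; y < Y; ++y) f[y] = d[idx3(z, y, x, Z, Y)];
      dt1d(f, out, spacing[1]);
      for (int y = 0; y < Y; ++y) d[idx3(z, y, x, Z, Y)] = out[y];
    }
  // axis x
  f.resize(X); out.resize(X);
  for (int y = 0; y < Y; ++y)
    for (int z = 0; z < Z; ++z) {
      for (int x = 0; x < X; ++x) f[x] = d[idx3(z, y, x, Z, Y)];
      dt1d(f, out, spacing[2]);
      for (int x = 0; x < X; ++x) d[idx3(z, y, x, Z, Y)] = out[x];
    }
  for (R_xlen_t i = 0; i < N; ++i) d[i] = std::sqrt(d[i]);
  d.attr("dim") = dim;
  return d;
}

struct WsNode {
  double prio;
  R_xlen_t order;
  R_xlen_t id;
  int lab;
};
struct WsCmp {
  bool operator()(const WsNode &a, const WsNode &b) const {
    if (a.prio != b.prio) return a.prio < b.prio;  // max-heap on priority
    return a.order > b.order;                      // FIFO tie-break
  }
};

// Marker-based watershed by priority flooding: seeds grow outward in order of
// decreasing `height` (the distance transform), constrained to `mask`.
// [[Rcpp::export]]
IntegerVector cpp_watershed3d(NumericVector height, IntegerVector markers,
                              LogicalVector mask, IntegerVector dim) {
  int Z = dim[0], Y = dim[1], X = dim[2];
  R_xlen_t N = mask.size();
  IntegerVector lab(N, 0);
  std::priority_queue<WsNode, std::vector<WsNode>, WsCmp> pq;
  R_xlen_t order = 0;
  for (R_xlen_t i = 0; i < N; ++i)
    if (markers[i] > 0) { lab[i] = markers[i]; pq.push({height[i], order++, i, markers[i]}); }

  const int dz[6] = {1, -1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, 1, -1, 0, 0};
  const int dx[6] = {0, 0, 0, 0, 1, -1};
  while (!pq.empty()) {
    WsNode nd = pq.top(); pq.pop();
    R_xlen_t i = nd.id;
    int x = (int)(i / ((R_xlen_t)Z * Y));
    int rem = (int)(i - (R_xlen_t)x * Z * Y);
    int y = rem / Z, z = rem % Z;
    for (int d6 = 0; d6 < 6; ++d6) {
      int zz = z + dz[d6], yy = y + dy[d6], xx = x + dx[d6];
      if (zz < 0 || zz >= Z || yy < 0 || yy >= Y || xx < 0 || xx >= X) continue;
      R_xlen_t j = idx3(zz, yy, xx, Z, Y);
      if (!mask[j] || lab[j] != 0) continue;
      lab[j] = nd.lab;
      pq.push({height[j], order++, j, nd.lab});
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

// Minimum-cost perfect assignment on a square cost matrix (Hungarian algorithm
// with potentials, O(n^3)). Returns 1-based column assigned to each row.
// [[Rcpp::export]]
IntegerVector cpp_hungarian(NumericMatrix cost) {
  int n = cost.nrow();
  if (cost.ncol() != n) stop("cost matrix must be square");
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> u(n + 1, 0), v(n + 1, 0);
  std::vector<int> p(n + 1, 0), way(n + 1, 0);
  for (int i = 1; i <= n; ++i) {
    p[0] = i;
    int j0 = 0;
    std::vector<double> minv(n + 1, INF);
    std::vector<char> used(n + 1, false);
    do {
      used[j0] = true;
      int i0 = p[j0], j1 = -1;
      double delta = INF;
      for (int j = 1; j <= n; ++j)
        if (!used[j]) {
          double cur = cost(i0 - 1, j - 1) - u[i0] - v[j];
          if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
          if (minv[j] < delta) { delta = minv[j]; j1 = j; }
        }
      for (int j = 0; j <= n; ++j) {
        if (used[j]) { u[p[j]] += delta; v[j] -= delta; }
        else minv[j] -= delta;
      }
      j0 = j1;
    } while (p[j0] != 0);
    do { int j1 = way[j0]; p[j0] = p[j1]; j0 = j1; } while (j0);
  }
  IntegerVector ans(n);
  for (int j = 1; j <= n; ++j)
    if (p[j] > 0) ans[p[j] - 1] = j;
  return ans;
}
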