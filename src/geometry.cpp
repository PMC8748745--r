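// Discrete 3D geometry kernels shared by the watershed / TASCAN stage.
// All volumes are R arrays with dim (Z, Y, X), col-major, z fastest.
// Connectivity is 6-neighborhood (shared voxel faces) throughout.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <map>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

static inline R_xlen_t vidx(int z, int y, int x, int Z, int Y) {
  return (R_xlen_t)z + (R_xlen_t)Z * ((R_xlen_t)y + (R_xlen_t)Y * (R_xlen_t)x);
}

static const int DZ[6] = { 1, -1, 0, 0, 0, 0 };
static const int DY[6] = { 0, 0, 1, -1, 0, 0 };
static const int DX[6] = { 0, 0, 0, 0, 1, -1 };

// [[Rcpp::export]]
IntegerVector cpp_label_components6(IntegerVector mask, IntegerVector dims) {
  int Z = dims[0], Y = dims[1], X = dims[2];
  R_xlen_t n = (R_xlen_t)Z * Y * X;
  IntegerVector lab(n, 0);
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (mask[s] == 0 || lab[s] != 0) continue;
    ++next;
    stack.push_back(s);
    lab[s] = next;
    while (!stack.empty()) {
      R_xlen_t cur = stack.back(); stack.pop_back();
      int x = (int)(cur / ((R_xlen_t)Z * Y));
      int rem = (int)(cur % ((R_xlen_t)Z * Y));
      int y = rem / Z, z = rem % Z;
      for (int k = 0; k < 6; ++k) {
        int zz = z + DZ[k], yy = y + DY[k], xx = x + DX[k];
        if (zz < 0 || zz >= Z || yy < 0 || yy >= Y || xx < 0 || xx >= X) continue;
        R_xlen_t q = vidx(zz, yy, xx, Z, Y);
        if (mask[q] != 0 && lab[q] == 0) { lab[q] = next; stack.push_back(q); }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

// Node surface areas S_u (exposed faces, volume boundary included) and
// pairwise touching areas S_uv (shared faces) for a supervoxel labeling.
// [[Rcpp::export]]
List cpp_touching_graph(IntegerVector lab, IntegerVector dims) {
  int Z = dims[0], Y = dims[1], X = dims[2];
  std::map<int, int64_t> volume, surface;
  std::map<std::pair<int,int>, int64_t> touch;
  for (int x = 0; x < X; ++x)
    for (int y = 0; y < Y; ++y)
      for (int z = 0; z < Z; ++z) {
        int u = lab[vidx(z, y, x, Z, Y)];
        if (u == 0) continue;
        volume[u] += 1;
        for (int k = 0; k < 6; ++k) {
          int zz = z + DZ[k], yy = y + DY[k], xx = x + DX[k];
          int v = 0;
          if (zz >= 0 && zz < Z && yy >= 0 && yy < Y && xx >= 0 && xx < X)
            v = lab[vidx(zz, yy, xx, Z, Y)];
          if (v != u) {
            surface[u] += 1;
            if (v != 0 && v > u)  // count each unordered pair once
              touch[std::make_pair(u, v)] += 1;
          }
        }
      }
  int nn = (int)volume.size();
  IntegerVector id(nn); NumericVector vol(nn), surf(nn);
  int i = 0;
  for (auto &kv : volume) {
    id[i] = kv.first; vol[i] = (double)kv.second;
    surf[i] = (double)surface[kv.first]; ++i;
  }
  int ne = (int)touch.size();
  IntegerVector eu(ne), ev(ne); NumericVector ea(ne);
  i = 0;
  for (auto &kv : touch) {
    eu[i] = kv.first.first; ev[i] = kv.first.second; ea[i] = (double)kv.second; ++i;
  }
  return List::create(_["id"] = id, _["volume"] = vol, _["surface"] = surf,
                      _["edge_u"] = eu, _["edge_v"] = ev, _["edge_area"] = ea);
}

// Seeded watershed by priority flood: voxels with higher relief are claimed
// first, growing out from the seed labels; FIFO order breaks exact ties so the
// result is deterministic.
// [[Rcpp::export]]
IntegerVector cpp_seeded_watershed(NumericVector relief, IntegerVector seeds,
                                   IntegerVector mask, IntegerVector dims) {
  int Z = dims[0], Y = dims[1], X = dims[2];
  R_xlen_t n = (R_xlen_t)Z * Y * X;
  IntegerVector lab(n, 0);
  struct Node { double pri; uint64_t ord; R_xlen_t idx; int label; };
  struct Cmp {
    bool operator()(const Node &a, const Node &b) const {
      if (a.pri != b.pri) return a.pri < b.pri;   // max-heap on relief
      return a.ord > b.ord;                        // FIFO on ties
    }
  };
  std::priority_queue<Node, std::vector<Node>, Cmp> pq;
  uint64_t ord = 0;
  for (R_xlen_t s = 0; s < n; ++s)
    if (seeds[s] != 0 && mask[s] != 0)
      pq.push(Node{relief[s], ord++, s, seeds[s]});
  while (!pq.empty()) {
    Node cur = pq.top(); pq.pop();
    if (lab[cur.idx] != 0) continue;
    lab[cur.idx] = cur.label;
    int x = (int)(cur.idx / ((R_xlen_t)Z * Y));
    int rem = (int)(cur.idx % ((R_xlen_t)Z * Y));
    int y = rem / Z, z = rem % Z;
    for (int k = 0; k < 6; ++k) {
      int zz = z + DZ[k], yy = y + DY[k], xx = x + DX[k];
      if (zz < 0 || zz >= Z || yy < 0 || yy >= Y || xx < 0 || xx >= X) continue;
      R_xlen_t q = vidx(zz, yy, xx, Z, Y);
      if (mask[q] != 0 && lab[q] == 0)
        pq.push(Node{relief[q], ord++, q, cur.label});
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

// For every query voxel, the label of the nearest labeled voxel by exact
// Euclidean distance; ties resolved to the smallest label id. Expanding-cube
// search: correct because any site closer than the current best must lie in
// the cube of half-width ceil(sqrt(best_d2)).
// [[Rcpp::export]]
IntegerVector cpp_nearest_label_assign(IntegerVector lab, IntegerVector query,
                                       IntegerVector dims) {
  int Z = dims[0], Y = dims[1], X = dims[2];
  R_xlen_t n = (R_xlen_t)Z * Y * X;
  IntegerVector out = clone(lab);
  int rmax = std::max(std::max(Z, Y), X);
  for (R_xlen_t s = 0; s < n; ++s) {
    if (query[s] == 0) continue;
    int x = (int)(s / ((R_xlen_t)Z * Y));
    int rem = (int)(s % ((R_xlen_t)Z * Y));
    int y = rem / Z, z = rem % Z;
    int64_t best = -1; int bestLab = 0;
    for (int r = 1; r <= rmax; ++r) {
      // scan the full cube of half-width r; skip interior already scanned
      int z0 = std::max(z - r, 0), z1 = std::min(z + r, Z - 1);
      int y0 = std::max(y - r, 0), y1 = std::min(y + r, Y - 1);
      int x0 = std::max(x - r, 0), x1 = std::min(x + r, X - 1);
      for (int xx = x0; xx <= x1; ++xx)
        for (int yy = y0; yy <= y1; ++yy)
          for (int zz = z0; zz <= z1; ++zz) {
            int cheb = std::max(std::abs(xx - x),
                       std::max(std::abs(yy - y), std::abs(zz - z)));
            if (cheb != r) continue;  // shell only
            int l = lab[vidx(zz, yy, xx, Z, Y)];
            if (l == 0) continue;
            int64_t d2 = (int64_t)(zz - z) * (zz - z) +
                         (int64_t)(yy - y) * (yy - y) +
                         (int64_t)(xx - x) * (xx - x);
            if (best < 0 || d2 < best || (d2 == best && l < bestLab)) {
              best = d2; bestLab = l;
            }
          }
      if (best >= 0 && (int64_t)r * r >= best) break;
      if (z0 == 0 && y0 == 0 && x0 == 0 && z1 == Z - 1 && y1 == Y - 1 &&
          x1 == X - 1 && best >= 0) break;
    }
    out[s] = bestLab;
  }
  out.attr("dim") = dims;
  return out;
}

// Local maxima of the relief inside the mask within a Chebyshev window of
// radius sep; plateau voxels all qualify and are fused into one seed per
// 6-connected plateau by the caller.
// [[Rcpp::export]]
IntegerVector cpp_window_maxima(NumericVector relief, IntegerVector mask,
                                IntegerVector dims, int sep) {
  int Z = dims[0], Y = dims[1], X = dims[2];
  R_xlen_t n = (R_xlen_t)Z * Y * X;
  IntegerVector out(n, 0);
  for (int x = 0; x < X; ++x)
    for (int y = 0; y < Y; ++y)
      for (int z = 0; z < Z; ++z) {
        R_xlen_t s = vidx(z, y, x, Z, Y);
        if (mask[s] == 0) continue;
        double v = relief[s];
        bool ismax = true;
        int z0 = std::max(z - sep, 0), z1 = std::min(z + sep, Z - 1);
        int y0 = std::max(y - sep, 0), y1 = std::min(y + sep, Y - 1);
        int x0 = std::max(x - sep, 0), x1 = std::min(x + sep, X - 1);
        for (int xx = x0; xx <= x1 && ismax; ++xx)
          for (int yy = y0; yy <= y1 && ismax; ++yy)
            for (int zz = z0; zz <= z1; ++zz) {
              if (relief[vidx(zz, yy, xx, Z, Y)] > v) { ismax = false; break; }
            }
        if (ismax) out[s] = 1;
      }
  out.attr("dim") = dims;
  return out;
}

// Exact 3D Euclidean distance transform (squared-distance lower envelope,
// separable 1D passes). Returns, for every voxel with mask != 0, the
// Euclidean distance to the nearest mask == 0 voxel; 0 on mask == 0 voxels.
// If the mask has no zero voxel, all distances are Inf.

static void dt1d(const std::vector<double> &f, std::vector<double> &d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -INFINITY; z[1] = INFINITY;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INFINITY;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt3(IntegerVector mask, IntegerVector dims) {
  int Z = dims[0], Y = dims[1], X = dims[2];
  R_xlen_t n = (R_xlen_t)Z * Y * X;
  const double BIG = 1e20;  // finite sentinel: keeps the envelope arithmetic NaN-free
  NumericVector D(n);
  for (R_xlen_t i = 0; i < n; ++i)
    D[i] = (mask[i] != 0) ? BIG : 0.0;
  int mx = std::max(std::max(Z, Y), X);
  std::vector<double> f(mx), d(mx);
  // pass along z
  for (int x = 0; x < X; ++x)
    for (int y = 0; y < Y; ++y) {
      R_xlen_t base = (R_xlen_t)Z * (y + (R_xlen_t)Y * x);
      for (int z = 0; z < Z; ++z) { f[z] = D[base + z]; }
      dt1d(f, d, Z);
      for (int z = 0; z < Z; ++z) D[base + z] = d[z];
    }
  // pass along y
  for (int x = 0; x < X; ++x)
    for (int z = 0; z < Z; ++z) {
      R_xlen_t base = (R_xlen_t)z + (R_xlen_t)Z * Y * (R_xlen_t)x;
      for (int y = 0; y < Y; ++y) { f[y] = D[base + (R_xlen_t)Z * y]; }
      dt1d(f, d, Y);
      for (int y = 0; y < Y; ++y) D[base + (R_xlen_t)Z * y] = d[y];
    }
  // pass along x
  for (int y = 0; y < Y; ++y)
    for (int z = 0; z < Z; ++z) {
      R_xlen_t base = (R_xlen_t)z + (R_xlen_t)Z * y;
      for (int x = 0; x < X; ++x) { f[x] = D[base + (R_xlen_t)Z * Y * x]; }
      dt1d(f, d, X);
      for (int x = 0; x < X; ++x) D[base + (R_xlen_t)Z * Y * x] = d[x];
    }
  for (R_xlen_t i = 0; i < n; ++i)
    D[i] = (D[i] >= 1e19) ? R_PosInf : std::sqrt(D[i]);
  D.attr("dim") = dims;
  return D;
}

// Chebyshev (box) dilation of a binary mask by radius r.
// [[Rcpp::export]]
IntegerVector cpp_box_dilate(IntegerVector mask, IntegerVector dims, int r) {
  int Z = dims[0], Y = dims[1], X = dims[2];
  R_xlen_t n = (R_xlen_t)Z * Y * X;
  IntegerVector out(n, 0);
  for (int x = 0; x < X; ++x)
    for (int y = 0; y < Y; ++y)
      for (int z = 0; z < Z; ++z) {
        if (mask[vidx(z, y, x, Z, Y)] == 0) continue;
        int z0 = std::max(z - r, 0), z1 = std::min(z + r, Z - 1);
        int y0 = std::max(y - r, 0), y1 = std::min(y + r, Y - 1);
        int x0 = std::max(x - r, 0), x1 = std::min(x + r, X - 1);
        for (int xx = x0; xx <= x1; ++xx)
          for (int yy = y0; yy <= y1; ++yy)
            for (int zz = z0; zz <= z1; ++zz)
              out[vidx(zz, yy, xx, Z, Y)] = 1;
      }
  out.attr("dim") = dims;
  return out;
}

// Per-pair saddle heights (max over shared faces of min(relief of the two
// voxels)) and per-label peak relief, for prominence-based basin merging.
// [[Rcpp::export]]
List cpp_basin_saddles(IntegerVector lab, NumericVector relief,
                       IntegerVector dims) {
  int Z = dims[0], Y = dims[1], X = dims[2];
  std::map<int, double> peak;
  std::map<std::pair<int,int>, double> saddle;
  for (int x = 0; x < X; ++x)
    for (int y = 0; y < Y; ++y)
      for (int z = 0; z < Z; ++z) {
        R_xlen_t s = vidx(z, y, x, Z, Y);
        int u = lab[s];
        if (u == 0) continue;
        double ru = relief[s];
        auto it = peak.find(u);
        if (it == peak.end() || ru > it->second) peak[u] = ru;
        for (int k = 0; k < 6; ++k) {
          int zz = z + DZ[k], yy = y + DY[k], xx = x + DX[k];
          if (zz < 0 || zz >= Z || yy < 0 || yy >= Y || xx < 0 || xx >= X)
            continue;
          int v = lab[vidx(zz, yy, xx, Z, Y)];
          if (v == 0 || v <= u) continue;
          double sd = std::min(ru, relief[vidx(zz, yy, xx, Z, Y)]);
          auto key = std::make_pair(u, v);
          auto jt = saddle.find(key);
          if (jt == saddle.end() || sd > jt->second) saddle[key] = sd;
        }
      }
  int nn = (int)peak.size(), ne = (int)saddle.size();
  IntegerVector id(nn); NumericVector pk(nn);
  int i = 0;
  for (auto &kv : peak) { id[i] = kv.first; pk[i] = kv.second; ++i; }
  IntegerVector eu(ne), ev(ne); NumericVector es(ne);
  i = 0;
  for (auto &kv : saddle) {
    eu[i] = kv.first.first; ev[i] = kv.first.second; es[i] = kv.second; ++i;
  }
  return List::create(_["id"] = id, _["peak"] = pk, _["edge_u"] = eu,
                      _["edge_v"] = ev, _["saddle"] = es);
}
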