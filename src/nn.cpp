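#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <queue>

using namespace Rcpp;

// Simple static 3-d kd-tree over reference points, used for nearest-surface
// distance queries. Points are stored once; nodes hold index ranges split at
// the median along the widest-spread axis.

namespace {

struct KDTree {
  const double *pts;            // 3 x n column-major? we store n x 3 row-major copy
  std::vector<double> coord;    // n*3, point i at coord[3*i + axis]
  std::vector<int> idx;
  int n;

  struct Node {
    int lo, hi;        // index range [lo, hi)
    int axis;
    double split;
    int left, right;   // child node ids, -1 if leaf
  };
  std::vector<Node> nodes;
  static const int LEAF = 16;

  void build(const NumericMatrix &m) {
    n = m.nrow();
    coord.resize(static_cast<size_t>(n) * 3);
    idx.resize(n);
    for (int i = 0; i < n; ++i) {
      idx[i] = i;
      for (int a = 0; a < 3; ++a) coord[3 * i + a] = m(i, a);
    }
    nodes.clear();
    nodes.reserve(2 * n / LEAF + 8);
    buildNode(0, n);
  }

  int buildNode(int lo, int hi) {
    int id = (int)nodes.size();
    nodes.push_back(Node{lo, hi, -1, 0.0, -1, -1});
    if (hi - lo <= LEAF) return id;
    // widest-spread axis
    double mn[3] = {R_PosInf, R_PosInf, R_PosInf};
    double mx[3] = {R_NegInf, R_NegInf, R_NegInf};
    for (int i = lo; i < hi; ++i)
      for (int a = 0; a < 3; ++a) {
        double v = coord[3 * idx[i] + a];
        if (v < mn[a]) mn[a] = v;
        if (v > mx[a]) mx[a] = v;
      }
    int axis = 0;
    double spread = mx[0] - mn[0];
    for (int a = 1; a < 3; ++a)
      if (mx[a] - mn[a] > spread) { spread = mx[a] - mn[a]; axis = a; }
    if (spread <= 0) return id;  // all points coincide: leave as leaf
    int mid = (lo + hi) / 2;
    std::nth_element(idx.begin() + lo, idx.begin() + mid, idx.begin() + hi,
                     [&](int a, int b) {
                       return coord[3 * a + axis] < coord[3 * b + axis];
                     });
    double split = coord[3 * idx[mid] + axis];
    nodes[id].axis = axis;
    nodes[id].split = split;
    int left = buildNode(lo, mid);
    int right = buildNode(mid, hi);
    nodes[id].left = left;
    nodes[id].right = right;
    return id;
  }

  void query(const double q[3], int node, double &best) const {
    const Node &nd = nodes[node];
    if (nd.left < 0) {
      for (int i = nd.lo; i < nd.hi; ++i) {
        const double *p = &coord[3 * idx[i]];
        double dx = p[0] - q[0], dy = p[1] - q[1], dz = p[2] - q[2];
        double d2 = dx * dx + dy * dy + dz * dz;
        if (d2 < best) best = d2;
      }
      return;
    }
    double diff = q[nd.axis] - nd.split;
    int nearChild = diff < 0 ? nd.left : nd.right;
    int farChild = diff < 0 ? nd.right : nd.left;
    query(q, nearChild, best);
    if (diff * diff < best) query(q, farChild, best);
  }

  double nearest(const double q[3]) const {
    double best = R_PosInf;
    query(q, 0, best);
    return std::sqrt(best);
  }
};

}  // namespace

// [[Rcpp::export]]
NumericVector cpp_nn_dist(NumericMatrix query, NumericMatrix ref) {
  if (ref.nrow() == 0) stop("reference point set is empty");
  if (query.ncol() != 3 || ref.ncol() != 3)
    stop("point matrices must have 3 columns");
  KDTree tree;
  tree.build(ref);
  int nq = query.nrow();
  NumericVector out(nq);
  for (int i = 0; i < nq; ++i) {
    double q[3] = {query(i, 0), query(i, 1), query(i, 2)};
    out[i] = tree.nearest(q);
  }
  return out;
}

// 6-connected component labelling of a 3-d logical array (flood fill).
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector occ, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (occ.size() != n) stop("occupancy length does not match dims");
  IntegerVector lab(n, 0);
  int cur = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!occ[s] || lab[s] != 0) continue;
    ++cur;
    stack.clear();
    stack.push_back(s);
    lab[s] = cur;
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      int x = (int)(v % nx);
      int y = (int)((v / nx) % ny);
      int z = (int)(v / ((R_xlen_t)nx * ny));
      const int dx[6] = {-1, 1, 0, 0, 0, 0};
      const int dy[6] = {0, 0, -1, 1, 0, 0};
      const int dz[6] = {0, 0, 0, 0, -1, 1};
      for (int k = 0; k < 6; ++k) {
        int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        R_xlen_t w = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
        if (occ[w] && lab[w] == 0) {
          lab[w] = cur;
          stack.push_back(w);
        }
      }
    }
  }
  lab.attr("dim") = dims;
  lab.attr("n_components") = cur;
  return lab;
}
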