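// Herraez-style 2D phase unwrapping by reliability sorting.
//
// Pixels are scored by the inverse root-sum-square of wrapped second
// differences over the horizontal, vertical and two diagonal neighbour
// triples.  Edges of the 4-connected pixel graph are sorted by the sum of
// their endpoint reliabilities (descending, stable; ties fall back to the
// row-major edge index) and merged with a union-find structure, shifting
// the smaller group by the integer multiple of 2*pi that brings the two
// endpoints within pi of each other.  The result is congruent to the
// input modulo 2*pi at every pixel and fully deterministic.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <functional>
#include <vector>

using namespace Rcpp;

static const double TWO_PI = 6.283185307179586476925286766559;

// wrap into (-pi, pi]
static inline double wrap_pi(double x) {
  double w = x - TWO_PI * std::ceil((x - M_PI) / TWO_PI);
  // guard against rounding placing us just outside the interval
  if (w <= -M_PI) w += TWO_PI;
  if (w > M_PI) w -= TWO_PI;
  return w;
}

// Reliability ceiling used where the second differences vanish exactly.
static const double R_MAX = 1e12;

static std::vector<double> reliability_impl(const NumericMatrix& phi) {
  const int nr = phi.nrow(), nc = phi.ncol();
  std::vector<double> rel(static_cast<size_t>(nr) * nc, 0.0);
  for (int j = 1; j < nc - 1; ++j) {
    for (int i = 1; i < nr - 1; ++i) {
      const double c = phi(i, j);
      const double H  = wrap_pi(phi(i, j - 1) - c) - wrap_pi(c - phi(i, j + 1));
      const double V  = wrap_pi(phi(i - 1, j) - c) - wrap_pi(c - phi(i + 1, j));
      const double D1 = wrap_pi(phi(i - 1, j - 1) - c) - wrap_pi(c - phi(i + 1, j + 1));
      const double D2 = wrap_pi(phi(i - 1, j + 1) - c) - wrap_pi(c - phi(i + 1, j - 1));
      const double D = std::sqrt(H * H + V * V + D1 * D1 + D2 * D2);
      rel[static_cast<size_t>(j) * nr + i] = (D < 1e-12) ? R_MAX : 1.0 / D;
    }
  }
  return rel;  // border rows/cols stay at 0 = lowest reliability
}

// [[Rcpp::export(name = ".herraez_reliability")]]
NumericMatrix herraez_reliability(NumericMatrix phi) {
  if (phi.nrow() < 3 || phi.ncol() < 3)
    stop("image must be at least 3x3 for reliability scoring");
  std::vector<double> rel = reliability_impl(phi);
  NumericMatrix out(phi.nrow(), phi.ncol());
  std::copy(rel.begin(), rel.end(), out.begin());
  return out;
}

struct Edge {
  double rel;
  int idx;  // row-major enumeration index; horizontal edges first
  int a, b; // flat (column-major) pixel indices
};

// [[Rcpp::export(name = ".herraez_unwrap")]]
NumericMatrix herraez_unwrap(NumericMatrix phi) {
  const int nr = phi.nrow(), nc = phi.ncol();
  if (nr < 3 || nc < 3)
    stop("image must be at least 3x3 for reliability-sorted unwrapping");
  const size_t n = static_cast<size_t>(nr) * nc;

  std::vector<double> rel = reliability_impl(phi);
  std::vector<double> val(n);
  for (size_t p = 0; p < n; ++p) val[p] = phi[p];

  // 4-connected edges: horizontal (i,j)-(i,j+1) in row-major order, then
  // vertical (i,j)-(i+1,j) in row-major order.
  std::vector<Edge> edges;
  edges.reserve(static_cast<size_t>(nr) * (nc - 1) + static_cast<size_t>(nr - 1) * nc);
  int idx = 0;
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc - 1; ++j) {
      int a = j * nr + i, b = (j + 1) * nr + i;
      edges.push_back({rel[a] + rel[b], idx++, a, b});
    }
  for (int i = 0; i < nr - 1; ++i)
    for (int j = 0; j < nc; ++j) {
      int a = j * nr + i, b = j * nr + i + 1;
      edges.push_back({rel[a] + rel[b], idx++, a, b});
    }
  std::stable_sort(edges.begin(), edges.end(), [](const Edge& x, const Edge& y) {
    if (x.rel != y.rel) return x.rel > y.rel;
    return x.idx < y.idx;
  });

  // union-find with membership lists so a whole group can be re-levelled
  std::vector<int> parent(n), sz(n, 1), head(n), next_(n, -1), tail(n);
  for (size_t p = 0; p < n; ++p) { parent[p] = static_cast<int>(p); head[p] = tail[p] = static_cast<int>(p); }
  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };

  for (const Edge& e : edges) {
    int ra = find(e.a), rb = find(e.b);
    if (ra == rb) continue;
    // shift the smaller group; k multiples of 2*pi bring b's side onto a's
    double k = std::round((val[e.a] - val[e.b]) / TWO_PI);
    int rsmall, rbig;
    double shift;
    if (sz[ra] >= sz[rb]) { rbig = ra; rsmall = rb; shift = k * TWO_PI; }
    else                  { rbig = rb; rsmall = ra; shift = -k * TWO_PI; }
    if (shift != 0.0)
      for (int p = head[rsmall]; p != -1; p = next_[p]) val[p] += shift;
    parent[rsmall] = rbig;
    sz[rbig] += sz[rsmall];
    next_[tail[rbig]] = head[rsmall];
    tail[rbig] = tail[rsmall];
  }

  NumericMatrix out(nr, nc);
  for (size_t p = 0; p < n; ++p) out[p] = val[p];
  return out;
}
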