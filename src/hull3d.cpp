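#include <Rcpp.h>
#include <cmath>
#include <map>
#include <utility>
#include "hull3d.h"

using std::array;
using std::vector;

typedef array<double, 3> vec3;

static inline vec3 vsub(const vec3& a, const vec3& b) {
  return {{a[0] - b[0], a[1] - b[1], a[2] - b[2]}};
}
static inline vec3 vcross(const vec3& a, const vec3& b) {
  return {{a[1] * b[2] - a[2] * b[1],
           a[2] * b[0] - a[0] * b[2],
           a[0] * b[1] - a[1] * b[0]}};
}
static inline double vdot(const vec3& a, const vec3& b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
static inline double vnorm(const vec3& a) { return std::sqrt(vdot(a, a)); }

struct Facet {
  int a, b, c;
  vec3 n;      // outward, un-normalised
  bool alive;
};

static inline vec3 facet_normal(const vector<vec3>& P, int a, int b, int c) {
  return vcross(vsub(P[b], P[a]), vsub(P[c], P[a]));
}

vector<array<int, 3>> hull3d(const vector<vec3>& P) {
  const int n = (int)P.size();
  if (n < 4) Rcpp::stop("convex hull needs at least 4 points");

  double L = 0.0;
  for (int i = 1; i < n; ++i) L = std::max(L, vnorm(vsub(P[i], P[0])));
  if (L <= 0.0) Rcpp::stop("degenerate point cloud: all points coincide");
  const double eps = 1e-10 * L * L * L;   // visibility tolerance on a triple product

  // initial simplex: two extreme points, then max-area, then max-volume
  int i0 = 0, i1 = -1, i2 = -1, i3 = -1;
  double best = -1.0;
  for (int i = 1; i < n; ++i) {
    double d = vnorm(vsub(P[i], P[i0]));
    if (d > best) { best = d; i1 = i; }
  }
  best = -1.0;
  for (int i = 0; i < n; ++i) {
    if (i == i0 || i == i1) continue;
    double ar = vnorm(vcross(vsub(P[i1], P[i0]), vsub(P[i], P[i0])));
    if (ar > best) { best = ar; i2 = i; }
  }
  if (i2 < 0 || best <= 1e-12 * L * L) Rcpp::stop("degenerate point cloud: collinear");
  vec3 n012 = facet_normal(P, i0, i1, i2);
  best = -1.0;
  for (int i = 0; i < n; ++i) {
    if (i == i0 || i == i1 || i == i2) continue;
    double vol = std::fabs(vdot(n012, vsub(P[i], P[i0])));
    if (vol > best) { best = vol; i3 = i; }
  }
  if (i3 < 0 || best <= eps) Rcpp::stop("degenerate point cloud: coplanar");

  vec3 centroid = {{0, 0, 0}};
  for (int k : {i0, i1, i2, i3})
    for (int d = 0; d < 3; ++d) centroid[d] += P[k][d] / 4.0;

  vector<Facet> F;
  auto add_facet = [&](int a, int b, int c) {
    vec3 nn = facet_normal(P, a, b, c);
    if (vdot(nn, vsub(centroid, P[a])) > 0) {  // make outward
      std::swap(b, c);
      nn = facet_normal(P, a, b, c);
    }
    F.push_back({a, b, c, nn, true});
  };
  add_facet(i0, i1, i2);
  add_facet(i0, i1, i3);
  add_facet(i0, i2, i3);
  add_facet(i1, i2, i3);

  for (int p = 0; p < n; ++p) {
    if (p == i0 || p == i1 || p == i2 || p == i3) continue;
    // facets visible from p
    vector<int> vis;
    for (int f = 0; f < (int)F.size(); ++f) {
      if (!F[f].alive) continue;
      if (vdot(F[f].n, vsub(P[p], P[F[f].a])) > eps) vis.push_back(f);
    }
    if (vis.empty()) continue;
    // horizon: directed edges of visible facets whose reverse is not visible
    std::map<std::pair<int, int>, int> dir_edges;
    for (int f : vis) {
      const Facet& fa = F[f];
      dir_edges[{fa.a, fa.b}] = 1;
      dir_edges[{fa.b, fa.c}] = 1;
      dir_edges[{fa.c, fa.a}] = 1;
    }
    vector<std::pair<int, int>> horizon;
    for (auto& e : dir_edges)
      if (dir_edges.find({e.first.second, e.first.first}) == dir_edges.end())
        horizon.push_back(e.first);
    for (int f : vis) F[f].alive = false;
    // new facets keep the horizon's winding, so normals stay outward
    for (auto& e : horizon) {
      vec3 nn = facet_normal(P, e.first, e.second, p);
      F.push_back({e.first, e.second, p, nn, true});
    }
  }

  vector<array<int, 3>> out;
  for (const Facet& f : F)
    if (f.alive) out.push_back({{f.a, f.b, f.c}});
  return out;
}

//' @noRd
// [[Rcpp::export]]
Rcpp::IntegerMatrix cpp_convex_hull(Rcpp::NumericMatrix pts) {
  const int n = pts.nrow();
  vector<vec3> P(n);
  for (int i = 0; i < n; ++i) P[i] = {{pts(i, 0), pts(i, 1), pts(i, 2)}};
  vector<array<int, 3>> H = hull3d(P);
  Rcpp::IntegerMatrix out((int)H.size(), 3);
  for (int f = 0; f < (int)H.size(); ++f)
    for (int k = 0; k < 3; ++k) out(f, k) = H[f][k] + 1;  // 1-based for R
  return out;
}
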