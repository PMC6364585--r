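// Force computation and overdamped Langevin stepping for the subcellular
// element model: intra-cell Morse interactions, inter-cell repulsion and
// density-normalised cortex adhesion, and a constant-magnitude cortical
// tension network over the spherical-Delaunay triangulation of each cell's
// cortex elements.
#include <Rcpp.h>
#include <cmath>
#include <set>
#include <unordered_map>
#include <vector>
#include <array>
#include "hull3d.h"

using namespace Rcpp;
using std::vector;
using std::array;

struct Pars {
  double re, cutoff_core, cutoff_adh, label_cutoff, measure_cutoff, cutoff_max;
  double De_core, a_core;   // intra-cell Morse (all element pairs of one cell)
  double De_rep, a_rep;     // inter-cell repulsive-only core
  double a_adh;             // range parameter of the adhesive Morse branch
  double rep_cap;           // ceiling on the inter-cell repulsive force
  double AM[3][3];          // adhesion magnitude by cell-type pair (1-based)
  double gamma_m;
  double beta[3][3];        // interfacial tension factors (1-based, symmetric)
  double noise_amp, dt, gamma_drag;
  double radius_fraction;
  int realloc_stride;
  int edge_label_rule;  // 0: both endpoints share a label; 1: either endpoint
};

static Pars parse_pars(const List& p) {
  Pars q;
  q.re = as<double>(p["re"]);
  q.cutoff_core = as<double>(p["cutoff_core"]);
  q.cutoff_adh = as<double>(p["cutoff_adh"]);
  q.label_cutoff = as<double>(p["label_cutoff"]);
  q.measure_cutoff = as<double>(p["measure_cutoff"]);
  q.cutoff_max = std::max(q.cutoff_core, q.cutoff_adh);
  q.De_core = as<double>(p["De_core"]);
  q.a_core = as<double>(p["a_core"]);
  q.De_rep = as<double>(p["De_rep"]);
  q.a_rep = as<double>(p["a_rep"]);
  q.a_adh = as<double>(p["a_adh"]);
  q.rep_cap = as<double>(p["rep_cap"]);
  NumericMatrix AM = p["A_M"];
  NumericMatrix be = p["beta"];
  for (int i = 0; i < 2; ++i)
    for (int j = 0; j < 2; ++j) {
      q.AM[i + 1][j + 1] = AM(i, j);
      q.beta[i + 1][j + 1] = be(i, j);
    }
  q.gamma_m = as<double>(p["gamma_m"]);
  q.noise_amp = as<double>(p["noise_amp"]);
  q.dt = as<double>(p["dt"]);
  q.gamma_drag = as<double>(p["gamma_drag"]);
  q.radius_fraction = as<double>(p["radius_fraction"]);
  q.realloc_stride = as<int>(p["realloc_stride"]);
  q.edge_label_rule = p.containsElementNamed("edge_label_rule") ? as<int>(p["edge_label_rule"]) : 0;
  return q;
}

// signed Morse force magnitude, positive = repulsive: -dV/dr
static inline double fmorse(double r, double De, double a, double re) {
  double e1 = std::exp(-a * (r - re));
  return 2.0 * a * De * (e1 * e1 - e1);
}

// ---------- neighbour search: uniform grid cell list -----------------------

static void grid_pairs(const vector<array<double, 3>>& X, double cutoff,
                       vector<std::pair<int, int>>& out) {
  out.clear();
  const int n = (int)X.size();
  const double inv = 1.0 / cutoff;
  std::unordered_map<long long, vector<int>> grid;
  grid.reserve(n * 2);
  auto key = [&](int ix, int iy, int iz) -> long long {
    return ((long long)(ix + 1048576) << 42) |
           ((long long)(iy + 1048576) << 21) |
           (long long)(iz + 1048576);
  };
  vector<array<int, 3>> cell(n);
  for (int i = 0; i < n; ++i) {
    int ix = (int)std::floor(X[i][0] * inv);
    int iy = (int)std::floor(X[i][1] * inv);
    int iz = (int)std::floor(X[i][2] * inv);
    cell[i] = {{ix, iy, iz}};
    grid[key(ix, iy, iz)].push_back(i);
  }
  const double c2 = cutoff * cutoff;
  for (int i = 0; i < n; ++i) {
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          auto it = grid.find(key(cell[i][0] + dx, cell[i][1] + dy, cell[i][2] + dz));
          if (it == grid.end()) continue;
          for (int j : it->second) {
            if (j <= i) continue;
            double ddx = X[i][0] - X[j][0];
            double ddy = X[i][1] - X[j][1];
            double ddz = X[i][2] - X[j][2];
            if (ddx * ddx + ddy * ddy + ddz * ddz <= c2) out.push_back({i, j});
          }
        }
  }
}

//' @noRd
// [[Rcpp::export]]
IntegerMatrix cpp_neighbour_pairs(NumericMatrix pos, double cutoff) {
  const int n = pos.nrow();
  vector<array<double, 3>> X(n);
  for (int i = 0; i < n; ++i) X[i] = {{pos(i, 0), pos(i, 1), pos(i, 2)}};
  vector<std::pair<int, int>> pr;
  grid_pairs(X, cutoff, pr);
  IntegerMatrix out((int)pr.size(), 2);
  for (int k = 0; k < (int)pr.size(); ++k) {
    out(k, 0) = pr[k].first + 1;
    out(k, 1) = pr[k].second + 1;
  }
  return out;
}

// ---------- cortex allocation: 32 equal-solid-angle sectors ----------------
// 4 equal-width z bands (equal area by Archimedes) x 8 azimuthal slices.

static inline int sector_of(double dx, double dy, double dz, double r) {
  if (r <= 0) return 0;
  double cz = dz / r;
  int band = (int)std::floor((cz + 1.0) * 2.0);  // 0..3
  if (band > 3) band = 3;
  if (band < 0) band = 0;
  double phi = std::atan2(dy, dx) + M_PI;        // 0..2pi
  int slice = (int)std::floor(phi * 8.0 / (2.0 * M_PI));
  if (slice > 7) slice = 7;
  if (slice < 0) slice = 0;
  return band * 8 + slice;
}

static void allocate_cortex_cell(const vector<array<double, 3>>& X,
                                 const vector<int>& members,
                                 const array<double, 3>& com,
                                 double frac, vector<int>& etype) {
  double rmax[32];
  for (int s = 0; s < 32; ++s) rmax[s] = -1.0;
  vector<double> rad(members.size());
  vector<int> sec(members.size());
  for (size_t k = 0; k < members.size(); ++k) {
    int i = members[k];
    double dx = X[i][0] - com[0], dy = X[i][1] - com[1], dz = X[i][2] - com[2];
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    rad[k] = r;
    sec[k] = sector_of(dx, dy, dz, r);
    if (r > rmax[sec[k]]) rmax[sec[k]] = r;
  }
  for (size_t k = 0; k < members.size(); ++k) {
    int i = members[k];
    // sector maximum is always cortex, including the degenerate r = 0 case
    etype[i] = (rad[k] >= rmax[sec[k]] || rad[k] > frac * rmax[sec[k]]) ? 1 : 0;
  }
}

//' @noRd
// [[Rcpp::export]]
IntegerVector cpp_allocate_cortex(NumericMatrix pos, NumericVector com, double frac) {
  const int n = pos.nrow();
  vector<array<double, 3>> X(n);
  vector<int> members(n), etype(n, 0);
  for (int i = 0; i < n; ++i) {
    X[i] = {{pos(i, 0), pos(i, 1), pos(i, 2)}};
    members[i] = i;
  }
  array<double, 3> c = {{com[0], com[1], com[2]}};
  allocate_cortex_cell(X, members, c, frac, etype);
  return wrap(etype);
}

// ---------- full structure update -------------------------------------------

struct Structure {
  vector<int> etype;                 // 0 cytoplasm, 1 cortex
  vector<int> label;                 // bitmask: 1 same-type, 2 other-type
  vector<int> mlabel;                // bound-contact labels for measurement
  vector<array<int, 3>> facets;      // global 0-based element ids
  vector<int> facet_cell;            // 1-based cell id
  vector<double> facet_area;
  vector<array<int, 2>> edges;       // unique cortical edges, global ids
  vector<int> edge_cell;
  vector<double> adh_factor;         // density-normalisation factor, 1 for cytoplasm
  vector<std::pair<int, int>> pairs; // neighbour pairs within cutoff
  vector<double> cell_area, cell_iface_area;  // indexed by cell id (1-based)
  vector<array<double, 3>> com;               // indexed by cell id (1-based)
};

static void compute_structure(const vector<array<double, 3>>& X,
                              const vector<int>& cell_id,     // 1-based
                              const vector<int>& cell_type,   // by cell id
                              const Pars& q, Structure& S,
                              bool redo_cortex) {
  const int n = (int)X.size();
  int C = 0;
  for (int i = 0; i < n; ++i) C = std::max(C, cell_id[i]);

  vector<vector<int>> members(C + 1);
  for (int i = 0; i < n; ++i) members[cell_id[i]].push_back(i);

  S.com.assign(C + 1, {{0, 0, 0}});
  for (int c = 1; c <= C; ++c) {
    if (members[c].empty()) continue;
    for (int i : members[c])
      for (int d = 0; d < 3; ++d) S.com[c][d] += X[i][d];
    for (int d = 0; d < 3; ++d) S.com[c][d] /= (double)members[c].size();
  }

  if (redo_cortex || (int)S.etype.size() != n) {
    S.etype.assign(n, 0);
    for (int c = 1; c <= C; ++c)
      if (!members[c].empty())
        allocate_cortex_cell(X, members[c], S.com[c], q.radius_fraction, S.etype);

    // surface mesh per cell: convex hull of the cortex element positions,
    // so tension edges are tangential to the cell surface (inner-layer
    // cortex elements carry adhesion and labels but no tension edges)
    S.facets.clear(); S.facet_cell.clear(); S.facet_area.clear();
    S.edges.clear(); S.edge_cell.clear();
    for (int c = 1; c <= C; ++c) {
      vector<int> cx;
      for (int i : members[c]) if (S.etype[i] == 1) cx.push_back(i);
      if ((int)cx.size() < 4) continue;
      vector<array<double, 3>> U(cx.size());
      for (size_t k = 0; k < cx.size(); ++k) {
        // tiny index-keyed jitter breaks exact degeneracies deterministically
        U[k] = {{X[cx[k]][0] + 1e-9 * std::sin(0.7 * (double)(k + 1)),
                 X[cx[k]][1] + 1e-9 * std::cos(1.3 * (double)(k + 1)),
                 X[cx[k]][2] + 1e-9 * std::sin(2.1 * (double)(k + 1))}};
      }
      vector<array<int, 3>> H = hull3d(U);
      std::set<std::pair<int, int>> eseen;
      for (auto& f : H) {
        int a = cx[f[0]], b = cx[f[1]], cc = cx[f[2]];
        S.facets.push_back({{a, b, cc}});
        S.facet_cell.push_back(c);
        int vv[3] = {a, b, cc};
        for (int e = 0; e < 3; ++e) {
          int u = vv[e], v = vv[(e + 1) % 3];
          if (u > v) std::swap(u, v);
          if (eseen.insert({u, v}).second) {
            S.edges.push_back({{u, v}});
            S.edge_cell.push_back(c);
          }
        }
      }
    }
  }

  // neighbour pairs (every call: positions move every step)
  grid_pairs(X, q.cutoff_max, S.pairs);

  // interface labels from adhesive inter-cell cortex-cortex contacts
  S.label.assign(n, 0);
  S.mlabel.assign(n, 0);
  const double ca2 = q.label_cutoff * q.label_cutoff;
  const double cm2 = q.measure_cutoff * q.measure_cutoff;
  for (auto& pr : S.pairs) {
    int i = pr.first, j = pr.second;
    int ci = cell_id[i], cj = cell_id[j];
    if (ci == cj) continue;
    if (S.etype[i] != 1 || S.etype[j] != 1) continue;
    int ti = cell_type[ci], tj = cell_type[cj];
    if (q.AM[ti][tj] <= 0.0) continue;  // no adhesive interaction to share
    double dx = X[i][0] - X[j][0], dy = X[i][1] - X[j][1], dz = X[i][2] - X[j][2];
    double d2 = dx * dx + dy * dy + dz * dz;
    if (d2 > ca2) continue;
    int bit = (ti == tj) ? 1 : 2;
    S.label[i] |= bit;
    S.label[j] |= bit;
    if (d2 <= cm2) { S.mlabel[i] |= bit; S.mlabel[j] |= bit; }
  }

  // facet areas from real positions; per-cell total and interface area
  S.facet_area.assign(S.facets.size(), 0.0);
  S.cell_area.assign(C + 1, 0.0);
  S.cell_iface_area.assign(C + 1, 0.0);
  for (size_t f = 0; f < S.facets.size(); ++f) {
    int a = S.facets[f][0], b = S.facets[f][1], c = S.facets[f][2];
    double ux = X[b][0] - X[a][0], uy = X[b][1] - X[a][1], uz = X[b][2] - X[a][2];
    double vx = X[c][0] - X[a][0], vy = X[c][1] - X[a][1], vz = X[c][2] - X[a][2];
    double cx = uy * vz - uz * vy, cy = uz * vx - ux * vz, cz = ux * vy - uy * vx;
    double ar = 0.5 * std::sqrt(cx * cx + cy * cy + cz * cz);
    S.facet_area[f] = ar;
    S.cell_area[S.facet_cell[f]] += ar;
    if (S.mlabel[a] && S.mlabel[b] && S.mlabel[c])
      S.cell_iface_area[S.facet_cell[f]] += ar;
  }

  // adhesion density normalisation: element surface share / cell mean share
  S.adh_factor.assign(n, 1.0);
  vector<double> share(n, 0.0);
  for (size_t f = 0; f < S.facets.size(); ++f)
    for (int k = 0; k < 3; ++k) share[S.facets[f][k]] += S.facet_area[f] / 3.0;
  for (int c = 1; c <= C; ++c) {
    double tot = 0.0;
    int m = 0;
    for (int i : members[c])
      if (S.etype[i] == 1 && share[i] > 0) { tot += share[i]; ++m; }
    if (m == 0 || tot <= 0) continue;
    double mean = tot / m;
    for (int i : members[c])
      if (S.etype[i] == 1 && share[i] > 0) S.adh_factor[i] = share[i] / mean;
  }
}

// ---------- forces -----------------------------------------------------------

static void compute_forces(const vector<array<double, 3>>& X,
                           const vector<int>& cell_id,
                           const vector<int>& cell_type,
                           const Pars& q, const Structure& S,
                           vector<array<double, 3>>& F,
                           vector<array<double, 3>>* Fmorse,
                           vector<array<double, 3>>* Ftens) {
  const int n = (int)X.size();
  F.assign(n, {{0, 0, 0}});
  if (Fmorse) Fmorse->assign(n, {{0, 0, 0}});
  if (Ftens) Ftens->assign(n, {{0, 0, 0}});

  for (auto& pr : S.pairs) {
    int i = pr.first, j = pr.second;
    double dx = X[i][0] - X[j][0], dy = X[i][1] - X[j][1], dz = X[i][2] - X[j][2];
    double d = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (d < 1e-12) continue;
    double f = 0.0;
    if (cell_id[i] == cell_id[j]) {
      // repulsive branch capped like the inter-cell wall (insertion spikes)
      if (d <= q.cutoff_core)
        f = std::min(fmorse(d, q.De_core, q.a_core, q.re), q.rep_cap);
    } else if (S.etype[i] == 1 && S.etype[j] == 1) {
      if (d <= q.cutoff_core)
        f = std::min(std::max(fmorse(d, q.De_rep, q.a_rep, q.re), 0.0), q.rep_cap);
      double am = q.AM[cell_type[cell_id[i]]][cell_type[cell_id[j]]];
      if (am > 0.0 && d <= q.cutoff_adh) {
        double De_adh = 2.0 * am / q.a_adh;  // peak attraction equals A_M
        double fa = std::min(fmorse(d, De_adh, q.a_adh, q.re), 0.0);
        f += 0.5 * (S.adh_factor[i] + S.adh_factor[j]) * fa;
      }
    } else {
      if (d <= q.cutoff_core)
        f = std::min(std::max(fmorse(d, q.De_rep, q.a_rep, q.re), 0.0), q.rep_cap);
    }
    double ux = dx / d, uy = dy / d, uz = dz / d;
    F[i][0] += f * ux; F[i][1] += f * uy; F[i][2] += f * uz;
    F[j][0] -= f * ux; F[j][1] -= f * uy; F[j][2] -= f * uz;
    if (Fmorse) {
      (*Fmorse)[i][0] += f * ux; (*Fmorse)[i][1] += f * uy; (*Fmorse)[i][2] += f * uz;
      (*Fmorse)[j][0] -= f * ux; (*Fmorse)[j][1] -= f * uy; (*Fmorse)[j][2] -= f * uz;
    }
  }

  // cortical tension: constant attractive force along each triangulation edge
  for (size_t e = 0; e < S.edges.size(); ++e) {
    int i = S.edges[e][0], j = S.edges[e][1];
    double g = q.gamma_m;
    int common = q.edge_label_rule == 1 ? (S.label[i] | S.label[j])
                                        : (S.label[i] & S.label[j]);
    if (common) {
      int t = cell_type[cell_id[i]];
      double b = 2.0;
      if (common & 1) b = std::min(b, q.beta[t][t]);
      if (common & 2) b = std::min(b, q.beta[t][3 - t]);
      g *= b;
    }
    double dx = X[j][0] - X[i][0], dy = X[j][1] - X[i][1], dz = X[j][2] - X[i][2];
    double d = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (d < 1e-12) continue;  // zero-length edge: skip
    double ux = dx / d, uy = dy / d, uz = dz / d;
    F[i][0] += g * ux; F[i][1] += g * uy; F[i][2] += g * uz;
    F[j][0] -= g * ux; F[j][1] -= g * uy; F[j][2] -= g * uz;
    if (Ftens) {
      (*Ftens)[i][0] += g * ux; (*Ftens)[i][1] += g * uy; (*Ftens)[i][2] += g * uz;
      (*Ftens)[j][0] -= g * ux; (*Ftens)[j][1] -= g * uy; (*Ftens)[j][2] -= g * uz;
    }
  }
}

// ---------- R-facing structure/force snapshots -------------------------------

static List structure_to_list(const Structure& S) {
  const int nf = (int)S.facets.size();
  IntegerMatrix fm(nf, 3);
  IntegerVector fc(nf);
  NumericVector fa(nf);
  for (int f = 0; f < nf; ++f) {
    fm(f, 0) = S.facets[f][0] + 1;
    fm(f, 1) = S.facets[f][1] + 1;
    fm(f, 2) = S.facets[f][2] + 1;
    fc[f] = S.facet_cell[f];
    fa[f] = S.facet_area[f];
  }
  const int ne = (int)S.edges.size();
  IntegerMatrix em(ne, 2);
  IntegerVector ec(ne);
  for (int e = 0; e < ne; ++e) {
    em(e, 0) = S.edges[e][0] + 1;
    em(e, 1) = S.edges[e][1] + 1;
    ec[e] = S.edge_cell[e];
  }
  const int np = (int)S.pairs.size();
  IntegerMatrix pm(np, 2);
  for (int p = 0; p < np; ++p) {
    pm(p, 0) = S.pairs[p].first + 1;
    pm(p, 1) = S.pairs[p].second + 1;
  }
  int C = (int)S.cell_area.size() - 1;
  NumericVector ca(C), cia(C);
  NumericMatrix com(C, 3);
  for (int c = 1; c <= C; ++c) {
    ca[c - 1] = S.cell_area[c];
    cia[c - 1] = S.cell_iface_area[c];
    for (int d = 0; d < 3; ++d) com(c - 1, d) = S.com[c][d];
  }
  return List::create(
      _["etype"] = wrap(S.etype), _["label"] = wrap(S.label),
      _["mlabel"] = wrap(S.mlabel),
      _["facets"] = fm, _["facet_cell"] = fc, _["facet_area"] = fa,
      _["edges"] = em, _["edge_cell"] = ec, _["pairs"] = pm,
      _["adh_factor"] = wrap(S.adh_factor),
      _["cell_area"] = ca, _["cell_interface_area"] = cia, _["com"] = com);
}

static void read_inputs(NumericMatrix pos, IntegerVector cell_id,
                        IntegerVector cell_type,
                        vector<array<double, 3>>& X, vector<int>& cid,
                        vector<int>& ctype) {
  const int n = pos.nrow();
  X.resize(n); cid.resize(n);
  for (int i = 0; i < n; ++i) {
    X[i] = {{pos(i, 0), pos(i, 1), pos(i, 2)}};
    cid[i] = cell_id[i];
  }
  ctype.assign(cell_type.size() + 1, 0);
  for (int c = 0; c < cell_type.size(); ++c) ctype[c + 1] = cell_type[c];
}

//' @noRd
// [[Rcpp::export]]
List cpp_structure(NumericMatrix pos, IntegerVector cell_id,
                   IntegerVector cell_type, List pars) {
  Pars q = parse_pars(pars);
  vector<array<double, 3>> X;
  vector<int> cid, ctype;
  read_inputs(pos, cell_id, cell_type, X, cid, ctype);
  Structure S;
  compute_structure(X, cid, ctype, q, S, true);
  return structure_to_list(S);
}

//' @noRd
// [[Rcpp::export]]
List cpp_forces(NumericMatrix pos, IntegerVector cell_id,
                IntegerVector cell_type, List pars) {
  Pars q = parse_pars(pars);
  vector<array<double, 3>> X;
  vector<int> cid, ctype;
  read_inputs(pos, cell_id, cell_type, X, cid, ctype);
  Structure S;
  compute_structure(X, cid, ctype, q, S, true);
  vector<array<double, 3>> F, Fm, Ft;
  compute_forces(X, cid, ctype, q, S, F, &Fm, &Ft);
  const int n = (int)X.size();
  NumericMatrix Fo(n, 3), Fmo(n, 3), Fto(n, 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) {
      Fo(i, d) = F[i][d];
      Fmo(i, d) = Fm[i][d];
      Fto(i, d) = Ft[i][d];
    }
  return List::create(_["total"] = Fo, _["morse"] = Fmo, _["tension"] = Fto,
                      _["structure"] = structure_to_list(S));
}

//' @noRd
// [[Rcpp::export]]
List cpp_simulate(NumericMatrix pos, IntegerVector cell_id,
                  IntegerVector cell_type, List pars, int nsteps,
                  int record_stride, double t0) {
  Pars q = parse_pars(pars);
  vector<array<double, 3>> X;
  vector<int> cid, ctype;
  read_inputs(pos, cell_id, cell_type, X, cid, ctype);
  const int n = (int)X.size();

  Structure S;
  vector<array<double, 3>> F;
  vector<double> rec_t, rec_ip;
  const double guard = 0.5 * q.re;
  double maxdisp_seen = 0.0;

  for (int s = 0; s < nsteps; ++s) {
    bool redo = (s % q.realloc_stride == 0);
    compute_structure(X, cid, ctype, q, S, redo);
    compute_forces(X, cid, ctype, q, S, F, nullptr, nullptr);
    double scale = q.dt / q.gamma_drag;
    for (int i = 0; i < n; ++i) {
      double dx = scale * (F[i][0] + q.noise_amp * norm_rand());
      double dy = scale * (F[i][1] + q.noise_amp * norm_rand());
      double dz = scale * (F[i][2] + q.noise_amp * norm_rand());
      double dn = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (dn > maxdisp_seen) maxdisp_seen = dn;
      if (dn > guard)
        stop("time step too large: element displacement %f exceeds re/2 at step %d; reduce dt",
             dn, s + 1);
      X[i][0] += dx; X[i][1] += dy; X[i][2] += dz;
    }
    if (record_stride > 0 && ((s + 1) % record_stride == 0 || s == nsteps - 1)) {
      compute_structure(X, cid, ctype, q, S, true);
      double tot = 0.0, ifa = 0.0;
      for (size_t c = 1; c < S.cell_area.size(); ++c) {
        tot += S.cell_area[c];
        ifa += S.cell_iface_area[c];
      }
      rec_t.push_back(t0 + (s + 1) * q.dt);
      rec_ip.push_back(tot > 0 ? ifa / tot : 0.0);
    }
  }
  compute_structure(X, cid, ctype, q, S, true);

  NumericMatrix Xo(n, 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) Xo(i, d) = X[i][d];
  return List::create(
      _["pos"] = Xo, _["time"] = t0 + nsteps * q.dt,
      _["max_displacement"] = maxdisp_seen,
      _["trace_time"] = wrap(rec_t), _["trace_ip"] = wrap(rec_ip),
      _["structure"] = structure_to_list(S));
}
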