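#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Anisotropic eikonal solver on a tetrahedral mesh, fast-iterative style:
// label-correcting sweeps with local tetrahedron updates. The per-element
// symmetric travel-time metric G gives segment travel time sqrt(d' G d);
// inactive (scar) elements are skipped entirely.

static inline double qform(const double *G, const double *d) {
  // G packed as xx yy zz xy xz yz
  return G[0] * d[0] * d[0] + G[1] * d[1] * d[1] + G[2] * d[2] * d[2] +
         2.0 * (G[3] * d[0] * d[1] + G[4] * d[0] * d[2] + G[5] * d[1] * d[2]);
}

static inline void gmul(const double *G, const double *d, double *out) {
  out[0] = G[0] * d[0] + G[3] * d[1] + G[4] * d[2];
  out[1] = G[3] * d[0] + G[1] * d[1] + G[5] * d[2];
  out[2] = G[4] * d[0] + G[5] * d[1] + G[2] * d[2];
}

static inline double seg_time(const double *G, const double *a, const double *b) {
  double d[3] = {b[0] - a[0], b[1] - a[1], b[2] - a[2]};
  double q = qform(G, d);
  return q > 0 ? std::sqrt(q) : 0.0;
}

// update through the interior of an edge (xa,Ta)-(xb,Tb) toward x0
static double edge_update(const double *G, const double *x0,
                          const double *xa, double Ta,
                          const double *xb, double Tb) {
  double P[3] = {xa[0] - xb[0], xa[1] - xb[1], xa[2] - xb[2]};
  double z[3] = {x0[0] - xb[0], x0[1] - xb[1], x0[2] - xb[2]};
  double e = Ta - Tb;
  double GP[3], Gz[3];
  gmul(G, P, GP);
  gmul(G, z, Gz);
  double A = P[0] * GP[0] + P[1] * GP[1] + P[2] * GP[2];
  if (A <= 0) return std::numeric_limits<double>::infinity();
  double a = (P[0] * Gz[0] + P[1] * Gz[1] + P[2] * Gz[2]) / A;
  double b = e / A;
  double u[3] = {z[0] - P[0] * a, z[1] - P[1] * a, z[2] - P[2] * a};
  double w[3] = {P[0] * b, P[1] * b, P[2] * b};
  double Gu[3], Gw[3];
  gmul(G, u, Gu);
  gmul(G, w, Gw);
  double uGu = u[0] * Gu[0] + u[1] * Gu[1] + u[2] * Gu[2];
  double uGw = u[0] * Gw[0] + u[1] * Gw[1] + u[2] * Gw[2];
  double wGw = w[0] * Gw[0] + w[1] * Gw[1] + w[2] * Gw[2];
  double c2 = 1.0 - wGw, c1 = -2.0 * uGw, c0 = -uGu;
  double best = std::numeric_limits<double>::infinity();
  double roots[2];
  int nr = 0;
  if (std::fabs(c2) < 1e-14) {
    if (std::fabs(c1) > 1e-14) roots[nr++] = -c0 / c1;
  } else {
    double disc = c1 * c1 - 4.0 * c2 * c0;
    if (disc >= 0) {
      double s = std::sqrt(disc);
      roots[nr++] = (-c1 + s) / (2.0 * c2);
      roots[nr++] = (-c1 - s) / (2.0 * c2);
    }
  }
  for (int r = 0; r < nr; ++r) {
    double t = roots[r];
    if (t <= 0 || !std::isfinite(t)) continue;
    double lam = a - b * t;
    if (lam < -1e-9 || lam > 1.0 + 1e-9) continue;
    double d[3] = {z[0] - P[0] * lam, z[1] - P[1] * lam, z[2] - P[2] * lam};
    double q = qform(G, d);
    double cand = Tb + lam * e + (q > 0 ? std::sqrt(q) : 0.0);
    if (cand < best) best = cand;
  }
  return best;
}

// update through the interior of face (x1,x2,x3) toward x0
static double face_update(const double *G, const double *x0,
                          const double *x1, double T1,
                          const double *x2, double T2,
                          const double *x3, double T3) {
  double P1[3] = {x1[0] - x3[0], x1[1] - x3[1], x1[2] - x3[2]};
  double P2[3] = {x2[0] - x3[0], x2[1] - x3[1], x2[2] - x3[2]};
  double z[3] = {x0[0] - x3[0], x0[1] - x3[1], x0[2] - x3[2]};
  double e1 = T1 - T3, e2 = T2 - T3;
  double GP1[3], GP2[3], Gz[3];
  gmul(G, P1, GP1);
  gmul(G, P2, GP2);
  gmul(G, z, Gz);
  double A11 = P1[0] * GP1[0] + P1[1] * GP1[1] + P1[2] * GP1[2];
  double A12 = P1[0] * GP2[0] + P1[1] * GP2[1] + P1[2] * GP2[2];
  double A22 = P2[0] * GP2[0] + P2[1] * GP2[1] + P2[2] * GP2[2];
  double r1 = P1[0] * Gz[0] + P1[1] * Gz[1] + P1[2] * Gz[2];
  double r2 = P2[0] * Gz[0] + P2[1] * Gz[1] + P2[2] * Gz[2];
  double det = A11 * A22 - A12 * A12;
  if (std::fabs(det) < 1e-14 || det <= 0)
    return std::numeric_limits<double>::infinity();
  double a1 = (A22 * r1 - A12 * r2) / det;
  double a2 = (-A12 * r1 + A11 * r2) / det;
  double b1 = (A22 * e1 - A12 * e2) / det;
  double b2 = (-A12 * e1 + A11 * e2) / det;
  double u[3] = {z[0] - P1[0] * a1 - P2[0] * a2,
                 z[1] - P1[1] * a1 - P2[1] * a2,
                 z[2] - P1[2] * a1 - P2[2] * a2};
  double w[3] = {P1[0] * b1 + P2[0] * b2,
                 P1[1] * b1 + P2[1] * b2,
                 P1[2] * b1 + P2[2] * b2};
  double Gu[3], Gw[3];
  gmul(G, u, Gu);
  gmul(G, w, Gw);
  double uGu = u[0] * Gu[0] + u[1] * Gu[1] + u[2] * Gu[2];
  double uGw = u[0] * Gw[0] + u[1] * Gw[1] + u[2] * Gw[2];
  double wGw = w[0] * Gw[0] + w[1] * Gw[1] + w[2] * Gw[2];
  double c2 = 1.0 - wGw, c1 = -2.0 * uGw, c0 = -uGu;
  double best = std::numeric_limits<double>::infinity();
  double roots[2];
  int nr = 0;
  if (std::fabs(c2) < 1e-14) {
    if (std::fabs(c1) > 1e-14) roots[nr++] = -c0 / c1;
  } else {
    double disc = c1 * c1 - 4.0 * c2 * c0;
    if (disc >= 0) {
      double s = std::sqrt(disc);
      roots[nr++] = (-c1 + s) / (2.0 * c2);
      roots[nr++] = (-c1 - s) / (2.0 * c2);
    }
  }
  for (int r = 0; r < nr; ++r) {
    double t = roots[r];
    if (t <= 0 || !std::isfinite(t)) continue;
    double l1 = a1 - b1 * t, l2 = a2 - b2 * t;
    if (l1 < -1e-9 || l2 < -1e-9 || l1 + l2 > 1.0 + 1e-9) continue;
    double d[3] = {z[0] - P1[0] * l1 - P2[0] * l2,
                   z[1] - P1[1] * l1 - P2[1] * l2,
                   z[2] - P1[2] * l1 - P2[2] * l2};
    double q = qform(G, d);
    double cand = T3 + l1 * e1 + l2 * e2 + (q > 0 ? std::sqrt(q) : 0.0);
    if (cand < best) best = cand;
  }
  return best;
}

// [[Rcpp::export(name = ".eikonal_solve_cpp")]]
NumericVector eikonal_solve_cpp(NumericMatrix nodes, IntegerMatrix tets,
                                NumericMatrix Gmat, LogicalVector active,
                                IntegerVector src_nodes, NumericVector src_times,
                                double tol = 1e-6) {
  const int n = nodes.nrow(), m = tets.nrow();
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> T(n, INF);
  std::vector<std::array<double, 3>> X(n);
  for (int i = 0; i < n; ++i)
    X[i] = {nodes(i, 0), nodes(i, 1), nodes(i, 2)};

  std::vector<std::vector<int>> inc(n);
  for (int e = 0; e < m; ++e) {
    if (!active[e]) continue;
    for (int k = 0; k < 4; ++k) inc[tets(e, k) - 1].push_back(e);
  }

  std::vector<char> in_q(n, 0);
  std::queue<int> q;
  for (int s = 0; s < src_nodes.size(); ++s) {
    int v = src_nodes[s] - 1;
    if (src_times[s] < T[v]) T[v] = src_times[s];
  }
  // seed the queue with all nodes sharing an element with a source
  for (int s = 0; s < src_nodes.size(); ++s) {
    int v = src_nodes[s] - 1;
    for (size_t a = 0; a < inc[v].size(); ++a) {
      int e = inc[v][a];
      for (int k = 0; k < 4; ++k) {
        int u = tets(e, k) - 1;
        if (!in_q[u]) { in_q[u] = 1; q.push(u); }
      }
    }
  }

  long pops = 0;
  const long max_pops = 2000L * (long)n + 1000000L;
  while (!q.empty() && pops < max_pops) {
    int v = q.front(); q.pop(); in_q[v] = 0; ++pops;
    double best = T[v];
    const double *x0 = X[v].data();
    for (size_t a = 0; a < inc[v].size(); ++a) {
      int e = inc[v][a];
      const double *G = &Gmat(0, e);
      // gather the three opposite vertices
      int o[3], no = 0;
      for (int k = 0; k < 4; ++k) {
        int u = tets(e, k) - 1;
        if (u != v) o[no++] = u;
      }
      if (no != 3) continue;  // degenerate (duplicated vertex)
      double Ta = T[o[0]], Tb = T[o[1]], Tc = T[o[2]];
      // vertex updates
      if (std::isfinite(Ta)) {
        double c = Ta + seg_time(G, X[o[0]].data(), x0);
        if (c < best) best = c;
      }
      if (std::isfinite(Tb)) {
        double c = Tb + seg_time(G, X[o[1]].data(), x0);
        if (c < best) best = c;
      }
      if (std::isfinite(Tc)) {
        double c = Tc + seg_time(G, X[o[2]].data(), x0);
        if (c < best) best = c;
      }
      // edge updates
      if (std::isfinite(Ta) && std::isfinite(Tb)) {
        double c = edge_update(G, x0, X[o[0]].data(), Ta, X[o[1]].data(), Tb);
        if (c < best) best = c;
      }
      if (std::isfinite(Ta) && std::isfinite(Tc)) {
        double c = edge_update(G, x0, X[o[0]].data(), Ta, X[o[2]].data(), Tc);
        if (c < best) best = c;
      }
      if (std::isfinite(Tb) && std::isfinite(Tc)) {
        double c = edge_update(G, x0, X[o[1]].data(), Tb, X[o[2]].data(), Tc);
        if (c < best) best = c;
      }
      // face update
      if (std::isfinite(Ta) && std::isfinite(Tb) && std::isfinite(Tc)) {
        double c = face_update(G, x0, X[o[0]].data(), Ta, X[o[1]].data(), Tb,
                               X[o[2]].data(), Tc);
        if (c < best) best = c;
      }
    }
    if (best < T[v] - tol) {
      T[v] = best;
      for (size_t a = 0; a < inc[v].size(); ++a) {
        int e = inc[v][a];
        for (int k = 0; k < 4; ++k) {
          int u = tets(e, k) - 1;
          if (u != v && !in_q[u]) { in_q[u] = 1; q.push(u); }
        }
      }
    }
  }

  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = std::isfinite(T[i]) ? T[i] : NA_REAL;
  return out;
}
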