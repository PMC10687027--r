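#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>
using namespace Rcpp;

// Exact earth-mover (Wasserstein-1) distance between two small discrete
// distributions, solved as an uncapacitated bipartite min-cost flow by
// successive shortest paths with Johnson potentials (dense Dijkstra).
// Costs must be nonnegative; supplies and demands must each sum to ~1.
//
// Termination: each augmentation exhausts a source, a sink, or zeroes an
// existing flow arc; a generous iteration guard catches pathological input.
static double emd_ssp(const std::vector<double>& a,
                      const std::vector<double>& b,
                      const std::vector<double>& C /* ns x nd, row-major */) {
  const int ns = (int)a.size(), nd = (int)b.size(), n = ns + nd;
  const double INF = std::numeric_limits<double>::infinity();
  const double EPS = 1e-13;

  std::vector<double> supply(a), demand(b);
  std::vector<double> flow((size_t)ns * nd, 0.0);
  std::vector<double> pot(n, 0.0);
  std::vector<double> dist(n);
  std::vector<int> prev(n);
  std::vector<char> done(n);

  double remaining = 0.0;
  for (int i = 0; i < ns; ++i) remaining += a[i];

  int guard = 0;
  const int guard_max = 60 * n + 2000;
  while (remaining > 1e-12) {
    if (++guard > guard_max) stop("transport solver failed to converge");

    std::fill(dist.begin(), dist.end(), INF);
    std::fill(prev.begin(), prev.end(), -1);
    std::fill(done.begin(), done.end(), 0);
    for (int i = 0; i < ns; ++i)
      if (supply[i] > EPS) dist[i] = 0.0;

    for (int it = 0; it < n; ++it) {
      int u = -1; double best = INF;
      for (int v = 0; v < n; ++v)
        if (!done[v] && dist[v] < best) { best = dist[v]; u = v; }
      if (u < 0) break;
      done[u] = 1;
      if (u < ns) {                       // source -> every sink
        const int i = u;
        for (int j = 0; j < nd; ++j) {
          double rc = C[(size_t)i * nd + j] + pot[i] - pot[ns + j];
          if (rc < 0 && rc > -1e-9) rc = 0.0;  // numerical guard
          if (dist[i] + rc < dist[ns + j]) {
            dist[ns + j] = dist[i] + rc;
            prev[ns + j] = i;
          }
        }
      } else {                            // sink -> sources with flow (residual)
        const int j = u - ns;
        for (int i = 0; i < ns; ++i) {
          if (flow[(size_t)i * nd + j] > EPS) {
            double rc = -C[(size_t)i * nd + j] + pot[ns + j] - pot[i];
            if (rc < 0 && rc > -1e-9) rc = 0.0;
            if (dist[ns + j] + rc < dist[i]) {
              dist[i] = dist[ns + j] + rc;
              prev[i] = ns + j;
            }
          }
        }
      }
    }

    // cheapest reachable sink with unmet demand
    int t = -1; double bestd = INF;
    for (int j = 0; j < nd; ++j)
      if (demand[j] > EPS && dist[ns + j] < bestd) { bestd = dist[ns + j]; t = ns + j; }
    if (t < 0) stop("transport infeasible: no reachable sink with unmet demand");

    // Johnson potential update, capped at the sink distance so reduced
    // costs stay nonnegative on arcs into unreached nodes
    for (int v = 0; v < n; ++v)
      pot[v] += std::min(dist[v], bestd);

    // bottleneck along the augmenting path
    double amt = demand[t - ns];
    for (int v = t; prev[v] >= 0; v = prev[v]) {
      const int u2 = prev[v];
      if (u2 >= ns && v < ns) {           // residual arc sink->source limited by flow
        amt = std::min(amt, flow[(size_t)v * nd + (u2 - ns)]);
      }
    }
    {
      int v = t;
      while (prev[v] >= 0) v = prev[v];
      amt = std::min(amt, supply[v]);     // path starts at a source
    }

    // apply augmentation
    for (int v = t; prev[v] >= 0; v = prev[v]) {
      const int u2 = prev[v];
      if (u2 < ns && v >= ns) flow[(size_t)u2 * nd + (v - ns)] += amt;
      else                    flow[(size_t)v  * nd + (u2 - ns)] -= amt;
    }
    {
      int v = t;
      while (prev[v] >= 0) v = prev[v];
      supply[v] -= amt;
    }
    demand[t - ns] -= amt;
    remaining -= amt;
  }

  double cost = 0.0;
  for (int i = 0; i < ns; ++i)
    for (int j = 0; j < nd; ++j)
      cost += flow[(size_t)i * nd + j] * C[(size_t)i * nd + j];
  return cost;
}

// [[Rcpp::export]]
double emd_cpp(NumericVector a, NumericVector b, NumericMatrix cost) {
  const int ns = a.size(), nd = b.size();
  if (cost.nrow() != ns || cost.ncol() != nd)
    stop("cost matrix dimensions do not match the distributions");
  std::vector<double> av(a.begin(), a.end()), bv(b.begin(), b.end());
  std::vector<double> C((size_t)ns * nd);
  for (int i = 0; i < ns; ++i)
    for (int j = 0; j < nd; ++j) {
      double c = cost(i, j);
      if (!std::isfinite(c) || c < 0) stop("ground distances must be finite and nonnegative");
      C[(size_t)i * nd + j] = c;
    }
  return emd_ssp(av, bv, C);
}

// Batched Ollivier-Ricci curvature for all edges of one sample graph.
// edges_i/edges_j: 0-based endpoint indices; adj: 0-based neighbor lists;
// r: positive node values; D: ground shortest-path matrix for W1;
// dvec: per-edge denominator distance d(i,j).
// kappa(i,j) = 1 - W1(mu_i, mu_j) / d(i,j), mu_i(k) ~ r_k over N(i).
// [[Rcpp::export]]
List orc_edges_cpp(IntegerVector edges_i, IntegerVector edges_j,
                   List adj, NumericVector r, NumericMatrix D,
                   NumericVector dvec) {
  const int m = edges_i.size();
  const int nnode = r.size();
  if (edges_j.size() != m) stop("edge endpoint vectors differ in length");
  if (dvec.size() != m) stop("dvec must have one entry per edge");
  if (adj.size() != nnode) stop("adjacency list does not match node count");

  // pre-normalized neighbor distributions
  std::vector<std::vector<int> > nbr(nnode);
  std::vector<std::vector<double> > mu(nnode);
  for (int v = 0; v < nnode; ++v) {
    IntegerVector nv = adj[v];
    const int d = nv.size();
    if (d == 0) stop("isolated node encountered");
    nbr[v].assign(nv.begin(), nv.end());
    double s = 0.0;
    for (int k = 0; k < d; ++k) s += r[nv[k]];
    mu[v].resize(d);
    for (int k = 0; k < d; ++k) mu[v][k] = r[nv[k]] / s;
  }

  NumericVector W1(m), dd(m), kappa(m);
  std::vector<double> C;
  for (int e = 0; e < m; ++e) {
    const int i = edges_i[e], j = edges_j[e];
    const int ni = (int)nbr[i].size(), nj = (int)nbr[j].size();
    C.assign((size_t)ni * nj, 0.0);
    for (int a = 0; a < ni; ++a)
      for (int b = 0; b < nj; ++b)
        C[(size_t)a * nj + b] = D(nbr[i][a], nbr[j][b]);
    const double w1 = emd_ssp(mu[i], mu[j], C);
    const double dij = dvec[e];
    W1[e] = w1;
    dd[e] = dij;
    kappa[e] = 1.0 - w1 / dij;
  }
  return List::create(_["W1"] = W1, _["d"] = dd, _["kappa"] = kappa);
}
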