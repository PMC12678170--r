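// Exact transportation-simplex solver (north-west-corner start, MODI pricing)
// for the empirical Wasserstein-1 distance used by the representation-
// balancing penalty.  Small dense problems (minibatch-sized); exactness
// matters because the same value serves as the reported IPM.

#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export(name = ".cpp_transport_simplex")]]
List cpp_transport_simplex(NumericMatrix cost, NumericVector supply,
                           NumericVector demand, int max_iter = 100000) {
  const int n = supply.size(), m = demand.size();
  if (cost.nrow() != n || cost.ncol() != m)
    stop("cost dimensions do not match supply/demand");

  const int nb = n + m - 1;
  std::vector<int> bi(nb), bj(nb);
  std::vector<double> alloc(nb);

  // north-west corner
  {
    std::vector<double> a(supply.begin(), supply.end());
    std::vector<double> b(demand.begin(), demand.end());
    int i = 0, j = 0;
    for (int k = 0; k < nb; ++k) {
      double t = std::min(a[i], b[j]);
      bi[k] = i; bj[k] = j; alloc[k] = t;
      a[i] -= t; b[j] -= t;
      if (i == n - 1 && j == m - 1) {
        // should only happen at k == nb - 1
        for (int kk = k + 1; kk < nb; ++kk) { bi[kk] = i; bj[kk] = j; alloc[kk] = 0.0; }
        break;
      }
      if (a[i] <= b[j] + 1e-15 && i < n - 1) ++i; else ++j;
    }
  }

  double cmax = 1.0;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j) cmax = std::max(cmax, std::fabs(cost(i, j)));
  const double tol = 1e-11 * cmax;

  std::vector<double> u(n), v(m);
  std::vector<char> useen(n), vseen(m);
  // adjacency over nodes: rows 0..n-1, cols n..n+m-1; edges are basic cells
  std::vector<std::vector<int>> adj(n + m);
  std::vector<int> prev_edge(n + m), prev_node(n + m);
  std::vector<char> visited(n + m);

  for (int iter = 0; iter < max_iter; ++iter) {
    // rebuild adjacency
    for (auto &a : adj) a.clear();
    for (int k = 0; k < nb; ++k) {
      adj[bi[k]].push_back(k);
      adj[n + bj[k]].push_back(k);
    }
    // potentials via BFS from row 0
    std::fill(useen.begin(), useen.end(), 0);
    std::fill(vseen.begin(), vseen.end(), 0);
    u[0] = 0.0; useen[0] = 1;
    std::queue<int> q;
    q.push(0);
    while (!q.empty()) {
      int node = q.front(); q.pop();
      for (int k : adj[node]) {
        if (node < n) {
          int jj = bj[k];
          if (!vseen[jj]) { v[jj] = cost(node, jj) - u[node]; vseen[jj] = 1; q.push(n + jj); }
        } else {
          int ii = bi[k];
          if (!useen[ii]) { u[ii] = cost(ii, node - n) - v[node - n]; useen[ii] = 1; q.push(ii); }
        }
      }
    }
    // most negative reduced cost
    double best = -tol; int ei = -1, ej = -1;
    for (int j = 0; j < m; ++j)
      for (int i = 0; i < n; ++i) {
        double r = cost(i, j) - u[i] - v[j];
        if (r < best) { best = r; ei = i; ej = j; }
      }
    if (ei < 0) break;

    // path from row ei to col ej through the basis tree (BFS)
    std::fill(visited.begin(), visited.end(), 0);
    visited[ei] = 1;
    std::queue<int> q2; q2.push(ei);
    const int target = n + ej;
    while (!q2.empty()) {
      int node = q2.front(); q2.pop();
      if (node == target) break;
      for (int k : adj[node]) {
        int nxt = (node < n) ? (n + bj[k]) : bi[k];
        if (!visited[nxt]) {
          visited[nxt] = 1; prev_edge[nxt] = k; prev_node[nxt] = node;
          q2.push(nxt);
        }
      }
    }
    if (!visited[target]) stop("transport_simplex: basis tree disconnected");
    std::vector<int> path;
    for (int node = target; node != ei; node = prev_node[node])
      path.push_back(prev_edge[node]);
    std::reverse(path.begin(), path.end());

    // entering cell +, path alternates -, +, -, ... starting with -
    double theta = R_PosInf; int leave = -1;
    for (size_t t = 0; t < path.size(); t += 2) {
      if (alloc[path[t]] < theta) { theta = alloc[path[t]]; leave = path[t]; }
    }
    for (size_t t = 0; t < path.size(); ++t)
      alloc[path[t]] += (t % 2 == 0 ? -theta : theta);
    bi[leave] = ei; bj[leave] = ej; alloc[leave] = theta;
  }

  double total = 0.0;
  int keep = 0;
  for (int k = 0; k < nb; ++k) if (alloc[k] > 0) ++keep;
  IntegerVector oi(keep), oj(keep);
  NumericVector om(keep);
  for (int k = 0, t = 0; k < nb; ++k) {
    if (alloc[k] > 0) {
      oi[t] = bi[k] + 1; oj[t] = bj[k] + 1; om[t] = alloc[k];
      total += cost(bi[k], bj[k]) * alloc[k];
      ++t;
    }
  }
  return List::create(_["cost"] = total, _["i"] = oi, _["j"] = oj, _["mass"] = om);
}
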