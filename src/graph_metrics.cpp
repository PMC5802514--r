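// R-facing wrappers for the single-graph metric kernels in graph_core.h.
// Input: dense symmetric nonnegative weight matrix with zero diagonal.

#include <Rcpp.h>
#include "graph_core.h"

using namespace Rcpp;

static scov::Adj adj_from_dense(const NumericMatrix& W) {
  int n = W.nrow();
  scov::Adj a(n);
  for (int j = 0; j < n; ++j)
    for (int i = j + 1; i < n; ++i)
      if (W(i, j) > 0.0) a.add_edge(i, j, W(i, j));
  return a;
}

// [[Rcpp::export]]
List cpp_triangle_metrics(NumericMatrix W) {
  scov::Adj a = adj_from_dense(W);
  int n = a.n;
  NumericVector cc(n);
  double trans, cmean;
  scov::triangle_metrics(a, REAL(W), &trans, &cmean, REAL(cc));
  return List::create(_["transitivity"] = trans,
                      _["clustering_coefficient"] = cmean,
                      _["clustering_nodal"] = cc);
}

// [[Rcpp::export]]
NumericMatrix cpp_apsp(NumericMatrix W) {
  scov::Adj a = adj_from_dense(W);
  int n = a.n;
  NumericMatrix D(n, n);
  std::vector<double> dist;
  for (int s = 0; s < n; ++s) {
    scov::dijkstra(a, s, dist);
    for (int v = 0; v < n; ++v) D(s, v) = dist[v] == scov::INF ? R_PosInf : dist[v];
  }
  return D;
}

// [[Rcpp::export]]
NumericVector cpp_betweenness(NumericMatrix W) {
  scov::Adj a = adj_from_dense(W);
  std::vector<double> bc;
  scov::betweenness(a, bc);
  return NumericVector(bc.begin(), bc.end());
}

// [[Rcpp::export]]
List cpp_louvain(NumericMatrix W, int n_runs, double seed) {
  scov::Adj a = adj_from_dense(W);
  std::vector<int> mem(a.n, 0);
  double q = scov::louvain_best(a, n_runs, (uint64_t)seed, &mem);
  IntegerVector out(a.n);
  for (int i = 0; i < a.n; ++i) out[i] = mem.empty() ? 1 : mem[i] + 1;
  return List::create(_["modularity"] = q, _["membership"] = out);
}
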