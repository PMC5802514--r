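// Permutation engine: for every group-label assignment (observed + nulls),
// rebuild both group networks from the subject x ROI volume matrix —
// Pearson correlation, negative-edge removal, density thresholding with the
// deterministic (-weight, i, j) tie rule — incrementally across the density
// grid, evaluate the requested metrics, and return stress-minus-control
// differences. Doing the whole inner loop here keeps a 10,000-permutation
// run at rodent scale tractable.

#include <Rcpp.h>
#include <algorithm>
#include "graph_core.h"

using namespace Rcpp;

// metric codes (kept in sync with the R wrapper):
// 1 transitivity, 2 clustering_coefficient, 3 modularity, 4 path_length,
// 5 degree(node), 6 strength(node), 7 betweenness(node), 8 closeness(node)

// [[Rcpp::export]]
NumericMatrix cpp_perm_engine(NumericMatrix X, IntegerMatrix stress_rows,
                              IntegerVector ks, IntegerVector metric_codes,
                              int node, int modularity_runs,
                              NumericMatrix lseed) {
  const int n = X.nrow(), p = X.ncol();
  const int n_stress = stress_rows.nrow();
  const int n_assign = stress_rows.ncol();
  const int nd = ks.size(), nm = metric_codes.size();
  const int kmax = ks[nd - 1];
  const long M = (long)p * (p - 1) / 2;
  const int node0 = node - 1;

  bool need_tri = false, need_pl = false;
  for (int mi = 0; mi < nm; ++mi) {
    if (metric_codes[mi] == 1 || metric_codes[mi] == 2) need_tri = true;
    if (metric_codes[mi] == 4) need_pl = true;
  }

  NumericMatrix out(n_assign, nm * nd);

  // edge enumeration i < j (0-based), column-major upper triangle
  std::vector<int> ei(M), ej(M);
  {
    long e = 0;
    for (int j = 1; j < p; ++j)
      for (int i = 0; i < j; ++i) { ei[e] = i; ej[e] = j; ++e; }
  }

  std::vector<char> in_stress(n);
  std::vector<int> rows;
  std::vector<double> mu(p), sd(p), Z((size_t)n * p), R((size_t)p * p),
      Wd((size_t)p * p), w(M);
  std::vector<long> ord(M);
  scov::Adj adj(p);
  std::vector<double> dist, bc;

  for (int a = 0; a < n_assign; ++a) {
    if (a % 64 == 0) Rcpp::checkUserInterrupt();
    std::fill(in_stress.begin(), in_stress.end(), 0);
    for (int s = 0; s < n_stress; ++s) in_stress[stress_rows(s, a) - 1] = 1;

    for (int gi = 0; gi < 2; ++gi) {
      rows.clear();
      for (int i = 0; i < n; ++i)
        if ((int)in_stress[i] == gi) rows.push_back(i);
      const int ng = (int)rows.size();

      // column-standardize the group's submatrix, then R = Z'Z / (ng-1)
      for (int j = 0; j < p; ++j) {
        double m = 0.0;
        for (int r = 0; r < ng; ++r) m += X(rows[r], j);
        m /= ng;
        double v = 0.0;
        for (int r = 0; r < ng; ++r) {
          double d = X(rows[r], j) - m;
          Z[(size_t)j * ng + r] = d;
          v += d * d;
        }
        if (v <= 0.0)
          stop("zero within-group variance for ROI %d during permutation", j + 1);
        double inv = 1.0 / std::sqrt(v);
        for (int r = 0; r < ng; ++r) Z[(size_t)j * ng + r] *= inv;
      }
      for (long e = 0; e < M; ++e) {
        const double* zi = &Z[(size_t)ei[e] * ng];
        const double* zj = &Z[(size_t)ej[e] * ng];
        double s = 0.0;
        for (int r = 0; r < ng; ++r) s += zi[r] * zj[r];
        w[e] = s > 0.0 ? s : 0.0;  // discard negatives
      }
      for (long e = 0; e < M; ++e) ord[e] = e;
      std::partial_sort(ord.begin(), ord.begin() + kmax, ord.end(),
                        [&](long x, long y) {
                          if (w[x] != w[y]) return w[x] > w[y];
                          if (ei[x] != ei[y]) return ei[x] < ei[y];
                          return ej[x] < ej[y];
                        });
      if (w[ord[kmax - 1]] <= 0.0) {
        long npos = 0;
        for (long e = 0; e < M; ++e) if (w[e] > 0.0) ++npos;
        stop("only %d positive correlations in a permuted group; "
             "maximum achievable density is %.4f",
             (int)npos, (double)npos / M);
      }

      adj.reset(p);
      std::fill(Wd.begin(), Wd.end(), 0.0);
      int prev = 0;
      for (int di = 0; di < nd; ++di) {
        for (int e = prev; e < ks[di]; ++e) {
          int i = ei[ord[e]], j = ej[ord[e]];
          double we = w[ord[e]];
          adj.add_edge(i, j, we);
          Wd[(size_t)j * p + i] = we;
          Wd[(size_t)i * p + j] = we;
        }
        prev = ks[di];

        double trans = NA_REAL, cmean = NA_REAL;
        if (need_tri) scov::triangle_metrics(adj, Wd.data(), &trans, &cmean,
                                             (double*)0);
        double pl = NA_REAL;
        if (need_pl) pl = scov::mean_path_length(adj);

        for (int mi = 0; mi < nm; ++mi) {
          double val = NA_REAL;
          switch (metric_codes[mi]) {
          case 1: val = trans; break;
          case 2: val = cmean; break;
          case 3:
            val = scov::louvain_best(
                adj, modularity_runs,
                (uint64_t)lseed(a, gi * nd + di), (std::vector<int>*)0);
            break;
          case 4: val = pl; break;
          case 5: val = (double)adj.nbr[node0].size(); break;
          case 6: {
            double s = 0.0;
            for (size_t q = 0; q < adj.wt[node0].size(); ++q)
              s += adj.wt[node0][q];
            val = s;
            break;
          }
          case 7:
            scov::betweenness(adj, bc);
            val = bc[node0];
            break;
          case 8: val = scov::closeness_node(adj, node0); break;
          }
          // accumulate stress - control
          if (gi == 0) out(a, mi * nd + di) = -val;
          else out(a, mi * nd + di) += val;
        }
      }
    }
  }
  return out;
}
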