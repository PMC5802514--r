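// Shared core for weighted graph metrics: adjacency representation, a
// deterministic PRNG, and the metric kernels used both by the single-graph
// R-facing wrappers and by the permutation engine.
//
// Conventions: undirected graphs, nonnegative weights, no self-loops.
// Triangle metrics are Onnela-style with max-weight normalization; distances
// are 1/weight; modularity is Newman Q optimized by multi-restart Louvain.

#ifndef SCOVNET_GRAPH_CORE_H
#define SCOVNET_GRAPH_CORE_H

#include <vector>
#include <queue>
#include <cmath>
#include <cstdint>
#include <limits>

namespace scov {

const double INF = std::numeric_limits<double>::infinity();

struct Adj {
  int n;
  std::vector<std::vector<int> > nbr;
  std::vector<std::vector<double> > wt;
  double wmax;
  explicit Adj(int n_ = 0) { reset(n_); }
  void reset(int n_) {
    n = n_;
    nbr.assign(n, std::vector<int>());
    wt.assign(n, std::vector<double>());
    wmax = 0.0;
  }
  void add_edge(int i, int j, double w) {
    nbr[i].push_back(j); wt[i].push_back(w);
    nbr[j].push_back(i); wt[j].push_back(w);
    if (w > wmax) wmax = w;
  }
};

// xorshift64* PRNG: deterministic across platforms, independent of R's RNG.
struct XorShift {
  uint64_t s;
  explicit XorShift(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    s ^= s >> 12; s ^= s << 25; s ^= s >> 27;
    return s * 0x2545F4914F6CDD1DULL;
  }
  int below(int m) { return (int)(next() % (uint64_t)m); }
};

// Onnela transitivity and mean nodal clustering; Wdense is the n x n dense
// weight matrix (column-major, leading dimension n) used for O(1) edge
// lookup. cc_nodal may be null.
inline void triangle_metrics(const Adj& a, const double* Wdense,
                             double* transitivity, double* clustering,
                             double* cc_nodal) {
  int n = a.n;
  double num_sum = 0.0, den_sum = 0.0, cmean = 0.0;
  if (a.wmax <= 0.0) {
    *transitivity = NAN; *clustering = NAN;
    if (cc_nodal) for (int i = 0; i < n; ++i) cc_nodal[i] = 0.0;
    return;
  }
  double inv_wmax = 1.0 / a.wmax;
  for (int i = 0; i < n; ++i) {
    int k = (int)a.nbr[i].size();
    double num = 0.0, ci = 0.0;
    if (k >= 2) {
      for (int p = 0; p < k; ++p) {
        int j = a.nbr[i][p];
        double wij = a.wt[i][p] * inv_wmax;
        for (int q = p + 1; q < k; ++q) {
          int h = a.nbr[i][q];
          double wjh = Wdense[(size_t)h * n + j];
          if (wjh > 0.0)
            num += 2.0 * std::cbrt(wij * (a.wt[i][q] * inv_wmax) *
                                   (wjh * inv_wmax));
        }
      }
      ci = num / ((double)k * (k - 1));
    }
    if (cc_nodal) cc_nodal[i] = ci;
    cmean += ci;
    num_sum += num;
    den_sum += (double)k * (k - 1);
  }
  *transitivity = den_sum > 0.0 ? num_sum / den_sum : 0.0;
  *clustering = cmean / n;
}

// Dijkstra from one source; fills dist (length n) with 1/w distances.
inline void dijkstra(const Adj& a, int s, std::vector<double>& dist) {
  int n = a.n;
  dist.assign(n, INF);
  std::vector<char> done(n, 0);
  typedef std::pair<double, int> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;
  dist[s] = 0.0;
  pq.push(QE(0.0, s));
  while (!pq.empty()) {
    QE top = pq.top(); pq.pop();
    int u = top.second;
    if (done[u]) continue;
    done[u] = 1;
    for (size_t p = 0; p < a.nbr[u].size(); ++p) {
      int v = a.nbr[u][p];
      double nd = dist[u] + 1.0 / a.wt[u][p];
      if (nd < dist[v]) { dist[v] = nd; pq.push(QE(nd, v)); }
    }
  }
}

// mean shortest-path distance over connected ordered pairs; NAN if none
inline double mean_path_length(const Adj& a) {
  std::vector<double> dist;
  double sum = 0.0;
  long cnt = 0;
  for (int s = 0; s < a.n; ++s) {
    dijkstra(a, s, dist);
    for (int v = 0; v < a.n; ++v)
      if (v != s && dist[v] < INF) { sum += dist[v]; ++cnt; }
  }
  return cnt ? sum / cnt : NAN;
}

// Wasserman-Faust closeness of one node: ((r-1)/sum d) * (r-1)/(n-1)
inline double closeness_node(const Adj& a, int i) {
  std::vector<double> dist;
  dijkstra(a, i, dist);
  double sum = 0.0;
  int r = 1;
  for (int v = 0; v < a.n; ++v)
    if (v != i && dist[v] < INF) { sum += dist[v]; ++r; }
  if (r <= 1) return 0.0;
  return ((r - 1) / sum) * ((double)(r - 1) / (a.n - 1));
}

// Brandes betweenness (endpoints excluded), normalized by (n-1)(n-2)/2.
// Near-equal path lengths (relative 1e-12) count as ties.
inline void betweenness(const Adj& a, std::vector<double>& bc) {
  int n = a.n;
  bc.assign(n, 0.0);
  if (n < 3) return;
  typedef std::pair<double, int> QE;
  for (int s = 0; s < n; ++s) {
    std::vector<double> dist(n, INF), sigma(n, 0.0), delta(n, 0.0);
    std::vector<char> done(n, 0);
    std::vector<std::vector<int> > pred(n);
    std::vector<int> order; order.reserve(n);
    dist[s] = 0.0; sigma[s] = 1.0;
    std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;
    pq.push(QE(0.0, s));
    while (!pq.empty()) {
      QE top = pq.top(); pq.pop();
      int u = top.second;
      if (done[u]) continue;
      done[u] = 1;
      order.push_back(u);
      for (size_t p = 0; p < a.nbr[u].size(); ++p) {
        int v = a.nbr[u][p];
        double nd = dist[u] + 1.0 / a.wt[u][p];
        double ref = dist[v] == INF ? nd : dist[v];
        double eps = 1e-12 * (1.0 + std::abs(ref));
        if (nd < dist[v] - eps) {
          dist[v] = nd;
          sigma[v] = sigma[u];
          pred[v].clear();
          pred[v].push_back(u);
          pq.push(QE(nd, v));
        } else if (std::abs(nd - dist[v]) <= eps) {
          sigma[v] += sigma[u];
          pred[v].push_back(u);
        }
      }
    }
    for (int t = (int)order.size() - 1; t >= 0; --t) {
      int w = order[t];
      for (size_t p = 0; p < pred[w].size(); ++p) {
        int v = pred[w][p];
        delta[v] += sigma[v] / sigma[w] * (1.0 + delta[w]);
      }
      if (w != s) bc[w] += delta[w];
    }
  }
  double norm = (double)(n - 1) * (n - 2);
  for (int i = 0; i < n; ++i) bc[i] /= norm;
}

// ---- Louvain ----

struct LouvainGraph {
  int n;
  std::vector<std::vector<int> > nbr;
  std::vector<std::vector<double> > wt;
  std::vector<double> self_loop;  // 2x internal weight after aggregation
  std::vector<double> strength;
  double two_m;
};

inline LouvainGraph lg_from_adj(const Adj& a) {
  LouvainGraph g;
  g.n = a.n;
  g.nbr = a.nbr;
  g.wt = a.wt;
  g.self_loop.assign(a.n, 0.0);
  g.strength.assign(a.n, 0.0);
  g.two_m = 0.0;
  for (int i = 0; i < a.n; ++i) {
    double s = 0.0;
    for (size_t p = 0; p < a.wt[i].size(); ++p) s += a.wt[i][p];
    g.strength[i] = s;
    g.two_m += s;
  }
  return g;
}

inline double one_louvain_run(const LouvainGraph& g0, XorShift& rng,
                              std::vector<int>& membership) {
  LouvainGraph g = g0;
  int n0 = g0.n;
  membership.resize(n0);
  for (int i = 0; i < n0; ++i) membership[i] = i;
  double two_m = g.two_m;
  if (two_m <= 0.0) return 0.0;

  while (true) {
    int n = g.n;
    std::vector<int> comm(n), ord(n);
    std::vector<double> tot(n);
    for (int i = 0; i < n; ++i) { comm[i] = i; tot[i] = g.strength[i]; ord[i] = i; }
    for (int i = n - 1; i > 0; --i) {
      int j = rng.below(i + 1);
      std::swap(ord[i], ord[j]);
    }
    std::vector<double> kin(n, 0.0);
    std::vector<int> touched;
    bool any_move = false, improved = true;
    while (improved) {
      improved = false;
      for (int oi = 0; oi < n; ++oi) {
        int i = ord[oi];
        int ci = comm[i];
        touched.clear();
        for (size_t p = 0; p < g.nbr[i].size(); ++p) {
          int c = comm[g.nbr[i][p]];
          if (kin[c] == 0.0) touched.push_back(c);
          kin[c] += g.wt[i][p];
        }
        tot[ci] -= g.strength[i];
        double best_gain = 0.0;
        int best_c = ci;
        double base = kin[ci] - tot[ci] * g.strength[i] / two_m;
        for (size_t t = 0; t < touched.size(); ++t) {
          int c = touched[t];
          double gain = (kin[c] - tot[c] * g.strength[i] / two_m) - base;
          if (gain > best_gain + 1e-12) { best_gain = gain; best_c = c; }
        }
        tot[best_c] += g.strength[i];
        if (best_c != ci) { comm[i] = best_c; improved = true; any_move = true; }
        for (size_t t = 0; t < touched.size(); ++t) kin[touched[t]] = 0.0;
        if (kin[ci] != 0.0) kin[ci] = 0.0;
      }
    }
    std::vector<int> remap(n, -1);
    int nc = 0;
    for (int i = 0; i < n; ++i)
      if (remap[comm[i]] < 0) remap[comm[i]] = nc++;
    for (int i = 0; i < n; ++i) comm[i] = remap[comm[i]];
    for (int i = 0; i < n0; ++i) membership[i] = comm[membership[i]];
    if (!any_move || nc == n) break;
    // aggregate communities into a smaller graph
    LouvainGraph h;
    h.n = nc;
    h.nbr.resize(nc);
    h.wt.resize(nc);
    h.self_loop.assign(nc, 0.0);
    h.strength.assign(nc, 0.0);
    h.two_m = two_m;
    std::vector<double> acc(nc, 0.0);
    std::vector<int> seen;
    std::vector<std::vector<int> > members(nc);
    for (int i = 0; i < g.n; ++i) members[comm[i]].push_back(i);
    for (int c = 0; c < nc; ++c) {
      for (size_t mi = 0; mi < members[c].size(); ++mi) {
        int i = members[c][mi];
        h.self_loop[c] += g.self_loop[i];
        for (size_t p = 0; p < g.nbr[i].size(); ++p) {
          int d = comm[g.nbr[i][p]];
          if (d == c) { h.self_loop[c] += g.wt[i][p]; continue; }
          if (acc[d] == 0.0) seen.push_back(d);
          acc[d] += g.wt[i][p];
        }
      }
      for (size_t t = 0; t < seen.size(); ++t) {
        h.nbr[c].push_back(seen[t]);
        h.wt[c].push_back(acc[seen[t]]);
        acc[seen[t]] = 0.0;
      }
      seen.clear();
    }
    for (int c = 0; c < nc; ++c) {
      double s = h.self_loop[c];
      for (size_t p = 0; p < h.wt[c].size(); ++p) s += h.wt[c][p];
      h.strength[c] = s;
    }
    g = h;
  }
  double q = 0.0;
  for (int c = 0; c < g.n; ++c)
    q += g.self_loop[c] / two_m - (g.strength[c] / two_m) * (g.strength[c] / two_m);
  return q;
}

// best Q over n_runs restarts from one RNG stream (prefix-monotone in n_runs)
inline double louvain_best(const Adj& a, int n_runs, uint64_t seed,
                           std::vector<int>* best_membership) {
  LouvainGraph g = lg_from_adj(a);
  XorShift rng(seed);
  double best_q = -INF;
  std::vector<int> mem;
  for (int r = 0; r < n_runs; ++r) {
    double q = one_louvain_run(g, rng, mem);
    if (q > best_q) {
      best_q = q;
      if (best_membership) *best_membership = mem;
    }
  }
  return best_q;
}

} // namespace scov

#endif
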