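#include <Rcpp.h>
#include <vector>
#include <cstdint>

using namespace Rcpp;

// Greedy multi-level (Louvain-style) maximisation of the linearised Markov
// stability objective
//   F(H) = t * sum_c(in_c) / w2 - sum_c (pi_c)^2
// where in_c counts A_ij over ordered pairs (i,j) in c (self-loops once),
// w2 = total weight over ordered pairs, and pi_i = d_i / w2.  At t = 1 this
// is Newman-Girvan modularity.  The (1 - t) offset of the full objective is
// constant in H and handled by the caller.
//
// Deterministic given `seed`: node visit order is shuffled with an internal
// xorshift generator, never R's RNG.

namespace {

struct XorShift {
  uint64_t s;
  explicit XorShift(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    s ^= s << 13; s ^= s >> 7; s ^= s << 17;
    return s;
  }
  // uniform integer in [0, n)
  int below(int n) { return static_cast<int>(next() % static_cast<uint64_t>(n)); }
};

struct Graph {
  int n;
  double w2;                    // total weight over ordered pairs
  std::vector<std::vector<std::pair<int,double> > > adj; // neighbour, weight
  std::vector<double> self;     // self-loop weight (counted once in in_c)
  std::vector<double> pi;       // node null-model weight, sums to 1
};

// one pass of local moves + aggregation, repeated until no improvement.
// init_groups > 0 seeds the first level with a uniform-random membership
// over that many groups instead of singletons (restart diversity).
IntegerVector louvain_run(const Graph &g0, double t, XorShift &rng,
                          int init_groups) {
  // community-of-origin for each original node
  std::vector<int> membership(g0.n);
  for (int i = 0; i < g0.n; ++i) membership[i] = i;

  Graph g = g0;
  bool improved_any_level = true;
  bool first_level = true;
  const double eps = 1e-12;

  while (improved_any_level) {
    int n = g.n;
    std::vector<int> comm(n);
    std::vector<double> comm_pi(n, 0.0);
    std::vector<int> csize(n, 0);
    if (first_level && init_groups > 0 && init_groups < n) {
      for (int i = 0; i < n; ++i) comm[i] = rng.below(init_groups);
    } else {
      for (int i = 0; i < n; ++i) comm[i] = i;
    }
    first_level = false;
    for (int i = 0; i < n; ++i) { comm_pi[comm[i]] += g.pi[i]; csize[comm[i]] += 1; }

    std::vector<int> order(n);
    for (int i = 0; i < n; ++i) order[i] = i;
    for (int i = n - 1; i > 0; --i) {
      int j = rng.below(i + 1);
      std::swap(order[i], order[j]);
    }

    std::vector<double> w_to_comm(n, 0.0);
    bool moved = true;
    bool any_move = false;
    int sweeps = 0;
    while (moved && sweeps < 200) {
      moved = false;
      ++sweeps;
      for (int oi = 0; oi < n; ++oi) {
        int v = order[oi];
        int cv = comm[v];
        // weights from v to each neighbouring community
        std::vector<int> touched;
        for (size_t e = 0; e < g.adj[v].size(); ++e) {
          int u = g.adj[v][e].first;
          int cu = comm[u];
          if (w_to_comm[cu] == 0.0) touched.push_back(cu);
          w_to_comm[cu] += g.adj[v][e].second;
        }
        // remove v from its community
        comm_pi[cv] -= g.pi[v];
        csize[cv] -= 1;
        // gain of joining community c (relative to standing alone):
        //   t * 2 * w_{v,c} / w2 - 2 * pi_c * pi_v
        double best_gain = t * 2.0 * w_to_comm[cv] / g.w2 -
                           2.0 * comm_pi[cv] * g.pi[v];
        int best_comm = cv;
        for (size_t k = 0; k < touched.size(); ++k) {
          int c = touched[k];
          if (c == cv) continue;
          double gain = t * 2.0 * w_to_comm[c] / g.w2 -
                        2.0 * comm_pi[c] * g.pi[v];
          if (gain > best_gain + eps) { best_gain = gain; best_comm = c; }
        }
        if (best_gain < -eps) {
          // isolating v beats every neighbouring community; reuse an empty label
          for (int c = 0; c < n; ++c) {
            if (csize[c] == 0) { best_comm = c; break; }
          }
        }
        comm_pi[best_comm] += g.pi[v];
        csize[best_comm] += 1;
        if (best_comm != cv) { comm[v] = best_comm; moved = true; any_move = true; }
        for (size_t k = 0; k < touched.size(); ++k) w_to_comm[touched[k]] = 0.0;
        if (w_to_comm[cv] != 0.0) w_to_comm[cv] = 0.0;
      }
    }

    // a randomised first level must still aggregate so that the next level
    // can merge whole groups, even if no single-node move improved
    bool was_random_level = (init_groups > 0 && n == g0.n);
    if (!any_move && !was_random_level) break;

    // relabel communities contiguously
    std::vector<int> relab(n, -1);
    int nc = 0;
    for (int i = 0; i < n; ++i) {
      if (relab[comm[i]] < 0) relab[comm[i]] = nc++;
    }
    for (int i = 0; i < n; ++i) comm[i] = relab[comm[i]];

    // update membership of original nodes
    for (int i = 0; i < g0.n; ++i) membership[i] = comm[membership[i]];

    if (nc == n) break;

    // aggregate graph
    Graph h;
    h.n = nc;
    h.w2 = g.w2;
    h.adj.assign(nc, std::vector<std::pair<int,double> >());
    h.self.assign(nc, 0.0);
    h.pi.assign(nc, 0.0);
    for (int i = 0; i < n; ++i) {
      h.pi[comm[i]] += g.pi[i];
      h.self[comm[i]] += g.self[i];
    }
    // accumulate inter/intra community weights
    std::vector<double> acc(nc, 0.0);
    for (int c = 0; c < nc; ++c) {
      std::vector<int> touched;
      for (int i = 0; i < n; ++i) {
        if (comm[i] != c) continue;
        for (size_t e = 0; e < g.adj[i].size(); ++e) {
          int cu = comm[g.adj[i][e].first];
          if (acc[cu] == 0.0 && (cu != c || true)) touched.push_back(cu);
          acc[cu] += g.adj[i][e].second;
        }
      }
      for (size_t k = 0; k < touched.size(); ++k) {
        int cu = touched[k];
        if (acc[cu] == 0.0) continue;
        if (cu == c) {
          h.self[c] += acc[cu] / 2.0; // each intra edge seen twice
        } else {
          h.adj[c].push_back(std::make_pair(cu, acc[cu]));
        }
        acc[cu] = 0.0;
      }
    }
    g = h;
    improved_any_level = true;
  }

  return wrap(membership);
}

} // namespace

// [[Rcpp::export(name = ".louvain_cpp")]]
IntegerVector louvain_cpp(int n, IntegerVector from, IntegerVector to,
                          NumericVector weight, NumericVector pi,
                          double w2, double t, double seed,
                          int init_groups = 0) {
  Graph g;
  g.n = n;
  g.w2 = w2;
  g.adj.assign(n, std::vector<std::pair<int,double> >());
  g.self.assign(n, 0.0);
  g.pi.assign(n, 0.0);
  for (int i = 0; i < n; ++i) g.pi[i] = pi[i];
  int m = from.size();
  for (int e = 0; e < m; ++e) {
    int a = from[e], b = to[e];
    double w = weight[e];
    if (a == b) { g.self[a] += w; continue; }
    g.adj[a].push_back(std::make_pair(b, w));
    g.adj[b].push_back(std::make_pair(a, w));
  }
  XorShift rng(static_cast<uint64_t>(seed));
  return louvain_run(g, t, rng, init_groups);
}
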