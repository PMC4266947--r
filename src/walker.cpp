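#include <Rcpp.h>
#include <cstdint>
#include <vector>
using namespace Rcpp;

// Self-contained counter-based RNG (splitmix64): every walker gets its own
// stream keyed by (seed, walker index, retry attempt), so estimates are
// bit-reproducible for a fixed seed and changing the number of walkers never
// correlates streams. R's own RNG state is untouched.
static inline uint64_t splitmix64(uint64_t& s) {
  s += 0x9E3779B97F4A7C15ULL;
  uint64_t z = s;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

static inline double unif01(uint64_t& s) {
  return (splitmix64(s) >> 11) * (1.0 / 9007199254740992.0); /* 2^-53 */
}

static inline uint64_t stream_seed(uint64_t seed, uint64_t walker,
                                   uint64_t attempt) {
  uint64_t s = seed * 0xD1B54A32D192ED03ULL + walker * 0x8CB92BA72F3D8DD7ULL +
               attempt * 0x2545F4914F6CDD1DULL;
  // warm up so nearby keys decorrelate
  splitmix64(s);
  splitmix64(s);
  return s;
}

// Signed random walkers implementing Aldous' first-entrance spanning-tree
// sampling. Each walker: starts at the reference with sign +1; repeatedly
// picks an incident edge with probability proportional to its traversal
// weight (direction and sign ignored); traversing a negative edge flips its
// sign; at a first entrance the node is marked with the walker's sign and the
// edge joins the tree; at a re-entry the walker adopts the node's stored
// sign; the walk stops when all nodes are visited. The first-entrance edges
// form a spanning tree, uniform over all spanning trees when weights are
// equal.
//
// eu, ev: 0-based endpoints; esign: -1/+1; ew: positive traversal weights;
// ref: 0-based reference node. Returns per-node positive/negative visit
// counts, per-walker step counts, and (if collect) the tree edge indices
// (1-based) and node signs per walker.
// [[Rcpp::export]]
List cpp_run_walkers(int n_nodes, IntegerVector eu, IntegerVector ev,
                     IntegerVector esign, NumericVector ew, int ref,
                     int n_walkers, double seed, double max_steps,
                     bool collect, int max_retries) {
  const int m = eu.size();
  // incident edge lists
  std::vector<std::vector<int> > inc(n_nodes);
  for (int k = 0; k < m; ++k) {
    inc[eu[k]].push_back(k);
    inc[ev[k]].push_back(k);
  }
  std::vector<std::vector<double> > cumw(n_nodes);
  for (int v = 0; v < n_nodes; ++v) {
    double acc = 0.0;
    cumw[v].reserve(inc[v].size());
    for (size_t j = 0; j < inc[v].size(); ++j) {
      acc += ew[inc[v][j]];
      cumw[v].push_back(acc);
    }
  }

  IntegerVector n_plus(n_nodes), n_minus(n_nodes);
  NumericVector steps_out(n_walkers);
  IntegerMatrix trees, signs_out;
  if (collect) {
    trees = IntegerMatrix(n_walkers, n_nodes > 0 ? n_nodes - 1 : 0);
    signs_out = IntegerMatrix(n_walkers, n_nodes);
  }

  std::vector<int> node_sign(n_nodes), entry_edge(n_nodes);
  std::vector<char> visited(n_nodes);
  const uint64_t useed = (uint64_t)(int64_t)seed;

  for (int w = 0; w < n_walkers; ++w) {
    bool done = false;
    for (int attempt = 0; attempt <= max_retries && !done; ++attempt) {
      uint64_t rng = stream_seed(useed, (uint64_t)w + 1, (uint64_t)attempt);
      std::fill(visited.begin(), visited.end(), 0);
      int cur = ref, sign = 1, nvis = 1;
      visited[ref] = 1;
      node_sign[ref] = 1;
      double steps = 0.0;
      bool failed = false;
      while (nvis < n_nodes) {
        if (steps >= max_steps) { failed = true; break; }
        const std::vector<double>& cw = cumw[cur];
        const double total = cw.back();
        const double r = unif01(rng) * total;
        size_t lo = 0, hi = cw.size() - 1;
        while (lo < hi) {
          size_t mid = (lo + hi) / 2;
          if (cw[mid] > r) hi = mid; else lo = mid + 1;
        }
        const int e = inc[cur][lo];
        const int nxt = (eu[e] == cur) ? ev[e] : eu[e];
        const int s_arrive = sign * esign[e];
        if (!visited[nxt]) {
          visited[nxt] = 1;
          node_sign[nxt] = s_arrive;
          entry_edge[nxt] = e;
          ++nvis;
          sign = s_arrive;
        } else {
          sign = node_sign[nxt];
        }
        cur = nxt;
        steps += 1.0;
      }
      if (failed) continue;
      done = true;
      steps_out[w] = steps;
      int col = 0;
      for (int v = 0; v < n_nodes; ++v) {
        if (node_sign[v] > 0) ++n_plus[v]; else ++n_minus[v];
        if (collect) {
          signs_out(w, v) = node_sign[v];
          if (v != ref) trees(w, col++) = entry_edge[v] + 1; /* 1-based */
        }
      }
    }
    if (!done)
      stop("walker %d exceeded max_steps (%.0f) in all %d attempt(s): "
           "cover time too large; check connectivity or traversal weights",
           w + 1, max_steps, max_retries + 1);
  }

  List out = List::create(_["n_plus"] = n_plus, _["n_minus"] = n_minus,
                          _["steps"] = steps_out);
  if (collect) {
    out["trees"] = trees;
    out["signs"] = signs_out;
  }
  return out;
}
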