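#include <Rcpp.h>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

// Adaptive context model with PPM method-C style escape counts and full
// blending: at each order k the next-symbol probability is
//   P_k(x) = c_k(x) / (n_k + d_k) + d_k / (n_k + d_k) * P_{k-1}(x)
// down to P_{-1}(x) = 1 / alphabet, so probabilities sum to one exactly at
// every position. Code length is the ideal arithmetic-coding length
// sum_t -log2 P(x_t | context).

struct Node {
  std::unordered_map<int, int> children;  // symbol -> node index (context trie)
  std::unordered_map<int, int> counts;    // successor symbol -> count
  long total = 0;
};

// [[Rcpp::export(name = ".ppm_bits_cpp")]]
List ppm_bits_cpp(IntegerVector x, int alphabet, int order,
                  double node_budget, bool per_position) {
  const int n = x.size();
  if (alphabet < 1) stop("alphabet must be >= 1");
  if (order < 0) stop("order must be >= 0");
  std::vector<Node> nodes;
  nodes.reserve(1024);
  nodes.emplace_back();  // root = order-0 context
  const double budget = node_budget > 0 ? node_budget : 1e18;
  bool frozen = false;

  NumericVector pp(per_position ? n : 0);
  double bits = 0.0;
  std::vector<int> path(order + 1);

  for (int t = 0; t < n; ++t) {
    const int sym = x[t];
    if (sym < 0 || sym >= alphabet) stop("symbol id out of alphabet range");
    // walk the context trie: path[k] = node for the order-k context
    int depth = 0;
    path[0] = 0;
    for (int k = 1; k <= order && k <= t; ++k) {
      const int ctx_sym = x[t - k];
      Node &par = nodes[path[k - 1]];
      auto it = par.children.find(ctx_sym);
      int idx;
      if (it != par.children.end()) {
        idx = it->second;
      } else if (!frozen) {
        idx = (int)nodes.size();
        nodes.emplace_back();
        nodes[path[k - 1]].children.emplace(ctx_sym, idx);
        if ((double)nodes.size() >= budget) frozen = true;
      } else {
        break;  // memory cap reached: deeper contexts unavailable
      }
      path[k] = idx;
      depth = k;
    }
    // blend from order -1 upward
    double p = 1.0 / alphabet;
    for (int k = 0; k <= depth; ++k) {
      Node &nd = nodes[path[k]];
      const long d = (long)nd.counts.size();
      if (nd.total == 0) continue;  // unseen context: escape with prob 1
      const double denom = (double)(nd.total + d);
      auto it = nd.counts.find(sym);
      const double c = (it == nd.counts.end()) ? 0.0 : (double)it->second;
      p = c / denom + ((double)d / denom) * p;
    }
    const double b = -std::log2(p);
    bits += b;
    if (per_position) pp[t] = b;
    // update counts at all reachable orders
    for (int k = 0; k <= depth; ++k) {
      Node &nd = nodes[path[k]];
      nd.counts[sym] += 1;
      nd.total += 1;
    }
  }
  return List::create(_["bits"] = bits, _["per_position"] = pp,
                      _["nodes"] = (double)nodes.size(), _["frozen"] = frozen);
}

// Shift-circulant Markov sampler: the distribution of the next symbol is the
// base weight vector p cyclically shifted by the sum of the last `order`
// symbols (mod vocab). The stationary law over length-`order` histories is
// uniform, so the per-symbol entropy rate equals H(p) in closed form.
// Uses R's RNG so set.seed() governs reproducibility.

// [[Rcpp::export(name = ".markov_sample_cpp")]]
IntegerVector markov_sample_cpp(int n, NumericVector p, int order) {
  const int V = p.size();
  if (V < 1) stop("empty weight vector");
  std::vector<double> cum(V);
  double s = 0.0;
  for (int j = 0; j < V; ++j) { s += p[j]; cum[j] = s; }
  if (std::abs(s - 1.0) > 1e-8) stop("weights must sum to 1");
  IntegerVector out(n);
  RNGScope scope;
  int shift = 0;
  std::vector<int> hist;
  for (int t = 0; t < n; ++t) {
    if (order > 0) {
      shift = 0;
      const int m = std::min<int>(order, (int)hist.size());
      for (int k = 1; k <= m; ++k) shift += hist[hist.size() - k];
      shift %= V;
    }
    const double u = unif_rand() * s;
    int j = (int)(std::lower_bound(cum.begin(), cum.end(), u) - cum.begin());
    if (j >= V) j = V - 1;
    const int sym = (j + shift) % V;
    out[t] = sym;
    if (order > 0) hist.push_back(sym);
  }
  return out;
}
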