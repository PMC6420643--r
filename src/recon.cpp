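// Bulk lineage-tree reconstruction core.
//
// Works on the samples x edits incidence matrix. Sets of samples/edits are
// kept as 64-bit bitsets so that the iterative clade decomposition (detach the
// Poisson-binomial top edit, recompute components, recurse) stays fast enough
// to sit inside simulation sweeps. The R-level functions find_clades(),
// detection_rate() and select_top_node() implement the same rules and serve
// as the cross-checked reference.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>
using namespace Rcpp;

typedef std::vector<uint64_t> Bits;

static inline int popcnt(uint64_t x) {
#if defined(__GNUC__) || defined(__clang__)
  return __builtin_popcountll(x);
#else
  int c = 0; while (x) { x &= x - 1; ++c; } return c;
#endif
}

static inline int count_bits(const Bits &a) {
  int c = 0;
  for (uint64_t w : a) c += popcnt(w);
  return c;
}

static inline int count_and(const Bits &a, const Bits &b) {
  int c = 0;
  for (size_t i = 0; i < a.size(); ++i) c += popcnt(a[i] & b[i]);
  return c;
}

static inline bool any_and(const Bits &a, const Bits &b) {
  for (size_t i = 0; i < a.size(); ++i) if (a[i] & b[i]) return true;
  return false;
}

static inline void set_bit(Bits &a, int i) { a[i >> 6] |= (uint64_t(1) << (i & 63)); }
static inline void clear_bit(Bits &a, int i) { a[i >> 6] &= ~(uint64_t(1) << (i & 63)); }
static inline bool get_bit(const Bits &a, int i) {
  return (a[i >> 6] >> (i & 63)) & 1;
}

// Truncated Poisson-binomial CDF: P(X <= k) over `probs`, O(n * k) DP.
static double pb_cdf_trunc(const std::vector<double> &probs, int k) {
  std::vector<double> dp(k + 1, 0.0);
  dp[0] = 1.0;
  int filled = 0;
  for (double p : probs) {
    int hi = std::min(filled + 1, k);
    for (int j = hi; j >= 1; --j) dp[j] = dp[j] * (1.0 - p) + dp[j - 1] * p;
    dp[0] *= (1.0 - p);
    filled = hi;
  }
  double s = 0.0;
  for (int j = 0; j <= k; ++j) s += dp[j];
  if (s > 1.0) s = 1.0;
  return s;
}

// Same quantity computed from whichever tail is shorter: for k > n/2 run the
// DP over failure counts (P(X <= k) = 1 - P(F <= n-k-1) with F = failures).
static double pb_cdf_fast(const std::vector<double> &probs, int k) {
  const int n = (int)probs.size();
  if (k >= n) return 1.0;
  if (k + 1 <= n - k) return pb_cdf_trunc(probs, k);
  std::vector<double> q(probs);
  for (double &p : q) p = 1.0 - p;
  double upper = pb_cdf_trunc(q, n - k - 1);  // P(F <= n-k-1) = P(X >= k+1)
  double s = 1.0 - upper;
  if (s < 0.0) s = 0.0;
  return s;
}

// [[Rcpp::export]]
List recon_core(LogicalMatrix inc, double min_overlap, IntegerVector tie_rank) {
  const int S = inc.nrow(), E = inc.ncol();
  const int wS = (S + 63) / 64, wE = (E + 63) / 64;

  std::vector<Bits> bar(S, Bits(wE, 0)), expr(E, Bits(wS, 0));
  std::vector<int> n_bar(S, 0);
  for (int s = 0; s < S; ++s)
    for (int e = 0; e < E; ++e)
      if (inc(s, e)) { set_bit(bar[s], e); set_bit(expr[e], s); ++n_bar[s]; }
  for (int s = 0; s < S; ++s) n_bar[s] = count_bits(bar[s]);

  // --- first ancestor (root) sample ---------------------------------------
  int root = -1;
  for (int s = 0; s < S; ++s) if (n_bar[s] == 0) { root = s; break; }
  if (root < 0) {
    std::vector<int> deg(S, 0);
    for (int s = 0; s < S; ++s)
      for (int t = s + 1; t < S; ++t)
        if (any_and(bar[s], bar[t])) { ++deg[s]; ++deg[t]; }
    root = 0;
    for (int s = 1; s < S; ++s) {
      if (deg[s] > deg[root] ||
          (deg[s] == deg[root] && n_bar[s] < n_bar[root])) root = s;
    }
  }
  for (int e = 0; e < E; ++e) clear_bit(expr[e], root);
  std::vector<int> n_exp(E, 0);
  for (int e = 0; e < E; ++e) n_exp[e] = count_bits(expr[e]);

  // --- edit graph: co-observation + Jaccard-retained edges ----------------
  std::vector<Bits> adjAll(E, Bits(wE, 0)), adjRet(E, Bits(wE, 0));
  for (int e = 0; e < E; ++e) {
    if (n_exp[e] == 0) continue;
    for (int f = e + 1; f < E; ++f) {
      if (n_exp[f] == 0) continue;
      int c = count_and(expr[e], expr[f]);
      if (c == 0) continue;
      set_bit(adjAll[e], f); set_bit(adjAll[f], e);
      double jac = double(c) / double(n_exp[e] + n_exp[f] - c);
      if (jac >= min_overlap) { set_bit(adjRet[e], f); set_bit(adjRet[f], e); }
    }
  }

  // --- iterative clade decomposition --------------------------------------
  std::vector<int> edit_parent(E, -1);
  std::vector<int> assign_order; assign_order.reserve(E);

  // connected components of `members` under retained edges
  auto components = [&](const std::vector<int> &members) {
    std::vector<std::vector<int> > comps;
    Bits mask(wE, 0);
    for (int e : members) set_bit(mask, e);
    std::vector<char> seen(E, 0);
    for (int e : members) {
      if (seen[e]) continue;
      std::vector<int> comp, stack;
      stack.push_back(e); seen[e] = 1;
      while (!stack.empty()) {
        int u = stack.back(); stack.pop_back();
        comp.push_back(u);
        for (int w = 0; w < wE; ++w) {
          uint64_t bitsw = adjRet[u][w] & mask[w];
          while (bitsw) {
            int v = w * 64 + __builtin_ctzll(bitsw);
            bitsw &= bitsw - 1;
            if (!seen[v]) { seen[v] = 1; stack.push_back(v); }
          }
        }
      }
      std::sort(comp.begin(), comp.end());
      comps.push_back(comp);
    }
    return comps;
  };

  struct Task { std::vector<int> members; int parent; };
  std::vector<Task> work;
  {
    std::vector<int> act;
    for (int e = 0; e < E; ++e) if (n_exp[e] > 0) act.push_back(e);
    for (auto &comp : components(act)) work.push_back(Task{comp, -1});
  }

  Bits uexp(wS, 0);
  while (!work.empty()) {
    Task task = work.back(); work.pop_back();
    std::vector<int> &comp = task.members;
    const int csz = (int)comp.size();
    if (csz == 1) {
      edit_parent[comp[0]] = task.parent;
      assign_order.push_back(comp[0]);
      continue;
    }
    Bits mask(wE, 0);
    for (int e : comp) set_bit(mask, e);
    const int m = csz - 1;  // potential connections per candidate

    // pass 1: candidates co-observed with every clade mate score exactly 1
    int top = -1;
    for (int x : comp) {
      int k = 0;
      for (int w = 0; w < wE; ++w) k += popcnt(adjAll[x][w] & mask[w]);
      if (k == m) {
        if (top < 0 || n_exp[x] > n_exp[top] ||
            (n_exp[x] == n_exp[top] && tie_rank[x] < tie_rank[top])) top = x;
      }
    }
    if (top < 0) {
      // pass 2: Poisson-binomial scoring at the observed degree. The argmax
      // is computed exactly but lazily: each candidate first gets a cheap
      // Chernoff upper bound exp(-(mu - k)^2 / (2 mu)) on P(X <= k); exact
      // DP evaluation proceeds in decreasing bound order and stops once no
      // remaining bound can beat the best exact score. px == 1 with k < m
      // gives a CDF of exactly 0 without a DP.
      struct Cand { int x; int k; double px; double bound; };
      std::vector<Cand> cands;
      cands.reserve(csz);
      for (int x : comp) {
        int k = 0;
        uexp.assign(wS, 0);
        for (int w = 0; w < wE; ++w) {
          uint64_t bitsw = adjAll[x][w] & mask[w];
          while (bitsw) {
            int y = w * 64 + __builtin_ctzll(bitsw);
            bitsw &= bitsw - 1;
            ++k;
            for (int v = 0; v < wS; ++v) uexp[v] |= expr[y][v];
          }
        }
        if (k == 0) continue;  // isolated under co-observation: skip
        int n_c = count_bits(uexp);
        int n_xc = count_and(expr[x], uexp);
        double px = n_c > 0 ? double(n_xc) / double(n_c) : 0.0;
        cands.push_back(Cand{x, k, px, 1.0});
      }
      // Within a group of equal expressing-set size the score is strictly
      // decreasing in px and increasing in k (same success-prob multiset),
      // so only the (px asc, k desc) Pareto frontier can win the argmax.
      std::sort(cands.begin(), cands.end(), [&](const Cand &a, const Cand &b) {
        if (n_exp[a.x] != n_exp[b.x]) return n_exp[a.x] > n_exp[b.x];
        if (a.px != b.px) return a.px < b.px;
        if (a.k != b.k) return a.k > b.k;
        return tie_rank[a.x] < tie_rank[b.x];
      });
      {
        std::vector<Cand> frontier;
        frontier.reserve(cands.size());
        int cur_n = -1, maxk = -1;
        for (const Cand &c : cands) {
          if (n_exp[c.x] != cur_n) { cur_n = n_exp[c.x]; maxk = -1; }
          if (c.k > maxk) { frontier.push_back(c); maxk = c.k; }
        }
        cands.swap(frontier);
      }
      for (Cand &c : cands) {
        if (c.px >= 1.0) { c.bound = 0.0; continue; }
        double mu = 0.0;
        for (int y : comp) if (y != c.x)
          mu += 1.0 - std::pow(1.0 - c.px, double(n_exp[y]));
        c.bound = (double(c.k) >= mu) ? 1.0
          : std::exp(-(mu - double(c.k)) * (mu - double(c.k)) / (2.0 * mu));
      }
      std::sort(cands.begin(), cands.end(), [&](const Cand &a, const Cand &b) {
        if (a.bound != b.bound) return a.bound > b.bound;
        if (n_exp[a.x] != n_exp[b.x]) return n_exp[a.x] > n_exp[b.x];
        return tie_rank[a.x] < tie_rank[b.x];
      });
      double best = -1.0;
      for (const Cand &c : cands) {
        if (top >= 0 && c.bound < best) break;
        double score;
        if (c.px >= 1.0) {
          score = 0.0;
        } else {
          std::vector<double> probs;
          probs.reserve(m);
          for (int y : comp) if (y != c.x)
            probs.push_back(1.0 - std::pow(1.0 - c.px, double(n_exp[y])));
          score = pb_cdf_fast(probs, c.k);
        }
        if (top < 0 || score > best ||
            (score == best && (n_exp[c.x] > n_exp[top] ||
             (n_exp[c.x] == n_exp[top] && tie_rank[c.x] < tie_rank[top])))) {
          top = c.x; best = score;
        }
      }
      if (top < 0) top = comp[0];  // fully disconnected clade: first edit
    }

    edit_parent[top] = task.parent;
    assign_order.push_back(top);
    std::vector<int> rest;
    rest.reserve(csz - 1);
    for (int e : comp) if (e != top) rest.push_back(e);
    for (auto &sub : components(rest)) work.push_back(Task{sub, top});
  }

  // isolated edits (expressed nowhere outside the root) hang off the virtual root
  for (int e = 0; e < E; ++e)
    if (n_exp[e] == 0) assign_order.push_back(e);

  // --- ancestor chains -----------------------------------------------------
  std::vector<Bits> anc(E, Bits(wE, 0));
  std::vector<int> chain_len(E, 0);
  for (int e : assign_order) {
    int p = edit_parent[e];
    if (p >= 0) anc[e] = anc[p];
    else anc[e].assign(wE, 0);
    set_bit(anc[e], e);
    chain_len[e] = (p >= 0 ? chain_len[p] : 0) + 1;
  }

  // --- sample placement: maximal Jaccard with an ancestor chain -----------
  std::vector<int> placed(S, -1);
  for (int s = 0; s < S; ++s) {
    if (s == root || n_bar[s] == 0) continue;
    double best = -1.0; int best_e = -1;
    for (int e = 0; e < E; ++e) {
      int inter = count_and(bar[s], anc[e]);
      int uni = n_bar[s] + chain_len[e] - inter;
      double jac = uni > 0 ? double(inter) / double(uni) : 0.0;
      if (best_e < 0 || jac > best ||
          (jac == best && (chain_len[e] < chain_len[best_e] ||
           (chain_len[e] == chain_len[best_e] && tie_rank[e] < tie_rank[best_e])))) {
        best = jac; best_e = e;
      }
    }
    placed[s] = best_e;
  }

  // --- sample parent links: maximal sharing with an ancestral barcode ------
  // Mother-daughter assignment follows how much of a candidate ancestor's
  // barcode combination a node shares: among samples of the same clade with
  // smaller barcodes (ties broken by index, keeping the order strict and the
  // links acyclic), the parent maximizes |B_t intersect B_s| / |B_t|, ties
  // toward the larger (nearer) ancestor barcode, then the smaller index.
  // Samples without a qualifying ancestor attach to the root sample.
  std::vector<int> sample_parent(S, -1);
  for (int s = 0; s < S; ++s) {
    if (s == root) { sample_parent[s] = -1; continue; }
    int par = root;
    if (placed[s] >= 0) {
      double best = -1.0;
      int best_nbar = -1;
      const Bits &chain = anc[placed[s]];
      for (int t = 0; t < S; ++t) {
        if (t == s || t == root || n_bar[t] == 0) continue;
        if (placed[t] < 0 || !get_bit(chain, placed[t])) continue;
        if (n_bar[t] > n_bar[s] || (n_bar[t] == n_bar[s] && t > s)) continue;
        double sc = double(count_and(bar[t], bar[s])) / double(n_bar[t]);
        if (sc <= 0.0) continue;
        if (sc > best || (sc == best && (n_bar[t] > best_nbar ||
            (n_bar[t] == best_nbar && t < par)))) {
          best = sc; par = t; best_nbar = n_bar[t];
        }
      }
    }
    sample_parent[s] = par;
  }

  return List::create(_["root"] = root,
                      _["edit_parent"] = IntegerVector(edit_parent.begin(), edit_parent.end()),
                      _["placed"] = IntegerVector(placed.begin(), placed.end()),
                      _["sample_parent"] = IntegerVector(sample_parent.begin(), sample_parent.end()));
}
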