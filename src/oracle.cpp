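// Exhaustive backtracking over link-edge subsets of a scaffold graph.
//
// Vertices are 0..2n-1 where matching edge i covers {2i, 2i+1}. A solution
// is a set of link edges with all vertices of link-degree <= 1 whose union
// with the matching splits into alternating paths and cycles. The search
// picks the smallest unresolved vertex and branches on: every link edge at
// it (merging two path components, or closing one into a cycle), or leaving
// it as a path extremity. Each full solution is therefore enumerated exactly
// once. Modes: 0 = feasibility (early exit), 1 = maximum weight for an exact
// (sigma_p, sigma_c) with optional branch-and-bound that only discards
// strictly non-improving branches, 2 = profile (achievable (paths, cycles)
// pairs with solution counts).
#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

namespace {

struct Search {
  int n_me = 0, nv = 0, m = 0;
  std::vector<std::vector<std::pair<int, int> > > adj;  // vertex -> (other, edge)
  std::vector<double> w;
  std::vector<double> wprefix;  // descending prefix sums, length m+1
  int sigma_p = 0, sigma_c = 0, mode = 0;
  bool prune_w = true;
  double nodes = 0, node_cap = 0;
  bool aborted = false;

  std::vector<char> sat, fin;
  std::vector<int> other;
  std::vector<int> chosen;
  int p = 0, c = 0, open_total = 0, open_both = 0, open_half = 0;
  double cur_w = 0;

  bool found = false;
  double best_w = R_NegInf;
  std::vector<int> best_edges;
  double count_exact = 0;
  std::vector<double> profile;  // (n_me+1) x (n_me/2+1), column-major in p

  void record() {
    if (mode == 2) {
      profile[p + (n_me + 1) * c] += 1.0;
      return;
    }
    if (p != sigma_p || c != sigma_c) return;
    count_exact += 1.0;
    found = true;
    if (mode == 1 && cur_w > best_w + 1e-12) {
      best_w = cur_w;
      best_edges = chosen;
    }
  }

  bool prune() const {
    if (mode == 2) return false;
    if (p > sigma_p || c > sigma_c) return true;
    if (p + open_total < sigma_p) return true;
    if (c + open_both < sigma_c) return true;
    // a component with one finalized extremity can only end as a path
    // (two of them may merge into one)
    if (p + (open_half + 1) / 2 > sigma_p) return true;
    if (mode == 0 && found) return true;
    if (mode == 1 && prune_w && found) {
      int slots = (n_me - sigma_p) - static_cast<int>(chosen.size());
      if (slots < 0) return true;
      double ub = cur_w + wprefix[std::min(slots, m)];
      if (ub < best_w - 1e-9) return true;
    }
    return false;
  }

  void rec(int start) {
    if (aborted) return;
    if (++nodes > node_cap) { aborted = true; return; }
    if (prune()) return;
    int v = -1;
    for (int i = start; i < nv; ++i) {
      if (!sat[i] && !fin[i]) { v = i; break; }
    }
    if (v < 0) { record(); return; }
    for (size_t k = 0; k < adj[v].size(); ++k) {
      int u = adj[v][k].first, e = adj[v][k].second;
      if (sat[u] || fin[u]) continue;
      if (u == other[v]) {
        if (mode != 2 && c >= sigma_c) continue;
        sat[v] = sat[u] = 1; chosen.push_back(e); cur_w += w[e];
        ++c; --open_total; --open_both;
        rec(v + 1);
        --c; ++open_total; ++open_both;
        sat[v] = sat[u] = 0; chosen.pop_back(); cur_w -= w[e];
      } else {
        int x = other[v], y = other[u];
        int before = (!fin[x]) + (!fin[y]);
        int after = (!fin[x] && !fin[y]) ? 1 : 0;
        // joining two components whose far ends are both finalized
        // completes a path right away
        int done = (fin[x] && fin[y]) ? 1 : 0;
        int half_before = (fin[x] ? 1 : 0) + (fin[y] ? 1 : 0) - 2 * done;
        int half_after = (done || after) ? 0 : 1;
        sat[v] = sat[u] = 1; chosen.push_back(e); cur_w += w[e];
        other[x] = y; other[y] = x;
        open_total -= 1 + done; open_both += after - before;
        open_half += half_after - half_before;
        p += done;
        rec(v + 1);
        p -= done;
        open_half -= half_after - half_before;
        open_total += 1 + done; open_both -= after - before;
        other[x] = v; other[y] = u;
        sat[v] = sat[u] = 0; chosen.pop_back(); cur_w -= w[e];
      }
      if (aborted) return;
      if (mode == 0 && found) return;
    }
    int wv = other[v];
    fin[v] = 1;
    bool complete = fin[wv] != 0;
    if (complete) { ++p; --open_total; --open_half; }
    else { --open_both; ++open_half; }
    rec(v + 1);
    if (complete) { --p; ++open_total; ++open_half; }
    else { ++open_both; --open_half; }
    fin[v] = 0;
  }
};

}  // namespace

// [[Rcpp::export]]
List oracle_search_cpp(int n_me, IntegerMatrix links, NumericVector weights,
                       IntegerVector forced, int sigma_p, int sigma_c,
                       int mode, bool prune_weight, double node_cap) {
  Search S;
  S.n_me = n_me;
  S.nv = 2 * n_me;
  S.m = links.nrow();
  S.sigma_p = sigma_p;
  S.sigma_c = sigma_c;
  S.mode = mode;
  S.prune_w = prune_weight;
  S.node_cap = node_cap;
  S.w.assign(weights.begin(), weights.end());
  S.adj.assign(S.nv, std::vector<std::pair<int, int> >());
  for (int e = 0; e < S.m; ++e) {
    int a = links(e, 0), b = links(e, 1);
    S.adj[a].push_back(std::make_pair(b, e));
    S.adj[b].push_back(std::make_pair(a, e));
  }
  for (int v = 0; v < S.nv; ++v) std::sort(S.adj[v].begin(), S.adj[v].end());
  std::vector<double> ws(S.w);
  std::sort(ws.begin(), ws.end(), std::greater<double>());
  S.wprefix.assign(S.m + 1, 0.0);
  for (int i = 0; i < S.m; ++i) S.wprefix[i + 1] = S.wprefix[i] + ws[i];

  S.sat.assign(S.nv, 0);
  S.fin.assign(S.nv, 0);
  S.other.resize(S.nv);
  for (int i = 0; i < n_me; ++i) {
    S.other[2 * i] = 2 * i + 1;
    S.other[2 * i + 1] = 2 * i;
  }
  S.open_total = n_me;
  S.open_both = n_me;
  S.profile.assign((n_me + 1) * (n_me / 2 + 1), 0.0);

  // pre-apply the forced partial solution
  bool forced_ok = true;
  for (int i = 0; i < forced.size() && forced_ok; ++i) {
    int e = forced[i];
    int a = links(e, 0), b = links(e, 1);
    if (S.sat[a] || S.sat[b]) { forced_ok = false; break; }
    if (S.other[a] == b) {
      S.sat[a] = S.sat[b] = 1;
      ++S.c; --S.open_total; --S.open_both;
    } else {
      int x = S.other[a], y = S.other[b];
      S.sat[a] = S.sat[b] = 1;
      S.other[x] = y; S.other[y] = x;
      --S.open_total; --S.open_both;  // both comps were both-free, result is
    }
    S.chosen.push_back(e);
    S.cur_w += S.w[e];
  }
  if (forced_ok) S.rec(0);

  int np = S.n_me + 1, nc = S.n_me / 2 + 1;
  NumericMatrix prof(np, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < np; ++i) prof(i, j) = S.profile[i + np * j];
  }
  return List::create(
      _["feasible"] = S.found,
      _["best_weight"] = S.best_w,
      _["witness"] = IntegerVector(S.best_edges.begin(), S.best_edges.end()),
      _["count"] = S.count_exact,
      _["profile"] = prof,
      _["nodes"] = S.nodes,
      _["aborted"] = S.aborted,
      _["forced_ok"] = forced_ok);
}
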