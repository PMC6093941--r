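// Greedy structural-entropy minimization over height-2 coding trees.
//
// Vertices start as singleton modules under the root; the merge with the
// largest positive entropy gain is applied until no merge helps.  Candidate
// pairs are modules connected by at least one edge (a merge of a
// disconnected pair can never gain at the first level) and, in adjacent
// mode, only genomically neighboring modules.  A max-heap keyed by the gain
// with lazy invalidation (per-module version stamps) keeps each step near
// O(log n) on sparse graphs.

#include <Rcpp.h>
#include <queue>
#include <unordered_map>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct Cand {
  double delta;
  double wab;      // inter-module weight at push time (valid while stamps hold)
  int a, b;        // module roots at push time
  int va, vb;      // version stamps
  int lo, hi;      // tie keys: smaller marker min index, then partner's
};

struct CandLess {
  bool operator()(const Cand &x, const Cand &y) const {
    if (x.delta != y.delta) return x.delta < y.delta;
    if (x.lo != y.lo) return x.lo > y.lo;
    return x.hi > y.hi;
  }
};

inline double se_term(double g, double V, double Vp, double two_w) {
  if (g <= 0.0 || V <= 0.0 || V >= Vp) return 0.0;
  return -(g / two_w) * std::log2(V / Vp);
}

struct Greedy {
  int n;
  double two_w;
  std::vector<double> V, g, d;
  std::vector<int> minidx, version, parent, left, right;
  std::vector<bool> alive;
  std::vector<std::unordered_map<int, double>> nbr;
  std::priority_queue<Cand, std::vector<Cand>, CandLess> heap;
  bool adjacent;

  int find(int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  }

  // entropy gain of merging live roots a and b joined by weight wab
  double delta_of(int a, int b, double wab) const {
    double ga = g[a], gb = g[b], Va = V[a], Vb = V[b];
    double gm = ga + gb - 2.0 * wab, Vm = Va + Vb;
    double mod_diff = se_term(ga, Va, two_w, two_w) + se_term(gb, Vb, two_w, two_w)
                    - se_term(gm, Vm, two_w, two_w);
    double leaf_diff = 0.0;
    if (Va > 0.0 && Vm > 0.0) leaf_diff += Va * std::log2(Va / Vm);
    if (Vb > 0.0 && Vm > 0.0) leaf_diff += Vb * std::log2(Vb / Vm);
    return mod_diff + leaf_diff / two_w;
  }

  void push_cand(int a, int b, double wab) {
    double dl = delta_of(a, b, wab);
    if (dl <= 0.0) return;
    Cand c;
    c.delta = dl; c.wab = wab;
    c.a = a; c.b = b; c.va = version[a]; c.vb = version[b];
    c.lo = std::min(minidx[a], minidx[b]);
    c.hi = std::max(minidx[a], minidx[b]);
    heap.push(c);
  }

  bool valid(const Cand &c) {
    return alive[c.a] && alive[c.b] &&
           version[c.a] == c.va && version[c.b] == c.vb;
  }
};

} // namespace

// [[Rcpp::export(name = ".greedy_merge_cpp")]]
List greedy_merge_cpp(int n, NumericVector degree, NumericVector g0,
                      double total_weight,
                      IntegerVector ei, IntegerVector ej, NumericVector ew,
                      bool adjacent) {
  Greedy S;
  S.n = n;
  S.two_w = 2.0 * total_weight;
  S.adjacent = adjacent;
  S.V.assign(degree.begin(), degree.end());
  S.g.assign(g0.begin(), g0.end());
  S.d.assign(degree.begin(), degree.end());
  S.minidx.resize(n); S.version.assign(n, 0); S.parent.resize(n);
  S.left.resize(n); S.right.resize(n);
  S.alive.assign(n, true);
  S.nbr.resize(n);
  for (int i = 0; i < n; ++i) {
    S.minidx[i] = i; S.parent[i] = i;
    S.left[i] = i - 1; S.right[i] = (i + 1 < n) ? i + 1 : -1;
  }
  int m = ei.size();
  for (int e = 0; e < m; ++e) {
    int i = ei[e], j = ej[e];
    double w = ew[e];
    if (i == j || w == 0.0) continue;
    S.nbr[i][j] += w;
    S.nbr[j][i] += w;
  }

  // initial candidates
  if (adjacent) {
    for (int i = 0; i + 1 < n; ++i) {
      auto it = S.nbr[i].find(i + 1);
      double wab = (it == S.nbr[i].end()) ? 0.0 : it->second;
      S.push_cand(i, i + 1, wab);
    }
  } else {
    for (int i = 0; i < n; ++i)
      for (auto &kv : S.nbr[i])
        if (kv.first > i) S.push_cand(i, kv.first, kv.second);
  }

  std::vector<double> deltas;
  while (!S.heap.empty()) {
    Cand c = S.heap.top(); S.heap.pop();
    if (!S.valid(c)) continue;
    int a = c.a, b = c.b;
    double wab = c.wab;
    deltas.push_back(c.delta);

    // representative: keep the larger neighbor map
    int rep = (S.nbr[a].size() >= S.nbr[b].size()) ? a : b;
    int oth = (rep == a) ? b : a;
    // genomic span endpoints before relinking
    int leftmost  = (S.minidx[a] < S.minidx[b]) ? a : b;
    int rightmost = (leftmost == a) ? b : a;
    int L = S.left[leftmost], R = S.right[rightmost];

    S.V[rep] = S.V[a] + S.V[b];
    S.g[rep] = S.g[a] + S.g[b] - 2.0 * wab;
    S.minidx[rep] = std::min(S.minidx[a], S.minidx[b]);
    S.parent[oth] = rep;
    S.alive[oth] = false;
    S.version[rep]++; S.version[oth]++;

    // fold the smaller map into the larger, then normalize keys by root
    for (auto &kv : S.nbr[oth]) S.nbr[rep][kv.first] += kv.second;
    S.nbr[oth].clear();
    std::unordered_map<int, double> norm;
    norm.reserve(S.nbr[rep].size());
    for (auto &kv : S.nbr[rep]) {
      int r = S.find(kv.first);
      if (r == rep) continue;
      norm[r] += kv.second;
    }
    S.nbr[rep].swap(norm);

    // relink genomic neighbors and push fresh candidates
    S.left[rep] = L; S.right[rep] = R;
    if (L >= 0) S.right[L] = rep;
    if (R >= 0) S.left[R] = rep;
    if (adjacent) {
      if (L >= 0) {
        auto lt = S.nbr[rep].find(L);
        S.push_cand(L, rep, lt == S.nbr[rep].end() ? 0.0 : lt->second);
      }
      if (R >= 0) {
        auto rt = S.nbr[rep].find(R);
        S.push_cand(rep, R, rt == S.nbr[rep].end() ? 0.0 : rt->second);
      }
    } else {
      for (auto &kv : S.nbr[rep]) S.push_cand(rep, kv.first, kv.second);
    }
  }

  // final membership, compacted in order of first bin
  std::vector<int> root(n), order;
  std::unordered_map<int, int> label;
  IntegerVector membership(n);
  for (int i = 0; i < n; ++i) root[i] = S.find(i);
  for (int i = 0; i < n; ++i)
    if (label.find(root[i]) == label.end()) {
      int id = (int)label.size() + 1;
      label[root[i]] = id;
    }
  for (int i = 0; i < n; ++i) membership[i] = label[root[i]];

  // final height-2 entropy
  double H = 0.0;
  for (auto &kv : label) {
    int r = kv.first;
    H += se_term(S.g[r], S.V[r], S.two_w, S.two_w);
  }
  for (int i = 0; i < n; ++i) {
    double di = S.d[i], Vm = S.V[root[i]];
    if (di > 0.0 && Vm > 0.0 && di < Vm)
      H += -(di / S.two_w) * std::log2(di / Vm);
  }

  return List::create(_["membership"] = membership,
                      _["entropy"] = H,
                      _["deltas"] = NumericVector(deltas.begin(), deltas.end()),
                      _["n_merges"] = (int)deltas.size());
}
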