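#include <Rcpp.h>
#include <unordered_set>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Demography helpers. Epochs are given as parallel vectors: starts (gens,
// starts[0] == 0, strictly increasing) and sizes (haploid N_h > 1). The last
// epoch extends to +Inf.
// ---------------------------------------------------------------------------

static int find_epoch(const std::vector<double>& starts, double t) {
  int i = (int)starts.size() - 1;
  while (i > 0 && t < starts[i]) --i;
  return i;
}

// Continuous-time wait from t0 (generations) while k lineages remain:
// hazard C(k,2)/N_h(t) per generation, inverted epoch by epoch.
static double wait_continuous(double t0, double ck2,
                              const std::vector<double>& starts,
                              const std::vector<double>& sizes) {
  double E = exp_rand();
  int K = (int)starts.size();
  int i = find_epoch(starts, t0);
  double cur = t0;
  for (;; ++i) {
    double N = sizes[i];
    double end = (i + 1 < K) ? starts[i + 1] : R_PosInf;
    if (i + 1 >= K) return cur + E * N / ck2;
    double cap = (end - cur) * ck2 / N;
    if (E <= cap) return cur + E * N / ck2;
    E -= cap;
    cur = end;
  }
}

// Discrete-time wait: generation t (integer >= t0+1) succeeds with
// probability min(1, C(k,2)/N_h(t)); geometric draws per epoch, events at an
// epoch boundary belong to the later epoch.
static double wait_discrete(double t0, double ck2,
                            const std::vector<double>& starts,
                            const std::vector<double>& sizes) {
  int K = (int)starts.size();
  double cur = t0;
  for (;;) {
    int i = find_epoch(starts, cur + 1.0);
    double N = sizes[i];
    double p = ck2 / N;
    if (p > 1.0) p = 1.0;
    double g = (p >= 1.0) ? 0.0 : R::rgeom(p);
    double cand = cur + 1.0 + g;
    double end = (i + 1 < K) ? starts[i + 1] : R_PosInf;
    if (cand < end) return cand;
    cur = end - 1.0;  // geometric memorylessness: redraw in the next epoch
  }
}

// ---------------------------------------------------------------------------
// Core simulation (0-based ids; leaves 0..n-1, internal n..2n-2 in merge
// order, root = 2n-2). parent[root] = -1.
// ---------------------------------------------------------------------------

static void core_simulate(int n, const std::vector<double>& starts,
                          const std::vector<double>& sizes, bool discrete,
                          std::vector<int>& parent, std::vector<double>& time) {
  int total = 2 * n - 1;
  parent.assign(total, -1);
  time.assign(total, 0.0);
  std::vector<int> active(n);
  for (int i = 0; i < n; ++i) active[i] = i;
  double t = 0.0;
  int node = n;
  for (int k = n; k >= 2; --k, ++node) {
    double ck2 = 0.5 * (double)k * (double)(k - 1);
    t = discrete ? wait_discrete(t, ck2, starts, sizes)
                 : wait_continuous(t, ck2, starts, sizes);
    int ai = (int)(unif_rand() * k);
    if (ai >= k) ai = k - 1;
    int a = active[ai];
    active[ai] = active[k - 1];
    int bi = (int)(unif_rand() * (k - 1));
    if (bi >= k - 1) bi = k - 2;
    int b = active[bi];
    parent[a] = node;
    parent[b] = node;
    time[node] = t;
    active[bi] = node;
  }
}

// Per-branch nearest-crossover distances: d ~ Exp(rate = branch length in
// generations), one draw per side; zero-length branches get +Inf.
static void core_annotate(const std::vector<int>& parent,
                          const std::vector<double>& time,
                          std::vector<double>& dL, std::vector<double>& dR) {
  int total = (int)parent.size();
  dL.assign(total, NA_REAL);
  dR.assign(total, NA_REAL);
  for (int v = 0; v < total; ++v) {
    int p = parent[v];
    if (p < 0) continue;
    double len = time[p] - time[v];
    dL[v] = len > 0 ? exp_rand() / len : R_PosInf;
    dR[v] = len > 0 ? exp_rand() / len : R_PosInf;
  }
}

// ---------------------------------------------------------------------------
// Pruned detectable-segment enumeration. Bottom-up: each node carries
// (leaf, L, R) entries where L/R are running minima of d_left/d_right along
// the leaf's path; extents only shrink upward so filtering by the detection
// criterion is exact. m-tuples are emitted at their MRCA by combining entries
// from the two children.
// ---------------------------------------------------------------------------

struct Entry {
  int leaf;
  double L, R;
};

struct DetectOut {
  std::vector<int> members;  // flat, m per record
  std::vector<double> L, R;
};

static inline bool keep_entry(double L, double R, double w, int mode) {
  return mode == 0 ? (R >= w) : (L + R >= w);
}

// enumerate subsets of size `need` from `from`, combining with the partial
// (L,R) accumulated from the other child's subset
static void emit_combos(const std::vector<Entry>& from, size_t start, int need,
                        std::vector<int>& picked, double accL, double accR,
                        const std::vector<int>& other, double w, int mode,
                        DetectOut& out) {
  if (need == 0) {
    if (keep_entry(accL, accR, w, mode)) {
      for (int id : other) out.members.push_back(id);
      for (int id : picked) out.members.push_back(id);
      out.L.push_back(accL);
      out.R.push_back(accR);
    }
    return;
  }
  for (size_t i = start; i + (size_t)need <= from.size(); ++i) {
    picked.push_back(from[i].leaf);
    emit_combos(from, i + 1, need - 1, picked, std::min(accL, from[i].L),
                std::min(accR, from[i].R), other, w, mode, out);
    picked.pop_back();
  }
}

static void core_detect(const std::vector<int>& parent,
                        const std::vector<double>& time,
                        const std::vector<double>& dL,
                        const std::vector<double>& dR, double w, int mode,
                        int m, DetectOut& out) {
  int total = (int)parent.size();
  int n = (total + 1) / 2;
  std::vector<int> child1(total, -1), child2(total, -1);
  int root = -1;
  for (int v = 0; v < total; ++v) {
    int p = parent[v];
    if (p < 0) {
      root = v;
      continue;
    }
    if (child1[p] < 0)
      child1[p] = v;
    else
      child2[p] = v;
  }
  std::vector<std::vector<Entry> > lists(total);
  // post-order DFS so arbitrary valid id orderings work
  std::vector<int> stack, order;
  stack.push_back(root);
  while (!stack.empty()) {
    int v = stack.back();
    stack.pop_back();
    order.push_back(v);
    if (child1[v] >= 0) {
      stack.push_back(child1[v]);
      stack.push_back(child2[v]);
    }
  }
  for (int oi = (int)order.size() - 1; oi >= 0; --oi) {
    int v = order[oi];
    if (child1[v] < 0) {
      lists[v].push_back(Entry{v, R_PosInf, R_PosInf});
      continue;
    }
    // pull children lists through their branches (apply branch minima,
    // filter by the exact pruning rule)
    std::vector<Entry> adj[2];
    int ch[2] = {child1[v], child2[v]};
    for (int s = 0; s < 2; ++s) {
      int c = ch[s];
      adj[s].reserve(lists[c].size());
      for (const Entry& e : lists[c]) {
        double L = std::min(e.L, dL[c]);
        double R = std::min(e.R, dR[c]);
        if (keep_entry(L, R, w, mode)) adj[s].push_back(Entry{e.leaf, L, R});
      }
      lists[c].clear();
      lists[c].shrink_to_fit();
    }
    // emit m-tuples spanning both children (their MRCA is v)
    if (m == 2) {
      for (const Entry& a : adj[0])
        for (const Entry& b : adj[1]) {
          double L = std::min(a.L, b.L), R = std::min(a.R, b.R);
          if (keep_entry(L, R, w, mode)) {
            out.members.push_back(a.leaf);
            out.members.push_back(b.leaf);
            out.L.push_back(L);
            out.R.push_back(R);
          }
        }
    } else {
      std::vector<int> picked, other;
      for (int i = 1; i <= m - 1; ++i) {
        // i entries from child 0, m-i from child 1
        if ((int)adj[0].size() < i || (int)adj[1].size() < m - i) continue;
        std::vector<bool> sel(adj[0].size(), false);
        std::fill(sel.begin(), sel.begin() + i, true);
        do {
          double accL = R_PosInf, accR = R_PosInf;
          other.clear();
          for (size_t j = 0; j < adj[0].size(); ++j)
            if (sel[j]) {
              other.push_back(adj[0][j].leaf);
              accL = std::min(accL, adj[0][j].L);
              accR = std::min(accR, adj[0][j].R);
            }
          picked.clear();
          emit_combos(adj[1], 0, m - i, picked, accL, accR, other, w, mode,
                      out);
        } while (std::prev_permutation(sel.begin(), sel.end()));
      }
    }
    // merged candidate list moves upward
    lists[v].reserve(adj[0].size() + adj[1].size());
    lists[v].insert(lists[v].end(), adj[0].begin(), adj[0].end());
    lists[v].insert(lists[v].end(), adj[1].begin(), adj[1].end());
  }
  (void)n;
}

// ---------------------------------------------------------------------------
// Union-find connected-component features
// ---------------------------------------------------------------------------

static int uf_find(std::vector<int>& up, int x) {
  while (up[x] != x) {
    up[x] = up[up[x]];
    x = up[x];
  }
  return x;
}

// features: edges, tree2, tree3, complete3plus, largest
static void core_features(int n_nodes, const std::vector<int>& ei,
                          const std::vector<int>& ej, double* feats) {
  std::vector<int> up(n_nodes);
  for (int i = 0; i < n_nodes; ++i) up[i] = i;
  for (size_t k = 0; k < ei.size(); ++k) {
    int a = uf_find(up, ei[k]), b = uf_find(up, ej[k]);
    if (a != b) up[a] = b;
  }
  std::vector<int> nodes(n_nodes, 0), edges(n_nodes, 0);
  for (int i = 0; i < n_nodes; ++i) nodes[uf_find(up, i)]++;
  for (size_t k = 0; k < ei.size(); ++k) edges[uf_find(up, ei[k])]++;
  double tree2 = 0, tree3 = 0, comp3 = 0, largest = n_nodes > 0 ? 1 : 0;
  for (int i = 0; i < n_nodes; ++i) {
    if (nodes[i] == 0) continue;
    int nn = nodes[i], ne = edges[i];
    if (nn == 2 && ne == 1) tree2++;
    if (nn == 3 && ne == 2) tree3++;
    if (nn >= 3 && ne == nn * (nn - 1) / 2) comp3++;
    if (nn > largest) largest = nn;
  }
  feats[0] = (double)ei.size();
  feats[1] = tree2;
  feats[2] = tree3;
  feats[3] = comp3;
  feats[4] = largest;
}

// ---------------------------------------------------------------------------
// Exported single-step operations
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_simulate_tree(int n, NumericVector starts, NumericVector sizes,
                       bool discrete) {
  std::vector<double> st(starts.begin(), starts.end()),
      sz(sizes.begin(), sizes.end());
  std::vector<int> parent;
  std::vector<double> time;
  core_simulate(n, st, sz, discrete, parent, time);
  return List::create(_["parent"] = wrap(parent), _["time"] = wrap(time));
}

// [[Rcpp::export]]
NumericMatrix cpp_annotate(IntegerVector parent, NumericVector time) {
  std::vector<int> par(parent.begin(), parent.end());
  std::vector<double> tim(time.begin(), time.end()), dL, dR;
  core_annotate(par, tim, dL, dR);
  NumericMatrix d(par.size(), 2);
  for (int v = 0; v < (int)par.size(); ++v) {
    d(v, 0) = dL[v];
    d(v, 1) = dR[v];
  }
  return d;
}

// [[Rcpp::export]]
List cpp_detect(IntegerVector parent, NumericVector time, NumericVector dL,
                NumericVector dR, double w, int mode, int m) {
  std::vector<int> par(parent.begin(), parent.end());
  std::vector<double> tim(time.begin(), time.end()),
      dl(dL.begin(), dL.end()), dr(dR.begin(), dR.end());
  DetectOut out;
  core_detect(par, tim, dl, dr, w, mode, m, out);
  int nrec = (int)out.L.size();
  IntegerMatrix mem(nrec, m);
  for (int r = 0; r < nrec; ++r)
    for (int j = 0; j < m; ++j) mem(r, j) = out.members[(size_t)r * m + j];
  return List::create(_["members"] = mem, _["L"] = wrap(out.L),
                      _["R"] = wrap(out.R));
}

// [[Rcpp::export]]
NumericVector cpp_graph_features(int n_nodes, IntegerVector ei,
                                 IntegerVector ej) {
  std::vector<int> a(ei.begin(), ei.end()), b(ej.begin(), ej.end());
  double f[5];
  core_features(n_nodes, a, b, f);
  return NumericVector::create(f[0], f[1], f[2], f[3], f[4]);
}

// [[Rcpp::export]]
List cpp_simulate_er(int n, double p) {
  double M = 0.5 * (double)n * (double)(n - 1);
  long long m = (long long)R::rbinom(M, p);
  std::unordered_set<long long> seen;
  seen.reserve((size_t)(2 * m + 8));
  std::vector<int> ei, ej;
  ei.reserve(m);
  ej.reserve(m);
  while ((long long)ei.size() < m) {
    int a = (int)(unif_rand() * n);
    if (a >= n) a = n - 1;
    int b = (int)(unif_rand() * n);
    if (b >= n) b = n - 1;
    if (a == b) continue;
    int i = a < b ? a : b, j = a < b ? b : a;
    long long key = (long long)i * n + j;
    if (seen.insert(key).second) {
      ei.push_back(i);
      ej.push_back(j);
    }
  }
  return List::create(_["i"] = wrap(ei), _["j"] = wrap(ej));
}

// ---------------------------------------------------------------------------
// Batched replicate driver: one full replicate (tree -> annotation ->
// detectable pairs -> graph features) returning
// c(count, x01, count_half0, count_half1, edges, tree2, tree3, comp3, largest)
// where halves are leaves [0, n/2) and [n/2, n).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_ibd_replicate(int n, NumericVector starts,
                                NumericVector sizes, double w, int mode,
                                bool discrete) {
  std::vector<double> st(starts.begin(), starts.end()),
      sz(sizes.begin(), sizes.end());
  std::vector<int> parent;
  std::vector<double> time, dL, dR;
  core_simulate(n, st, sz, discrete, parent, time);
  core_annotate(parent, time, dL, dR);
  DetectOut out;
  core_detect(parent, time, dL, dR, w, mode, 2, out);
  int half = n / 2;
  double x01 = 0, c0 = 0, c1 = 0;
  std::vector<int> ei(out.L.size()), ej(out.L.size());
  for (size_t r = 0; r < out.L.size(); ++r) {
    int a = out.members[2 * r], b = out.members[2 * r + 1];
    ei[r] = a;
    ej[r] = b;
    if ((a == 0 && b == 1) || (a == 1 && b == 0)) x01 = 1;
    if (a < half && b < half) c0++;
    if (a >= half && b >= half) c1++;
  }
  double f[5];
  core_features(n, ei, ej, f);
  return NumericVector::create(
      _["count"] = (double)out.L.size(), _["x01"] = x01, _["count0"] = c0,
      _["count1"] = c1, _["edges"] = f[0], _["tree2"] = f[1],
      _["tree3"] = f[2], _["complete3plus"] = f[3], _["largest"] = f[4]);
}

// ---------------------------------------------------------------------------
// Monte-Carlo oracle: per-replicate detection indicators (and extents) for
// fixed tuples of leaves on freshly simulated small trees. Computed by the
// spanning-subtree method, independent of the pruned enumeration.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_tuple_mc(int n_leaves, NumericVector starts, NumericVector sizes,
                  double w, int mode, List tuples, int reps, bool discrete) {
  std::vector<double> st(starts.begin(), starts.end()),
      sz(sizes.begin(), sizes.end());
  int nt = tuples.size();
  std::vector<std::vector<int> > tup(nt);
  for (int j = 0; j < nt; ++j) {
    IntegerVector t0 = tuples[j];
    tup[j].assign(t0.begin(), t0.end());  // 0-based leaf ids
  }
  IntegerMatrix ind(reps, nt);
  int total = 2 * n_leaves - 1;
  std::vector<int> parent, cnt(total);
  std::vector<double> time, dL, dR;
  for (int r = 0; r < reps; ++r) {
    core_simulate(n_leaves, st, sz, discrete, parent, time);
    core_annotate(parent, time, dL, dR);
    for (int j = 0; j < nt; ++j) {
      int m = (int)tup[j].size();
      std::fill(cnt.begin(), cnt.end(), 0);
      for (int leaf : tup[j])
        for (int v = leaf; v >= 0; v = parent[v]) cnt[v]++;
      double L = R_PosInf, R = R_PosInf;
      for (int v = 0; v < total; ++v)
        if (cnt[v] >= 1 && cnt[v] < m) {
          L = std::min(L, dL[v]);
          R = std::min(R, dR[v]);
        }
      bool det = mode == 0 ? (R >= w) : (L + R >= w);
      ind(r, j) = det ? 1 : 0;
    }
  }
  return List::create(_["indicators"] = ind);
}
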