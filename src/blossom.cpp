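#include <Rcpp.h>
#include <queue>
#include <vector>

// Maximum matching in a general (non-bipartite) graph by blossom
// contraction: repeated alternating-tree BFS with base[] tracking of
// contracted odd cycles. O(V * E) per augmentation in the worst case, fast in
// practice on the sparse, regular compatibility graphs used here.

static std::vector<std::vector<int>> g;
static std::vector<int> match_, p_, base_;
static std::vector<char> used_, blossom_;

static int lca(int n, int a, int b) {
  std::vector<char> seen(n, 0);
  for (;;) {
    a = base_[a];
    seen[a] = 1;
    if (match_[a] == -1) break;
    a = p_[match_[a]];
  }
  for (;;) {
    b = base_[b];
    if (seen[b]) return b;
    b = p_[match_[b]];
  }
}

static void mark_path(int v, int b, int child) {
  while (base_[v] != b) {
    blossom_[base_[v]] = 1;
    blossom_[base_[match_[v]]] = 1;
    p_[v] = child;
    child = match_[v];
    v = p_[match_[v]];
  }
}

static int find_path(int n, int root) {
  std::fill(used_.begin(), used_.end(), 0);
  std::fill(p_.begin(), p_.end(), -1);
  for (int i = 0; i < n; ++i) base_[i] = i;
  used_[root] = 1;
  std::queue<int> q;
  q.push(root);
  while (!q.empty()) {
    int v = q.front();
    q.pop();
    for (int to : g[v]) {
      if (base_[v] == base_[to] || match_[v] == to) continue;
      if (to == root || (match_[to] != -1 && p_[match_[to]] != -1)) {
        int curbase = lca(n, v, to);
        std::fill(blossom_.begin(), blossom_.end(), 0);
        mark_path(v, curbase, to);
        mark_path(to, curbase, v);
        for (int i = 0; i < n; ++i) {
          if (blossom_[base_[i]]) {
            base_[i] = curbase;
            if (!used_[i]) {
              used_[i] = 1;
              q.push(i);
            }
          }
        }
      } else if (p_[to] == -1) {
        p_[to] = v;
        if (match_[to] == -1) return to;
        used_[match_[to]] = 1;
        q.push(match_[to]);
      }
    }
  }
  return -1;
}

// [[Rcpp::export]]
Rcpp::IntegerVector blossom_max_matching(int n_vertices,
                                         Rcpp::IntegerMatrix edges) {
  int n = n_vertices;
  g.assign(n, {});
  for (int i = 0; i < edges.nrow(); ++i) {
    int a = edges(i, 0) - 1, b = edges(i, 1) - 1;
    if (a < 0 || b < 0 || a >= n || b >= n || a == b)
      Rcpp::stop("invalid edge in matching input");
    g[a].push_back(b);
    g[b].push_back(a);
  }
  match_.assign(n, -1);
  p_.assign(n, -1);
  base_.assign(n, 0);
  used_.assign(n, 0);
  blossom_.assign(n, 0);
  // greedy initialisation cuts down the number of augmentation phases
  for (int v = 0; v < n; ++v) {
    if (match_[v] != -1) continue;
    for (int to : g[v]) {
      if (match_[to] == -1) {
        match_[v] = to;
        match_[to] = v;
        break;
      }
    }
  }
  for (int v = 0; v < n; ++v) {
    if (match_[v] != -1) continue;
    int u = find_path(n, v);
    while (u != -1) {  // flip matched/unmatched along the augmenting path
      int pv = p_[u], ppv = match_[pv];
      match_[u] = pv;
      match_[pv] = u;
      u = ppv;
    }
  }
  Rcpp::IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = match_[i] + 1;  // 0 = unmatched
  return out;
}
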