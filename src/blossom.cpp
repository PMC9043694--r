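// Exact minimum-weight perfect matching on a complete graph, via
// maximum-weight general matching (O(n^3) blossom algorithm with dual
// labels, dense-graph formulation). Minimization is obtained by weight
// reversal W = (max(d) + 1 - d); on a complete graph with strictly
// positive weights a maximum-weight matching is perfect, and maximizing
// sum(W) over perfect matchings minimizes sum(d). Input weights are
// doubled internally so all dual updates stay integral.

#include <Rcpp.h>
#include <vector>
#include <deque>
#include <algorithm>
using namespace Rcpp;
typedef long long ll;

namespace wmatch {

const ll INF = (ll)1e18;
struct Edge { int u, v; ll w; };

static int n, n_x;
static std::vector<std::vector<Edge> > g;
static std::vector<ll> lab;
static std::vector<int> match_, slack_, st, pa, S, vis;
static std::vector<std::vector<int> > flower, flower_from;
static std::deque<int> q;

static inline ll e_delta(const Edge &e) {
  return lab[e.u] + lab[e.v] - g[e.u][e.v].w * 2;
}

static inline void update_slack(int u, int x) {
  if (!slack_[x] || e_delta(g[u][x]) < e_delta(g[slack_[x]][x]))
    slack_[x] = u;
}

static void set_slack(int x) {
  slack_[x] = 0;
  for (int u = 1; u <= n; ++u)
    if (g[u][x].w > 0 && st[u] != x && S[st[u]] == 0) update_slack(u, x);
}

static void q_push(int x) {
  if (x <= n) q.push_back(x);
  else
    for (size_t i = 0; i < flower[x].size(); ++i) q_push(flower[x][i]);
}

static void set_st(int x, int b) {
  st[x] = b;
  if (x > n)
    for (size_t i = 0; i < flower[x].size(); ++i) set_st(flower[x][i], b);
}

static int get_pr(int b, int xr) {
  int pr = std::find(flower[b].begin(), flower[b].end(), xr) -
           flower[b].begin();
  if (pr % 2 == 1) {
    std::reverse(flower[b].begin() + 1, flower[b].end());
    return (int)flower[b].size() - pr;
  }
  return pr;
}

static void set_match(int u, int v) {
  match_[u] = g[u][v].v;
  if (u > n) {
    Edge e = g[u][v];
    int xr = flower_from[u][e.u], pr = get_pr(u, xr);
    for (int i = 0; i < pr; ++i)
      set_match(flower[u][i], flower[u][i ^ 1]);
    set_match(xr, v);
    std::rotate(flower[u].begin(), flower[u].begin() + pr,
                flower[u].end());
  }
}

static void augment(int u, int v) {
  for (;;) {
    int xnv = st[match_[u]];
    set_match(u, v);
    if (!xnv) return;
    set_match(xnv, st[pa[xnv]]);
    u = st[pa[xnv]], v = xnv;
  }
}

static int get_lca(int u, int v) {
  static int t = 0;
  for (++t; u || v; std::swap(u, v)) {
    if (u == 0) continue;
    if (vis[u] == t) return u;
    vis[u] = t;
    u = st[match_[u]];
    if (u) u = st[pa[u]];
  }
  return 0;
}

static void add_blossom(int u, int lca, int v) {
  int b = n + 1;
  while (b <= n_x && st[b]) ++b;
  if (b > n_x) ++n_x;
  lab[b] = 0, S[b] = 0;
  match_[b] = match_[lca];
  flower[b].clear();
  flower[b].push_back(lca);
  for (int x = u, y; x != lca; x = st[pa[y]])
    flower[b].push_back(x), flower[b].push_back(y = st[match_[x]]),
        q_push(y);
  std::reverse(flower[b].begin() + 1, flower[b].end());
  for (int x = v, y; x != lca; x = st[pa[y]])
    flower[b].push_back(x), flower[b].push_back(y = st[match_[x]]),
        q_push(y);
  set_st(b, b);
  for (int x = 1; x <= n_x; ++x) g[b][x].w = g[x][b].w = 0;
  for (int x = 1; x <= n; ++x) flower_from[b][x] = 0;
  for (size_t i = 0; i < flower[b].size(); ++i) {
    int xs = flower[b][i];
    for (int x = 1; x <= n_x; ++x)
      if (g[b][x].w == 0 || e_delta(g[xs][x]) < e_delta(g[b][x]))
        g[b][x] = g[xs][x], g[x][b] = g[x][xs];
    for (int x = 1; x <= n; ++x)
      if (flower_from[xs][x]) flower_from[b][x] = xs;
  }
  set_slack(b);
}

static void expand_blossom(int b) {
  for (size_t i = 0; i < flower[b].size(); ++i)
    set_st(flower[b][i], flower[b][i]);
  int xr = flower_from[b][g[b][pa[b]].u], pr = get_pr(b, xr);
  for (int i = 0; i < pr; i += 2) {
    int xs = flower[b][i], xns = flower[b][i + 1];
    pa[xs] = g[xns][xs].u;
    S[xs] = 1, S[xns] = 0;
    slack_[xs] = 0, set_slack(xns);
    q_push(xns);
  }
  S[xr] = 1, pa[xr] = pa[b];
  for (size_t i = pr + 1; i < flower[b].size(); ++i) {
    int xs = flower[b][i];
    S[xs] = -1, set_slack(xs);
  }
  st[b] = 0;
}

static void augment_pair(const Edge &e) {
  augment(st[e.u], st[e.v]);
  augment(st[e.v], st[e.u]);
}

static bool on_found_edge(const Edge &e) {
  int u = st[e.u], v = st[e.v];
  if (S[v] == -1) {
    pa[v] = e.u, S[v] = 1;
    int nu = st[match_[v]];
    slack_[v] = slack_[nu] = 0;
    S[nu] = 0, q_push(nu);
  } else if (S[v] == 0) {
    int lca = get_lca(u, v);
    if (!lca) {
      augment_pair(e);
      return true;
    }
    add_blossom(u, lca, v);
  }
  return false;
}

static bool matching() {
  std::fill(S.begin(), S.begin() + n_x + 1, -1);
  std::fill(slack_.begin(), slack_.begin() + n_x + 1, 0);
  q.clear();
  for (int x = 1; x <= n_x; ++x)
    if (st[x] == x && !match_[x]) pa[x] = 0, S[x] = 0, q_push(x);
  if (q.empty()) return false;
  for (;;) {
    while (!q.empty()) {
      int u = q.front();
      q.pop_front();
      if (S[st[u]] == 1) continue;
      for (int v = 1; v <= n; ++v)
        if (g[u][v].w > 0 && st[u] != st[v]) {
          if (e_delta(g[u][v]) == 0) {
            if (on_found_edge(g[u][v])) return true;
          } else {
            update_slack(u, st[v]);
          }
        }
    }
    ll d = INF;
    for (int b = n + 1; b <= n_x; ++b)
      if (st[b] == b && S[b] == 1) d = std::min(d, lab[b] / 2);
    for (int x = 1; x <= n_x; ++x)
      if (st[x] == x && slack_[x]) {
        if (S[x] == -1)
          d = std::min(d, e_delta(g[slack_[x]][x]));
        else if (S[x] == 0)
          d = std::min(d, e_delta(g[slack_[x]][x]) / 2);
      }
    for (int u = 1; u <= n; ++u) {
      if (S[st[u]] == 0) {
        if (lab[u] <= d) return false;
        lab[u] -= d;
      } else if (S[st[u]] == 1) {
        lab[u] += d;
      }
    }
    for (int b = n + 1; b <= n_x; ++b)
      if (st[b] == b) {
        if (S[b] == 0)
          lab[b] += d * 2;
        else if (S[b] == 1)
          lab[b] -= d * 2;
      }
    q.clear();
    for (int x = 1; x <= n_x; ++x)
      if (st[x] == x && slack_[x] && st[slack_[x]] != x &&
          e_delta(g[slack_[x]][x]) == 0)
        if (on_found_edge(g[slack_[x]][x])) return true;
    for (int b = n + 1; b <= n_x; ++b)
      if (st[b] == b && S[b] == 1 && lab[b] == 0) expand_blossom(b);
  }
  return false;
}

} // namespace wmatch

// [[Rcpp::export(name = ".mwpmCpp")]]
IntegerVector mwpmCpp(NumericMatrix dist) {
  using namespace wmatch;
  const int N = dist.nrow();
  if (N != dist.ncol()) stop("distance matrix must be square");
  if (N % 2 != 0) stop("perfect matching needs an even number of nodes");
  if (N == 0) return IntegerVector(0);

  double maxd = 0;
  for (int i = 0; i < N; ++i)
    for (int j = 0; j < N; ++j)
      if (i != j && dist(i, j) > maxd) maxd = dist(i, j);

  n = N;
  n_x = n;
  const int sz = 2 * n + 1;
  g.assign(sz, std::vector<Edge>(sz));
  lab.assign(sz, 0);
  match_.assign(sz, 0);
  slack_.assign(sz, 0);
  st.assign(sz, 0);
  pa.assign(sz, 0);
  S.assign(sz, 0);
  vis.assign(sz, 0);
  flower.assign(sz, std::vector<int>());
  flower_from.assign(sz, std::vector<int>(n + 1, 0));

  ll w_max = 0;
  for (int u = 1; u <= n; ++u)
    for (int v = 1; v <= n; ++v) {
      g[u][v].u = u;
      g[u][v].v = v;
      // reversed, doubled, strictly positive off-diagonal weight
      g[u][v].w = (u == v) ? 0
                           : 2 * (ll)(maxd + 1.0 - dist(u - 1, v - 1));
      if (g[u][v].w > w_max) w_max = g[u][v].w;
      flower_from[u][v] = (u == v ? u : 0);
    }
  for (int u = 0; u <= n; ++u) st[u] = u;
  for (int u = 1; u <= n; ++u) lab[u] = w_max;

  int n_matches = 0;
  while (matching()) ++n_matches;
  if (2 * n_matches != N)
    stop("internal error: matching is not perfect");

  IntegerVector out(N);
  for (int u = 1; u <= n; ++u) out[u - 1] = match_[u];
  return out;
}
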