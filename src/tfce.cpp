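#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Union-find with path halving; sizes tracked at roots.
static int uf_find(std::vector<int> &parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

// One-sided TFCE on values >= dh; adds into out. Thresholds are the grid
// h_k = k*dh, k = 1..ceil(max(val)/dh), swept from the top so connected
// components can be grown incrementally with a union-find.
static void tfce_one_side(const std::vector<double> &val,
                          const std::vector<std::vector<int> > &adj,
                          double E, double H, double dh,
                          double sign, std::vector<double> &out) {
  int n = val.size();
  double hmax = 0.0;
  for (int i = 0; i < n; ++i) if (val[i] > hmax) hmax = val[i];
  if (hmax <= 0.0 || dh <= 0.0) return;

  int nsteps = (int)std::ceil(hmax / dh - 1e-12);
  if (nsteps < 1) return;

  std::vector<int> order;
  order.reserve(n);
  for (int i = 0; i < n; ++i) if (val[i] > 0.0) order.push_back(i);
  std::sort(order.begin(), order.end(),
            [&val](int a, int b) { return val[a] > val[b]; });

  std::vector<int> parent(n), csize(n, 0);
  std::vector<char> active(n, 0);
  std::vector<int> act; // activation order, stable list of active nodes
  act.reserve(order.size());
  for (int i = 0; i < n; ++i) parent[i] = i;

  size_t ptr = 0;
  for (int k = nsteps; k >= 1; --k) {
    double h = k * dh;
    while (ptr < order.size() && val[order[ptr]] >= h) {
      int p = order[ptr];
      active[p] = 1;
      csize[p] = 1;
      act.push_back(p);
      for (size_t j = 0; j < adj[p].size(); ++j) {
        int q = adj[p][j];
        if (!active[q]) continue;
        int rp = uf_find(parent, p), rq = uf_find(parent, q);
        if (rp != rq) {
          if (csize[rp] < csize[rq]) std::swap(rp, rq);
          parent[rq] = rp;
          csize[rp] += csize[rq];
        }
      }
      ++ptr;
    }
    double hterm = std::pow(h, H) * dh;
    for (size_t j = 0; j < act.size(); ++j) {
      int p = act[j];
      out[p] += sign * std::pow((double)csize[uf_find(parent, p)], E) * hterm;
    }
  }
}

// [[Rcpp::export(name = ".tfce_enhance_cpp")]]
NumericVector tfce_enhance_cpp(NumericVector stat, IntegerMatrix edges,
                               double E, double H, double dh) {
  int n = stat.size();
  std::vector<std::vector<int> > adj(n);
  for (int e = 0; e < edges.nrow(); ++e) {
    int u = edges(e, 0) - 1, v = edges(e, 1) - 1; // 1-based in R
    adj[u].push_back(v);
    adj[v].push_back(u);
  }
  std::vector<double> out(n, 0.0), pos(n), neg(n);
  for (int i = 0; i < n; ++i) {
    double s = stat[i];
    pos[i] = s > 0 ? s : 0.0;
    neg[i] = s < 0 ? -s : 0.0;
  }
  tfce_one_side(pos, adj, E, H, dh, +1.0, out);
  tfce_one_side(neg, adj, E, H, dh, -1.0, out);
  return wrap(out);
}
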