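// Push-relabel maximum flow with highest-label selection and the gap
// heuristic. Capacities are integral (passed as doubles, held as 64-bit
// integers); the returned per-arc flows satisfy capacity and conservation
// constraints exactly. Fully deterministic: arcs are scanned in input
// order and active nodes are taken from per-height buckets in LIFO order.

#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// [[Rcpp::export]]
List cpp_push_relabel(int n, IntegerVector from, IntegerVector to,
                      NumericVector cap, int s, int t) {
  const int m = from.size();
  s -= 1; t -= 1;  // 1-based on the R side
  if (s < 0 || s >= n || t < 0 || t >= n) stop("source or sink out of range");
  if (s == t) stop("source equals sink");
  // residual arcs: 2*i forward (capacity cap[i]), 2*i+1 reverse (capacity 0)
  std::vector<int64_t> res(2 * m);
  std::vector<int> head(2 * m), dest(2 * m);
  std::vector<std::vector<int>> adj(n);
  for (int i = 0; i < m; ++i) {
    int u = from[i] - 1, v = to[i] - 1;
    if (u < 0 || u >= n || v < 0 || v >= n) stop("arc endpoint out of range");
    res[2 * i] = (int64_t) cap[i];
    res[2 * i + 1] = 0;
    head[2 * i] = u; dest[2 * i] = v;
    head[2 * i + 1] = v; dest[2 * i + 1] = u;
    adj[u].push_back(2 * i);
    adj[v].push_back(2 * i + 1);
  }
  std::vector<int64_t> excess(n, 0);
  std::vector<int> height(n, 0), cur(n, 0), cnt(2 * n + 1, 0);
  std::vector<std::vector<int>> bucket(2 * n + 1);
  std::vector<char> active(n, 0);
  int highest = 0;

  auto enqueue = [&](int v) {
    if (!active[v] && excess[v] > 0 && v != s && v != t) {
      active[v] = 1;
      bucket[height[v]].push_back(v);
      if (height[v] > highest) highest = height[v];
    }
  };

  height[s] = n;
  cnt[0] = n - 1;  // every node but s starts at height 0
  cnt[n] += 1;
  for (int a : adj[s]) {
    if ((a & 1) == 0 && res[a] > 0) {  // saturate forward arcs out of s
      int64_t d = res[a];
      res[a] -= d;
      res[a ^ 1] += d;
      excess[dest[a]] += d;
      excess[s] -= d;
    }
  }
  for (int a : adj[s]) enqueue(dest[a]);

  auto push = [&](int u, int a) {
    int v = dest[a];
    int64_t d = std::min(excess[u], res[a]);
    res[a] -= d;
    res[a ^ 1] += d;
    excess[u] -= d;
    excess[v] += d;
    enqueue(v);
  };

  auto gap = [&](int h) {
    // no node left at height h: lift everything in (h, n) above n
    for (int v = 0; v < n; ++v) {
      if (height[v] > h && height[v] < n) {
        cnt[height[v]] -= 1;
        height[v] = n + 1;
        cnt[height[v]] += 1;
      }
    }
  };

  auto discharge = [&](int u) {
    while (excess[u] > 0) {
      if (cur[u] == (int) adj[u].size()) {
        // relabel
        int oldh = height[u];
        int newh = 2 * n;
        for (int a : adj[u]) {
          if (res[a] > 0 && height[dest[a]] + 1 < newh) {
            newh = height[dest[a]] + 1;
          }
        }
        cnt[oldh] -= 1;
        height[u] = newh;
        cnt[newh] += 1;
        cur[u] = 0;
        if (oldh < n && cnt[oldh] == 0) gap(oldh);
        if (height[u] >= 2 * n) break;
      } else {
        int a = adj[u][cur[u]];
        if (res[a] > 0 && height[u] == height[dest[a]] + 1) {
          push(u, a);
        } else {
          cur[u] += 1;
        }
      }
    }
  };

  while (highest >= 0) {
    if (bucket[highest].empty()) {
      --highest;
      continue;
    }
    int u = bucket[highest].back();
    bucket[highest].pop_back();
    active[u] = 0;
    discharge(u);
    if (excess[u] > 0 && height[u] < 2 * n) enqueue(u);
  }

  NumericVector flow(m);
  for (int i = 0; i < m; ++i) {
    flow[i] = (double) ((int64_t) cap[i] - res[2 * i]);
  }
  return List::create(_["value"] = (double) excess[t], _["flow"] = flow);
}
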