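#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Sankoff dynamic programming for linearly ordered (Wagner) characters.
// Edge costs are |i - j| on the state lattice 0..S-1, so the per-node
// min-plus convolution with a child vector reduces to a two-pass distance
// transform in O(S) instead of O(S^2).

static inline void distance_transform(std::vector<double>& f) {
  const int S = (int)f.size();
  for (int i = 1; i < S; ++i)
    if (f[i - 1] + 1.0 < f[i]) f[i] = f[i - 1] + 1.0;
  for (int i = S - 2; i >= 0; --i)
    if (f[i + 1] + 1.0 < f[i]) f[i] = f[i + 1] + 1.0;
}

// edge: 2-column integer matrix (parent, child) in any row order. Node ids
// are arbitrary positive integers; ids <= nrow(states) index tip rows of
// `states` (ntip x nchar, NA = missing: zero initial cost for every state).
// Returns the per-character minimum tree length.
// [[Rcpp::export(name = ".sankoff_lengths")]]
NumericVector sankoff_lengths(IntegerMatrix edge, IntegerMatrix states,
                              int n_states) {
  const int ne = edge.nrow();
  const int ntip = states.nrow();
  const int nchar = states.ncol();
  const double INF = std::numeric_limits<double>::infinity();

  int maxid = 0;
  for (int e = 0; e < ne; ++e) {
    if (edge(e, 0) > maxid) maxid = edge(e, 0);
    if (edge(e, 1) > maxid) maxid = edge(e, 1);
  }
  // root = node appearing as parent but never as child
  std::vector<char> is_child(maxid + 1, 0);
  for (int e = 0; e < ne; ++e) is_child[edge(e, 1)] = 1;
  int root = -1;
  for (int e = 0; e < ne; ++e)
    if (!is_child[edge(e, 0)]) { root = edge(e, 0); break; }
  if (root < 0) stop("no root found: edge matrix is cyclic");

  // child-edge adjacency (CSR) and a postorder edge sequence via DFS
  std::vector<int> head(maxid + 1, -1), nxt(ne, -1);
  for (int e = ne - 1; e >= 0; --e) {       // preserve row order per parent
    nxt[e] = head[edge(e, 0)];
    head[edge(e, 0)] = e;
  }
  std::vector<int> post(ne), stack;
  stack.reserve(ne);
  int n = 0;
  for (int e = head[root]; e != -1; e = nxt[e]) stack.push_back(e);
  std::vector<int> pre;
  pre.reserve(ne);
  while (!stack.empty()) {
    int e = stack.back();
    stack.pop_back();
    pre.push_back(e);
    for (int c = head[edge(e, 1)]; c != -1; c = nxt[c]) stack.push_back(c);
  }
  if ((int)pre.size() != ne) stop("disconnected edge matrix");
  for (int i = 0; i < ne; ++i) post[i] = pre[ne - 1 - i];
  (void)n;

  NumericVector out(nchar);
  std::vector<double> cost((size_t)(maxid + 1) * n_states);
  std::vector<double> buf(n_states);

  for (int ch = 0; ch < nchar; ++ch) {
    for (int v = 1; v <= maxid; ++v) {
      double* c = &cost[(size_t)v * n_states];
      if (v <= ntip) {
        int s = states(v - 1, ch);
        if (s == NA_INTEGER) {
          for (int k = 0; k < n_states; ++k) c[k] = 0.0;
        } else {
          if (s < 0 || s >= n_states) stop("state out of range");
          for (int k = 0; k < n_states; ++k) c[k] = INF;
          c[s] = 0.0;
        }
      } else {
        for (int k = 0; k < n_states; ++k) c[k] = 0.0;
      }
    }
    for (int i = 0; i < ne; ++i) {
      int e = post[i];
      const double* cc = &cost[(size_t)edge(e, 1) * n_states];
      double* cp = &cost[(size_t)edge(e, 0) * n_states];
      for (int k = 0; k < n_states; ++k) buf[k] = cc[k];
      distance_transform(buf);
      for (int k = 0; k < n_states; ++k) cp[k] += buf[k];
    }
    const double* cr = &cost[(size_t)root * n_states];
    double best = INF;
    for (int k = 0; k < n_states; ++k) if (cr[k] < best) best = cr[k];
    out[ch] = best;
  }
  return out;
}
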