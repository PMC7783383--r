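#include <Rcpp.h>
#include <numeric>
#include <vector>
using namespace Rcpp;

// Greedy multilevel (Louvain-style) maximisation of
//   Q(comm) = sum_{i,j : comm[i]==comm[j]} B[i][j]
// for a symmetric dense matrix B (e.g. the Markov-stability matrix
// Pi exp(-t(I-M)) - pi pi^T). Level-0 nodes are visited in the caller's
// order; moves are accepted only on a strict gain, ties resolved to the
// lowest community index, so the result is deterministic given the order.

static bool one_level(const std::vector<double>& B, int n,
                      const std::vector<int>& order,
                      std::vector<int>& comm) {
  const double eps = 1e-12;
  std::vector<double> s(n);
  bool any_move = false, improved = true;
  while (improved) {
    improved = false;
    for (int oi = 0; oi < n; ++oi) {
      int i = order[oi];
      std::fill(s.begin(), s.end(), 0.0);
      const double* Bi = &B[(size_t)i * n];
      for (int j = 0; j < n; ++j)
        if (j != i) s[comm[j]] += Bi[j];
      int c0 = comm[i];
      double best_gain = eps;
      int best_c = c0;
      for (int c = 0; c < n; ++c) {
        if (c == c0) continue;
        double gain = 2.0 * (s[c] - s[c0]);
        if (gain > best_gain) { best_gain = gain; best_c = c; }
      }
      if (best_c != c0) {
        comm[i] = best_c;
        improved = true;
        any_move = true;
      }
    }
  }
  return any_move;
}

// [[Rcpp::export]]
IntegerVector louvain_dense_cpp(NumericMatrix B0, IntegerVector order0) {
  int n0 = B0.nrow();
  if (B0.ncol() != n0) stop("B must be square");
  if (order0.size() != n0) stop("order must have length nrow(B)");
  // column-major copy; B symmetric so row i is &B[i*n]
  std::vector<double> B(B0.begin(), B0.end());
  std::vector<int> assign(n0);
  std::iota(assign.begin(), assign.end(), 0);
  std::vector<int> order(order0.begin(), order0.end());
  int n = n0;
  while (true) {
    std::vector<int> comm(n);
    std::iota(comm.begin(), comm.end(), 0);
    bool moved = one_level(B, n, order, comm);
    // relabel communities 0..K-1 by first occurrence (deterministic)
    std::vector<int> relab(n, -1);
    int K = 0;
    for (int i = 0; i < n; ++i)
      if (relab[comm[i]] < 0) relab[comm[i]] = K++;
    for (int i = 0; i < n; ++i) comm[i] = relab[comm[i]];
    for (int v = 0; v < n0; ++v) assign[v] = comm[assign[v]];
    if (!moved || K == n) break;
    std::vector<double> B2((size_t)K * K, 0.0);
    for (int i = 0; i < n; ++i) {
      const double* Bi = &B[(size_t)i * n];
      for (int j = 0; j < n; ++j)
        B2[(size_t)comm[i] * K + comm[j]] += Bi[j];
    }
    B.swap(B2);
    n = K;
    order.resize(n);
    std::iota(order.begin(), order.end(), 0);
  }
  IntegerVector out(n0);
  for (int v = 0; v < n0; ++v) out[v] = assign[v];
  return out;
}
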