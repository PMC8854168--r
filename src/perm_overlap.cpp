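#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Weighted reassignment null for distinct-gene overlap: each permutation
// draws h1 and h2 gene indices from the cumulative weight distribution cw
// (binary search per draw, R's RNG stream) and counts genes hit on both
// sides. Generation stamps avoid clearing the presence arrays per
// permutation.
// [[Rcpp::export]]
IntegerVector perm_overlap(NumericVector cw, int h1, int h2, int n_perm) {
  const int G = cw.size();
  IntegerVector out(n_perm);
  std::vector<int> stamp1(G, -1), stamp2(G, -1);
  for (int p = 0; p < n_perm; ++p) {
    for (int k = 0; k < h1; ++k) {
      int idx = std::upper_bound(cw.begin(), cw.end(), unif_rand()) - cw.begin();
      if (idx >= G) idx = G - 1;
      stamp1[idx] = p;
    }
    int ov = 0;
    for (int k = 0; k < h2; ++k) {
      int idx = std::upper_bound(cw.begin(), cw.end(), unif_rand()) - cw.begin();
      if (idx >= G) idx = G - 1;
      if (stamp1[idx] == p && stamp2[idx] != p) { ++ov; stamp2[idx] = p; }
    }
    out[p] = ov;
  }
  return out;
}
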