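#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component labeling of a logical grid by breadth-first search.
// Components are numbered 1..K in the order their first cell appears in
// column-major scan order, which makes labels reproducible regardless of
// how the occupancy grid was assembled.
//
// connectivity: 4 (edge neighbors) or 8 (edge + diagonal neighbors).
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerMatrix label_components_cpp(LogicalMatrix occ, int connectivity) {
  const int nr = occ.nrow(), nc = occ.ncol();
  IntegerMatrix lab(nr, nc);
  if (nr == 0 || nc == 0) return lab;
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");

  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nn = (connectivity == 4) ? 4 : 8;

  std::vector<int> stack;
  stack.reserve(256);
  int next = 0;

  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!occ(r, c) || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      stack.push_back(r + c * nr);
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int rr = idx % nr, cc = idx / nr;
        for (int k = 0; k < nn; ++k) {
          int r2 = rr + dr8[k], c2 = cc + dc8[k];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (occ(r2, c2) && lab(r2, c2) == 0) {
            lab(r2, c2) = next;
            stack.push_back(r2 + c2 * nr);
          }
        }
      }
    }
  }
  return lab;
}
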