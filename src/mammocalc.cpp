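#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Forest traversal over a sample matrix. The forest is passed flattened:
// nodes of all trees concatenated, `tree_offset` giving each root (1-based).
// feature == 0 marks a leaf; split predicate is strict x < threshold (left).
// [[Rcpp::export]]
NumericVector rcpp_forest_predict(NumericMatrix X,
                                  IntegerVector tree_offset,
                                  IntegerVector feature,
                                  NumericVector threshold,
                                  IntegerVector left,
                                  IntegerVector right,
                                  NumericVector p1) {
  const int n = X.nrow();
  const int n_trees = tree_offset.size();
  NumericVector out(n);
  for (int t = 0; t < n_trees; ++t) {
    const int root = tree_offset[t] - 1;
    for (int i = 0; i < n; ++i) {
      int node = root;
      while (feature[node] != 0) {
        const double x = X(i, feature[node] - 1);
        node = (x < threshold[node]) ? (left[node] - 1) : (right[node] - 1);
      }
      out[i] += p1[node];
    }
  }
  for (int i = 0; i < n; ++i) out[i] /= n_trees;
  return out;
}

// 8-connected component labelling; labels assigned in row-major scan order
// (row 0 first), matching the package-wide (row, col) convention.
// [[Rcpp::export]]
IntegerMatrix rcpp_label_components(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> stack;
  int next = 0;
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(r + c * nr);
      lab(r, c) = next;
      while (!stack.empty()) {
        const int idx = stack.back();
        stack.pop_back();
        const int cr = idx % nr, cc = idx / nr;
        for (int dr = -1; dr <= 1; ++dr) {
          for (int dc = -1; dc <= 1; ++dc) {
            if (dr == 0 && dc == 0) continue;
            const int r2 = cr + dr, c2 = cc + dc;
            if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
            if (mask(r2, c2) && lab(r2, c2) == 0) {
              lab(r2, c2) = next;
              stack.push_back(r2 + c2 * nr);
            }
          }
        }
      }
    }
  }
  return lab;
}
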