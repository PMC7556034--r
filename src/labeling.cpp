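#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// Connected-component labeling of a logical matrix by iterative flood fill.
// Labels are assigned in raster-scan order of each component's first pixel,
// matching the numbering ImageJ's particle analyzer produces.
// connectivity: 4 (edge neighbors) or 8 (edge + diagonal neighbors).
// [[Rcpp::export(name = ".label_components")]]
IntegerMatrix label_components_cpp(LogicalMatrix mask, int connectivity) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix labels(nr, nc);
  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nnb = (connectivity == 4) ? 4 : 8;
  int next_label = 0;
  std::vector<int> stack;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || labels(r, c) != 0) continue;
      ++next_label;
      labels(r, c) = next_label;
      stack.clear();
      stack.push_back(r + c * nr);
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int cr = idx % nr, cc = idx / nr;
        for (int k = 0; k < nnb; ++k) {
          int rr = cr + dr8[k], cx = cc + dc8[k];
          if (rr < 0 || rr >= nr || cx < 0 || cx >= nc) continue;
          if (mask(rr, cx) && labels(rr, cx) == 0) {
            labels(rr, cx) = next_label;
            stack.push_back(rr + cx * nr);
          }
        }
      }
    }
  }
  return labels;
}
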