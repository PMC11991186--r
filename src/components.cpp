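#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 8-connected component labelling of a logical matrix (BFS flood fill).
// Labels are assigned in raster-scan order of each component's first pixel.
// [[Rcpp::export(name = ".label8_cpp")]]
IntegerMatrix label8_cpp(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<std::pair<int, int> > stack;

  for (int j = 0; j < nc; j++)
    for (int i = 0; i < nr; i++) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      next++;
      stack.clear();
      stack.push_back(std::make_pair(i, j));
      lab(i, j) = next;
      while (!stack.empty()) {
        std::pair<int, int> px = stack.back();
        stack.pop_back();
        for (int dj = -1; dj <= 1; dj++)
          for (int di = -1; di <= 1; di++) {
            if (di == 0 && dj == 0) continue;
            int ii = px.first + di, jj = px.second + dj;
            if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
            if (mask(ii, jj) && lab(ii, jj) == 0) {
              lab(ii, jj) = next;
              stack.push_back(std::make_pair(ii, jj));
            }
          }
      }
    }
  return lab;
}
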