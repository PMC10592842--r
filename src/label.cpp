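// Connected-component labeling with selectable 4- or 8-connectivity
// (EBImage::bwlabel is 4-connected only). Simple BFS flood fill; labels
// are assigned in raster-scan order of each component's first pixel.

#include <Rcpp.h>
#include <queue>

// [[Rcpp::export]]
Rcpp::IntegerMatrix label_components_cpp(Rcpp::LogicalMatrix x,
                                         int connectivity = 8) {
  if (connectivity != 4 && connectivity != 8)
    Rcpp::stop("connectivity must be 4 or 8");
  const int H = x.nrow(), W = x.ncol();
  Rcpp::IntegerMatrix lab(H, W);
  const int dr4[] = {-1, 1, 0, 0};
  const int dc4[] = {0, 0, -1, 1};
  const int dr8[] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int* dr = connectivity == 4 ? dr4 : dr8;
  const int* dc = connectivity == 4 ? dc4 : dc8;
  const int nn = connectivity;
  int next = 0;
  std::queue<std::pair<int, int>> q;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (!x(i, j) || lab(i, j) != 0) continue;
      lab(i, j) = ++next;
      q.push({i, j});
      while (!q.empty()) {
        auto [r, c] = q.front();
        q.pop();
        for (int k = 0; k < nn; ++k) {
          int r2 = r + dr[k], c2 = c + dc[k];
          if (r2 < 0 || r2 >= H || c2 < 0 || c2 >= W) continue;
          if (x(r2, c2) && lab(r2, c2) == 0) {
            lab(r2, c2) = next;
            q.push({r2, c2});
          }
        }
      }
    }
  }
  return lab;
}
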