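#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// 8- (or 4-) connected component labelling of a binary mask by flood fill.
// Labels are assigned in raster scan order (row-major over columns), so the
// output is deterministic.
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(LogicalMatrix mask, bool eight = true) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> stack;
  stack.reserve(256);
  int next = 0;
  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dr4[4] = {-1, 0, 0, 1};
  const int dc4[4] = {0, -1, 1, 0};
  const int nn = eight ? 8 : 4;
  const int* dr = eight ? dr8 : dr4;
  const int* dc = eight ? dc8 : dc4;

  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      stack.push_back(r + c * H);
      lab(r, c) = next;
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int rr = idx % H, cc = idx / H;
        for (int k = 0; k < nn; ++k) {
          int r2 = rr + dr[k], c2 = cc + dc[k];
          if (r2 < 0 || r2 >= H || c2 < 0 || c2 >= W) continue;
          if (mask(r2, c2) && lab(r2, c2) == 0) {
            lab(r2, c2) = next;
            stack.push_back(r2 + c2 * H);
          }
        }
      }
    }
  }
  return lab;
}

// Add isotropic Gaussian spots (amplitude amps[i], s.d. sigma, truncated at
// truncate*sigma) to a frame at sub-pixel positions pos (n x 2, row/col,
// 0-based). Pixel centers sit at integer coordinates.
// [[Rcpp::export]]
NumericMatrix add_gaussian_spots_cpp(NumericMatrix frame, NumericMatrix pos,
                                     NumericVector amps, double sigma,
                                     double truncate = 4.0) {
  NumericMatrix out = clone(frame);
  const int H = out.nrow(), W = out.ncol();
  const int n = pos.nrow();
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  const int halo = (int)std::ceil(truncate * sigma);
  for (int i = 0; i < n; ++i) {
    double r0 = pos(i, 0), c0 = pos(i, 1), a = amps[i];
    if (!R_finite(r0) || !R_finite(c0) || a == 0.0) continue;
    int rlo = std::max(0, (int)std::floor(r0) - halo);
    int rhi = std::min(H - 1, (int)std::ceil(r0) + halo);
    int clo = std::max(0, (int)std::floor(c0) - halo);
    int chi = std::min(W - 1, (int)std::ceil(c0) + halo);
    for (int c = clo; c <= chi; ++c) {
      double dc = c - c0;
      for (int r = rlo; r <= rhi; ++r) {
        double dr = r - r0;
        out(r, c) += a * std::exp(-(dr * dr + dc * dc) * inv2s2);
      }
    }
  }
  return out;
}
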