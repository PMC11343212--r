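// Small image utilities for the segmentation picker: disc dilation and
// soft-profile filament rasterization.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Binary dilation with a Euclidean disc of the given radius (pixels).
// [[Rcpp::export]]
IntegerMatrix dilate_disc_cpp(IntegerMatrix img, double radius) {
  const int nr = img.nrow(), nc = img.ncol();
  const int R = (int) std::floor(radius);
  std::vector<std::pair<int,int> > offs;
  for (int dr = -R; dr <= R; ++dr)
    for (int dc = -R; dc <= R; ++dc)
      if (dr*dr + dc*dc <= radius*radius) offs.push_back(std::make_pair(dr, dc));
  IntegerMatrix out(nr, nc);
  for (int r = 0; r < nr; ++r) for (int c = 0; c < nc; ++c) {
    if (!img(r, c)) continue;
    for (size_t q = 0; q < offs.size(); ++q) {
      int rr = r + offs[q].first, cc = c + offs[q].second;
      if (rr >= 0 && rr < nr && cc >= 0 && cc < nc) out(rr, cc) = 1;
    }
  }
  return out;
}

// Remove pixels of img within `radius` of any seed pixel.
// [[Rcpp::export]]
IntegerMatrix clear_discs_cpp(IntegerMatrix img, IntegerMatrix seeds, double radius) {
  IntegerMatrix mask = dilate_disc_cpp(seeds, radius);
  IntegerMatrix out = clone(img);
  for (int q = 0; q < out.size(); ++q) if (mask[q]) out[q] = 0;
  return out;
}

// Rasterize polyline paths with a Gaussian cross-section profile.
// pts: m x 2 (row, col, 0-based, pixel centres), path_id unused except
// continuity; intensity at a pixel is max over path points of
// exp(-d^2 / (2 sigma^2)).
// [[Rcpp::export]]
NumericMatrix raster_paths_cpp(int nrow, int ncol, NumericMatrix pts, double sigma) {
  NumericMatrix out(nrow, ncol);
  const int R = (int) std::ceil(3.5 * sigma);
  for (int q = 0; q < pts.nrow(); ++q) {
    double pr = pts(q, 0), pc = pts(q, 1);
    int r0 = std::max(0, (int) std::floor(pr) - R);
    int r1 = std::min(nrow - 1, (int) std::ceil(pr) + R);
    int c0 = std::max(0, (int) std::floor(pc) - R);
    int c1 = std::min(ncol - 1, (int) std::ceil(pc) + R);
    for (int r = r0; r <= r1; ++r) for (int c = c0; c <= c1; ++c) {
      double d2 = (r - pr) * (r - pr) + (c - pc) * (c - pc);
      double v = std::exp(-d2 / (2.0 * sigma * sigma));
      if (v > out(r, c)) out(r, c) = v;
    }
  }
  return out;
}
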