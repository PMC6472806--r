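#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 8-connected component labeling of a binary mask by iterative flood fill.
// Labels are 1-based in raster-scan discovery order; background is 0.
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix labels(nr, nc);
  std::vector<int> stack;
  int next_label = 0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || labels(i, j) != 0) continue;
      ++next_label;
      stack.push_back(i + j * nr);
      labels(i, j) = next_label;
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int ci = idx % nr, cj = idx / nr;
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0) continue;
            int ni = ci + di, nj = cj + dj;
            if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
            if (mask(ni, nj) && labels(ni, nj) == 0) {
              labels(ni, nj) = next_label;
              stack.push_back(ni + nj * nr);
            }
          }
        }
      }
    }
  }
  return labels;
}

// Minimum distance from each query point to a polyline given by vertices.
// Points and vertices are (x, y) pairs; used by the synthetic renderer.
// [[Rcpp::export]]
NumericVector dist_to_polyline_cpp(const NumericVector& px,
                                   const NumericVector& py,
                                   const NumericVector& vx,
                                   const NumericVector& vy) {
  const int n = px.size(), m = vx.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    for (int s = 0; s + 1 < m; ++s) {
      double ax = vx[s], ay = vy[s];
      double dx = vx[s + 1] - ax, dy = vy[s + 1] - ay;
      double len2 = dx * dx + dy * dy;
      double t = 0.0;
      if (len2 > 0) {
        t = ((px[i] - ax) * dx + (py[i] - ay) * dy) / len2;
        if (t < 0) t = 0;
        if (t > 1) t = 1;
      }
      double ex = px[i] - (ax + t * dx), ey = py[i] - (ay + t * dy);
      double d2 = ex * ex + ey * ey;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
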