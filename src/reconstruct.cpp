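#include <Rcpp.h>
using namespace Rcpp;

// Grayscale morphological reconstruction by dilation (8-connected),
// computed with alternating forward/backward raster scans until stable.
// marker must be <= image everywhere; the result is the largest function
// below `image` obtainable by iterated geodesic dilation of `marker`.
// [[Rcpp::export(name = ".reconstruct_cpp")]]
NumericMatrix reconstruct_cpp(NumericMatrix marker, NumericMatrix image,
                              int max_sweeps = 100) {
  int nr = marker.nrow(), nc = marker.ncol();
  NumericMatrix rec(clone(marker));
  for (int sweep = 0; sweep < max_sweeps; ++sweep) {
    bool changed = false;
    // forward: neighbours already visited are W, NW, N, NE
    for (int j = 0; j < nc; ++j) {
      for (int i = 0; i < nr; ++i) {
        double v = rec(i, j);
        if (i > 0 && rec(i - 1, j) > v) v = rec(i - 1, j);
        if (j > 0) {
          if (rec(i, j - 1) > v) v = rec(i, j - 1);
          if (i > 0 && rec(i - 1, j - 1) > v) v = rec(i - 1, j - 1);
          if (i < nr - 1 && rec(i + 1, j - 1) > v) v = rec(i + 1, j - 1);
        }
        if (v > image(i, j)) v = image(i, j);
        if (v > rec(i, j)) { rec(i, j) = v; changed = true; }
      }
    }
    // backward: E, SE, S, SW
    for (int j = nc - 1; j >= 0; --j) {
      for (int i = nr - 1; i >= 0; --i) {
        double v = rec(i, j);
        if (i < nr - 1 && rec(i + 1, j) > v) v = rec(i + 1, j);
        if (j < nc - 1) {
          if (rec(i, j + 1) > v) v = rec(i, j + 1);
          if (i < nr - 1 && rec(i + 1, j + 1) > v) v = rec(i + 1, j + 1);
          if (i > 0 && rec(i - 1, j + 1) > v) v = rec(i - 1, j + 1);
        }
        if (v > image(i, j)) v = image(i, j);
        if (v > rec(i, j)) { rec(i, j) = v; changed = true; }
      }
    }
    if (!changed) break;
  }
  return rec;
}
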