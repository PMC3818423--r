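// Nearest-seed assignment of every pixel centre of an h x w frame.
// Brute force over seeds; ties broken by lowest seed index, so labelling
// is fully deterministic.
#include <Rcpp.h>

// [[Rcpp::export(name = ".nearest_seed")]]
Rcpp::IntegerMatrix nearest_seed(const Rcpp::NumericMatrix& pts,
                                 int w, int h) {
  int n = pts.nrow();
  Rcpp::IntegerMatrix lab(h, w);
  std::vector<double> pr(n), pc(n);
  for (int k = 0; k < n; ++k) { pr[k] = pts(k, 0); pc[k] = pts(k, 1); }
  for (int j = 0; j < w; ++j) {
    double cx = j + 0.5;
    for (int i = 0; i < h; ++i) {
      double cy = i + 0.5;
      double best = R_PosInf;
      int arg = 0;
      for (int k = 0; k < n; ++k) {
        double dy = pr[k] - cy, dx = pc[k] - cx;
        double d2 = dy * dy + dx * dx;
        if (d2 < best) { best = d2; arg = k; }
      }
      lab(i, j) = arg + 1;
    }
  }
  return lab;
}
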