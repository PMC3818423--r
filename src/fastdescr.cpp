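// Fast evaluation of the 2-PC separation descriptor for many candidate
// feature subsets. For a candidate subset J of the (normalized) image
// feature table X with covariance S and two groups of sizes nA, nB:
//   tr(T) = (N-1) * (lambda_1 + lambda_2)   of S[J,J]
//   tr(B) = nA*nB/N * || V' d[J] ||^2       d = group mean difference
//   descriptor = tr(B) / (tr(T) - tr(B))
// which equals trace(B)/trace(W) of the scatter of the top-2 PC scores.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// [[Rcpp::export(name = ".eval_descriptors")]]
Rcpp::NumericVector eval_descriptors(const arma::mat& S, const arma::vec& d,
                                     const Rcpp::List& subsets,
                                     double cab, double nm1) {
  int m = subsets.size();
  Rcpp::NumericVector out(m);
  for (int i = 0; i < m; ++i) {
    arma::uvec idx = Rcpp::as<arma::uvec>(subsets[i]) - 1;
    arma::mat sub = S.submat(idx, idx);
    arma::vec dj = d.elem(idx);
    double trB, trT, l1, l2;
    if (idx.n_elem == 2) {
      // top-2 PCs of a 2x2 span the whole plane: ||V'd||^2 = ||d||^2
      double tr = arma::trace(sub);
      double det = sub(0, 0) * sub(1, 1) - sub(0, 1) * sub(1, 0);
      double disc = std::sqrt(std::max(tr * tr / 4.0 - det, 0.0));
      l1 = tr / 2.0 + disc;
      l2 = tr / 2.0 - disc;
      trT = nm1 * tr;
      trB = cab * arma::dot(dj, dj);
    } else {
      arma::vec eigval;
      arma::mat eigvec;
      arma::eig_sym(eigval, eigvec, sub);   // ascending
      int k = eigval.n_elem;
      l1 = eigval(k - 1);
      l2 = eigval(k - 2);
      trT = nm1 * (l1 + l2);
      arma::vec p = eigvec.cols(k - 2, k - 1).t() * dj;
      trB = cab * arma::dot(p, p);
    }
    // rank-deficient candidates (collinear features) admit no 2-D
    // projection and are never selected
    if (l2 <= 1e-10 * std::max(l1, 1e-300)) { out[i] = R_NegInf; continue; }
    double trW = trT - trB;
    out[i] = (trW > 0) ? trB / trW : R_PosInf;
  }
  return out;
}
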