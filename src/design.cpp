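#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// All-atom analytic signal matrix (M x N) for one fascicle orientation.
// Inputs are the per-scheme precomputations: b (ms/um^2), GPA beta table
// (M x n_radii), radius quadrature weights, gradient directions and the
// b = 0 mask; plus the (fvf, Dex) atom grid and the orientation u.
// [[Rcpp::export(name = ".designBlockCpp")]]
arma::mat design_block_cpp(const arma::vec& b, const arma::mat& B,
                           const arma::vec& wr, const arma::mat& dirs,
                           const arma::uvec& b0, double dIn,
                           const arma::vec& fvf, const arma::vec& dex,
                           const arma::vec& u) {
  const int M = b.n_elem, N = fvf.n_elem, nr = wr.n_elem;
  vec ct = dirs * u;
  vec c2 = square(ct);
  vec s2 = clamp(1.0 - c2, 0.0, 1.0);
  // intra-axonal signal: atom-independent
  vec sIn(M);
  for (int m = 0; m < M; ++m) {
    double acc = 0;
    for (int r = 0; r < nr; ++r) acc += wr(r) * std::exp(-B(m, r) * s2(m));
    sIn(m) = std::exp(-b(m) * dIn * c2(m)) * acc;
  }
  mat A(M, N);
  vec e1 = -b % c2;                  // multiplies Dex
  vec e2 = -b % s2;                  // multiplies Dex (1 - fvf)
  for (int a = 0; a < N; ++a) {
    const double dx = dex(a), f = fvf(a), dxt = dx * (1.0 - f);
    for (int m = 0; m < M; ++m) {
      const double sEx = std::exp(e1(m) * dx + e2(m) * dxt);
      A(m, a) = f * sIn(m) + (1.0 - f) * sEx;
    }
  }
  for (unsigned int i = 0; i < b0.n_elem; ++i)
    if (b0(i)) A.row(i).fill(1.0);
  return A;
}
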