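#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Fused dense layer: pre = X W + b, A = relu(pre) with inverted dropout.
// The returned mask M combines the ReLU derivative and the dropout scaling
// (entries are 0 or 1/keep), so the backward pass is a single elementwise
// product.  Dropout draws come from R's RNG (seed-reproducible).
// [[Rcpp::export(name = ".denseFwdCpp")]]
Rcpp::List dense_fwd(const arma::mat& X, const arma::mat& W,
                     const arma::vec& b, double keep, bool train) {
  mat pre = X * W;
  pre.each_row() += b.t();
  mat M(pre.n_rows, pre.n_cols);
  if (train && keep < 1.0) {
    Rcpp::RNGScope scope;
    const double inv = 1.0 / keep;
    for (uword j = 0; j < pre.n_cols; ++j)
      for (uword i = 0; i < pre.n_rows; ++i)
        M(i, j) = (pre(i, j) > 0 && R::unif_rand() < keep) ? inv : 0.0;
  } else {
    for (uword j = 0; j < pre.n_cols; ++j)
      for (uword i = 0; i < pre.n_rows; ++i)
        M(i, j) = pre(i, j) > 0 ? 1.0 : 0.0;
  }
  mat A = pre % M;
  return Rcpp::List::create(Rcpp::Named("A") = A, Rcpp::Named("M") = M);
}

// gradients of a fused dense layer; dA is the loss gradient at the output
// [[Rcpp::export(name = ".denseBwdCpp")]]
Rcpp::List dense_bwd(const arma::mat& X, const arma::mat& W,
                     const arma::mat& M, const arma::mat& dA) {
  mat dPre = dA % M;
  mat dW = X.t() * dPre;
  vec db = sum(dPre, 0).t();
  mat dX = dPre * W.t();
  return Rcpp::List::create(Rcpp::Named("dW") = dW, Rcpp::Named("db") = db,
                            Rcpp::Named("dX") = dX);
}

// in-place Adam update on parameter/moment buffers owned by the training
// loop (never aliased elsewhere)
// [[Rcpp::export(name = ".adamInplaceCpp")]]
void adam_inplace(Rcpp::NumericVector p, Rcpp::NumericVector g,
                  Rcpp::NumericVector m, Rcpp::NumericVector v,
                  double t, double lr, double b1, double b2, double eps) {
  const R_xlen_t n = p.size();
  const double c1 = 1.0 - std::pow(b1, t), c2 = 1.0 - std::pow(b2, t);
  for (R_xlen_t i = 0; i < n; ++i) {
    m[i] = b1 * m[i] + (1.0 - b1) * g[i];
    v[i] = b2 * v[i] + (1.0 - b2) * g[i] * g[i];
    p[i] -= lr * (m[i] / c1) / (std::sqrt(v[i] / c2) + eps);
  }
}
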