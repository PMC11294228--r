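#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Lawson-Hanson active-set non-negative least squares:
//   minimize ||A x - y||_2  subject to  x >= 0.
// Returns the solution, the residual norm and the number of inner
// least-squares iterations.  `tol` is the dual-feasibility tolerance on the
// gradient A'(y - Ax); a negative value selects a machine-precision based
// default.
// [[Rcpp::export(name = ".nnlsCpp")]]
Rcpp::List nnls_cpp(const arma::mat& A, const arma::vec& y,
                    double tol = -1.0, int maxit = -1) {
  const int n = A.n_cols;
  if ((int)y.n_elem != (int)A.n_rows)
    Rcpp::stop("dimension mismatch between A and y");
  if (!A.is_finite() || !y.is_finite())
    Rcpp::stop("non-finite entries in NNLS input");

  vec x(n, fill::zeros);
  std::vector<bool> inP(n, false);
  if (maxit <= 0) maxit = 10 * n + 50;
  if (tol < 0)
    tol = 10.0 * datum::eps * norm(A, 1) * std::max(A.n_rows, A.n_cols);

  int iter = 0;
  vec w = A.t() * y;            // gradient at x = 0
  double lastRss = datum::inf;
  int stalled = 0;

  while (true) {
    // most positive gradient among zero-set variables
    int t = -1;
    double wmax = tol;
    for (int j = 0; j < n; ++j)
      if (!inP[j] && w(j) > wmax) { wmax = w(j); t = j; }
    if (t < 0) break;
    inP[t] = true;

    int innerPasses = 0;
    while (true) {
      if (++innerPasses > 100) break;   // cycling among collinear columns
      if (++iter > maxit) { Rcpp::warning("NNLS iteration limit reached"); break; }
      uvec idx(n);
      int np = 0;
      for (int j = 0; j < n; ++j) if (inP[j]) idx(np++) = j;
      idx.resize(np);
      mat Ap = A.cols(idx);
      vec z;
      bool ok = solve(z, Ap, y);     // least squares on the passive set
      if (!ok) { z = pinv(Ap) * y; }

      if (z.min() > 0) {
        x.zeros();
        x(idx) = z;
        break;
      }
      // step toward z until the first passive variable hits zero
      double alpha = datum::inf;
      for (int k = 0; k < np; ++k) {
        if (z(k) <= 0) {
          double xi = x(idx(k));
          double a = xi / (xi - z(k));
          if (a < alpha) alpha = a;
        }
      }
      for (int k = 0; k < np; ++k)
        x(idx(k)) += alpha * (z(k) - x(idx(k)));
      for (int k = 0; k < np; ++k) {
        if (x(idx(k)) <= 10.0 * datum::eps * std::abs(alpha)) {
          x(idx(k)) = 0.0;
          inP[idx(k)] = false;
        }
      }
    }
    if (iter > maxit) break;
    vec r = y - A * x;
    // anti-cycling: once the fit stops improving to machine precision the
    // remaining dual violations are numerical noise among collinear columns
    double rss = dot(r, r);
    if (lastRss - rss < 1e-14 * (rss + 1e-300)) {
      if (++stalled >= 5) break;
    } else stalled = 0;
    lastRss = rss;
    w = A.t() * r;
  }

  double rnorm = norm(y - A * x, 2);
  return Rcpp::List::create(Rcpp::Named("x") = x,
                            Rcpp::Named("residual") = rnorm,
                            Rcpp::Named("iterations") = iter);
}
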