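#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Exhaustive fingerprint matching for K = 2 fascicles.
//
// Every pair (i, j) of atoms from the two rotated sub-dictionaries defines a
// 2-variable NNLS sub-problem; with the Gram quantities precomputed, its
// optimum has a closed form via support enumeration (exact for 2 variables:
// if the unconstrained solution is feasible it is optimal, otherwise the
// best feasible single-atom support wins).  The pair scan runs in
// (i-major, j-minor) order with strict improvement, so ties resolve to the
// lowest combined index.
//
// G12:  t(C1) %*% C2,   a1: t(C1) %*% y,   a2: t(C2) %*% y,
// n1/n2: squared column norms, yty: ||y||^2.
// [[Rcpp::export(name = ".exhaustivePairsCpp")]]
Rcpp::List exhaustive_pairs_cpp(const arma::mat& G12,
                                const arma::vec& a1, const arma::vec& a2,
                                const arma::vec& n1, const arma::vec& n2,
                                double yty) {
  const int N1 = a1.n_elem, N2 = a2.n_elem;
  double qbest = -1.0;         // reduction in ||y||^2; q = 0 is always feasible
  int ibest = 0, jbest = 0;
  double w1best = 0.0, w2best = 0.0;
  const double tiny = 1e-14;

  for (int i = 0; i < N1; ++i) {
    const double a1i = a1(i), n1i = n1(i);
    const double q1 = (a1i > 0 && n1i > tiny) ? a1i * a1i / n1i : 0.0;
    for (int j = 0; j < N2; ++j) {
      const double g = G12(i, j), a2j = a2(j), n2j = n2(j);
      double q, w1, w2;
      const double det = n1i * n2j - g * g;
      bool interior = false;
      if (det > tiny * n1i * n2j) {
        w1 = (n2j * a1i - g * a2j) / det;
        w2 = (n1i * a2j - g * a1i) / det;
        if (w1 >= 0 && w2 >= 0) {
          q = w1 * a1i + w2 * a2j;
          interior = true;
        }
      }
      if (!interior) {
        const double q2 = (a2j > 0 && n2j > tiny) ? a2j * a2j / n2j : 0.0;
        if (q1 >= q2) { q = q1; w1 = (q1 > 0) ? a1i / n1i : 0.0; w2 = 0.0; }
        else          { q = q2; w2 = a2j / n2j;               w1 = 0.0; }
      }
      if (q > qbest) {
        qbest = q; ibest = i; jbest = j; w1best = w1; w2best = w2;
      }
    }
  }
  if (qbest < 0) qbest = 0;
  double r2 = yty - qbest;
  if (r2 < 0) r2 = 0;
  return Rcpp::List::create(
      Rcpp::Named("idx") = Rcpp::IntegerVector::create(ibest + 1, jbest + 1),
      Rcpp::Named("w") = Rcpp::NumericVector::create(w1best, w2best),
      Rcpp::Named("residual") = std::sqrt(r2),
      Rcpp::Named("nSolves") = (double)N1 * (double)N2);
}

// Exhaustive matching for K = 3 fascicles.  Each triple's 3-variable NNLS is
// solved exactly by enumerating all non-empty supports; the constrained
// optimum is the feasible support with the largest reduction a_S' G_S^-1 a_S.
// [[Rcpp::export(name = ".exhaustiveTriplesCpp")]]
Rcpp::List exhaustive_triples_cpp(const arma::mat& G12, const arma::mat& G13,
                                  const arma::mat& G23,
                                  const arma::vec& a1, const arma::vec& a2,
                                  const arma::vec& a3,
                                  const arma::vec& n1, const arma::vec& n2,
                                  const arma::vec& n3, double yty) {
  const int N1 = a1.n_elem, N2 = a2.n_elem, N3 = a3.n_elem;
  const double tiny = 1e-14;
  double qbest = -1.0;
  int ib = 0, jb = 0, kb = 0;
  double wb[3] = {0, 0, 0};

  for (int i = 0; i < N1; ++i) {
    const double A1 = a1(i), N1i = n1(i);
    const double q1 = (A1 > 0 && N1i > tiny) ? A1 * A1 / N1i : 0.0;
    for (int j = 0; j < N2; ++j) {
      const double A2 = a2(j), N2j = n2(j), g12 = G12(i, j);
      const double q2 = (A2 > 0 && N2j > tiny) ? A2 * A2 / N2j : 0.0;
      // pair {1,2}
      double q12 = -1, w12a = 0, w12b = 0;
      {
        const double det = N1i * N2j - g12 * g12;
        if (det > tiny * N1i * N2j) {
          const double u = (N2j * A1 - g12 * A2) / det;
          const double v = (N1i * A2 - g12 * A1) / det;
          if (u >= 0 && v >= 0) { q12 = u * A1 + v * A2; w12a = u; w12b = v; }
        }
      }
      for (int k = 0; k < N3; ++k) {
        const double A3 = a3(k), N3k = n3(k);
        const double g13 = G13(i, k), g23 = G23(j, k);
        double q = 0, w1 = 0, w2 = 0, w3 = 0;
        // full support {1,2,3} by Cramer
        const double det3 = N1i * (N2j * N3k - g23 * g23)
                          - g12 * (g12 * N3k - g23 * g13)
                          + g13 * (g12 * g23 - N2j * g13);
        if (std::abs(det3) > tiny * N1i * N2j * N3k) {
          const double u = (A1 * (N2j * N3k - g23 * g23)
                          - g12 * (A2 * N3k - g23 * A3)
                          + g13 * (A2 * g23 - N2j * A3)) / det3;
          const double v = (N1i * (A2 * N3k - A3 * g23)
                          - A1 * (g12 * N3k - g23 * g13)
                          + g13 * (g12 * A3 - A2 * g13)) / det3;
          const double t = (N1i * (N2j * A3 - g23 * A2)
                          - g12 * (g12 * A3 - A2 * g13)
                          + A1 * (g12 * g23 - N2j * g13)) / det3;
          if (u >= 0 && v >= 0 && t >= 0) {
            q = u * A1 + v * A2 + t * A3; w1 = u; w2 = v; w3 = t;
          }
        }
        // pairs and singletons
        auto tryPair = [&](double na, double nb2, double gab, double Aa,
                           double Ab, int ia, int ibb) {
          const double det = na * nb2 - gab * gab;
          if (det <= tiny * na * nb2) return;
          const double u = (nb2 * Aa - gab * Ab) / det;
          const double v = (na * Ab - gab * Aa) / det;
          if (u >= 0 && v >= 0) {
            const double qq = u * Aa + v * Ab;
            if (qq > q) {
              q = qq; w1 = w2 = w3 = 0;
              if (ia == 0) w1 = u; else if (ia == 1) w2 = u; else w3 = u;
              if (ibb == 0) w1 = v; else if (ibb == 1) w2 = v; else w3 = v;
            }
          }
        };
        if (q12 > q) { q = q12; w1 = w12a; w2 = w12b; w3 = 0; }
        tryPair(N1i, N3k, g13, A1, A3, 0, 2);
        tryPair(N2j, N3k, g23, A2, A3, 1, 2);
        const double q3 = (A3 > 0 && N3k > tiny) ? A3 * A3 / N3k : 0.0;
        if (q1 > q) { q = q1; w1 = A1 / N1i; w2 = w3 = 0; }
        if (q2 > q) { q = q2; w2 = A2 / N2j; w1 = w3 = 0; }
        if (q3 > q) { q = q3; w3 = A3 / N3k; w1 = w2 = 0; }

        if (q > qbest) {
          qbest = q; ib = i; jb = j; kb = k;
          wb[0] = w1; wb[1] = w2; wb[2] = w3;
        }
      }
    }
  }
  if (qbest < 0) qbest = 0;
  double r2 = yty - qbest;
  if (r2 < 0) r2 = 0;
  return Rcpp::List::create(
      Rcpp::Named("idx") = Rcpp::IntegerVector::create(ib + 1, jb + 1, kb + 1),
      Rcpp::Named("w") = Rcpp::NumericVector::create(wb[0], wb[1], wb[2]),
      Rcpp::Named("residual") = std::sqrt(r2),
      Rcpp::Named("nSolves") = (double)N1 * (double)N2 * (double)N3);
}
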