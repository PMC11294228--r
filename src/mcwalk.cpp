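#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Monte Carlo random walk in a periodic 2D packing of parallel cylinders
// (axis = z), with impermeable membranes, under a rectangular-lobe PGSE
// sequence.  Spins diffuse freely along z; restriction acts in the xy plane.
// Boundary handling: a step crossing a membrane is reflected radially
// (mirror about the circle); if the mirrored position is still invalid the
// step is rejected.  Phase accrual uses the identity
//   phi_m = gamma * G_m * dt * g_m . (sum_{t in lobe1} x_t - sum_{t in lobe2} x_t),
// so trajectories are walked once and shared by all measurements.
//
// Units: um, ms, mT/m; gamma_eff in rad / (um * (mT/m) * ms).
// [[Rcpp::export(name = ".mcWalkCpp")]]
Rcpp::List mc_walk_cpp(const arma::mat& centers, const arma::vec& radii,
                       double L, double D_in, double D_ex,
                       const arma::mat& gdir, const arma::vec& G,
                       double delta, double Delta, double dt,
                       int n_intra, int n_extra, int seed,
                       double gamma_eff) {
  const int ncyl = centers.n_rows;
  const int M = gdir.n_rows;
  const int nsteps = (int)std::ceil((Delta + delta) / dt);
  const double sig_in = std::sqrt(2.0 * D_in * dt);
  const double sig_ex = std::sqrt(2.0 * D_ex * dt);

  std::mt19937_64 rng((uint64_t)seed);
  std::normal_distribution<double> gauss(0.0, 1.0);
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  // cell list over the periodic box for extra-axonal collision checks
  int nb = 1;
  std::vector<std::vector<int>> bins;
  double bw = L;
  if (ncyl > 0 && L > 0) {
    double rmax = radii.max();
    nb = std::max(1, (int)std::floor(L / std::max(2.0 * rmax, L / 16.0)));
    bw = L / nb;
    bins.assign(nb * nb, {});
    for (int c = 0; c < ncyl; ++c) {
      int x0 = (int)std::floor((centers(c, 0) - radii(c)) / bw);
      int x1 = (int)std::floor((centers(c, 0) + radii(c)) / bw);
      int y0 = (int)std::floor((centers(c, 1) - radii(c)) / bw);
      int y1 = (int)std::floor((centers(c, 1) + radii(c)) / bw);
      for (int bx = x0; bx <= x1; ++bx)
        for (int by = y0; by <= y1; ++by) {
          int wx = ((bx % nb) + nb) % nb, wy = ((by % nb) + nb) % nb;
          bins[wx * nb + wy].push_back(c);
        }
    }
  }
  auto insideCyl = [&](double x, double y, int& hit) -> bool {
    if (ncyl == 0) return false;
    double xw = x - L * std::floor(x / L);
    double yw = y - L * std::floor(y / L);
    int bx = std::min(nb - 1, (int)(xw / bw)), by = std::min(nb - 1, (int)(yw / bw));
    for (int c : bins[bx * nb + by]) {
      double dx = xw - centers(c, 0); dx -= L * std::round(dx / L);
      double dy = yw - centers(c, 1); dy -= L * std::round(dy / L);
      if (dx * dx + dy * dy < radii(c) * radii(c)) { hit = c; return true; }
    }
    return false;
  };

  const int lobe1_end = (int)std::ceil(delta / dt);
  const int lobe2_start = (int)std::floor(Delta / dt);

  vec cosS(M, fill::zeros), sinS(M, fill::zeros);
  vec cosI(M, fill::zeros), sinI(M, fill::zeros);
  vec cosE(M, fill::zeros), sinE(M, fill::zeros);

  // sample intra spins proportional to cylinder cross-section r^2
  vec cumw;
  if (ncyl > 0) {
    cumw = cumsum(square(radii));
    cumw /= cumw(ncyl - 1);
  }

  const int ntot = n_intra + n_extra;
  for (int s = 0; s < ntot; ++s) {
    const bool intra = s < n_intra;
    double x = 0, y = 0, z = 0;     // unwrapped coordinates
    int mycyl = -1;
    if (intra) {
      double u = unif(rng);
      mycyl = 0;
      while (cumw(mycyl) < u) ++mycyl;
      const double r = radii(mycyl);
      double rr = r * std::sqrt(unif(rng));
      double th = 2.0 * datum::pi * unif(rng);
      x = centers(mycyl, 0) + rr * std::cos(th);
      y = centers(mycyl, 1) + rr * std::sin(th);
    } else {
      int hit;
      int tries = 0;
      do {
        x = L > 0 ? L * unif(rng) : unif(rng);
        y = L > 0 ? L * unif(rng) : unif(rng);
        if (++tries > 100000) Rcpp::stop("cannot seed extra-axonal spin");
      } while (insideCyl(x, y, hit));
    }

    double X1x = 0, X1y = 0, X1z = 0, X2x = 0, X2y = 0, X2z = 0;
    const double sig = intra ? sig_in : sig_ex;

    for (int t = 0; t < nsteps; ++t) {
      double nx = x + sig * gauss(rng);
      double ny = y + sig * gauss(rng);
      double nz = z + sig * gauss(rng);
      if (intra) {
        double dx = nx - centers(mycyl, 0), dy = ny - centers(mycyl, 1);
        double d = std::sqrt(dx * dx + dy * dy);
        const double r = radii(mycyl);
        if (d > r) {
          double dnew = 2.0 * r - d;        // radial mirror
          if (dnew < 0) dnew = r * 0.999;   // oversized step: clamp at wall
          nx = centers(mycyl, 0) + dx / d * dnew;
          ny = centers(mycyl, 1) + dy / d * dnew;
        }
      } else if (ncyl > 0) {
        int hit;
        if (insideCyl(nx, ny, hit)) {
          // mirror out of the hit cylinder (in wrapped coordinates)
          double xw = nx - L * std::floor(nx / L);
          double yw = ny - L * std::floor(ny / L);
          double dx = xw - centers(hit, 0); dx -= L * std::round(dx / L);
          double dy = yw - centers(hit, 1); dy -= L * std::round(dy / L);
          double d = std::sqrt(dx * dx + dy * dy);
          const double r = radii(hit);
          if (d > 1e-12) {
            double push = (2.0 * r - d) - d;   // displacement along (dx,dy)/d
            double cx = nx + dx / d * push;
            double cy = ny + dy / d * push;
            int hit2;
            if (!insideCyl(cx, cy, hit2)) { nx = cx; ny = cy; }
            else { nx = x; ny = y; }           // reject
          } else { nx = x; ny = y; }
        }
      }
      x = nx; y = ny; z = nz;
      if (t < lobe1_end)      { X1x += x; X1y += y; X1z += z; }
      else if (t >= lobe2_start) { X2x += x; X2y += y; X2z += z; }
    }

    const double ddx = X1x - X2x, ddy = X1y - X2y, ddz = X1z - X2z;
    for (int m = 0; m < M; ++m) {
      const double phi = gamma_eff * G(m) * dt *
        (gdir(m, 0) * ddx + gdir(m, 1) * ddy + gdir(m, 2) * ddz);
      const double cp = std::cos(phi), sp = std::sin(phi);
      cosS(m) += cp; sinS(m) += sp;
      if (intra) { cosI(m) += cp; sinI(m) += sp; }
      else       { cosE(m) += cp; sinE(m) += sp; }
    }
  }

  vec S = sqrt(square(cosS) + square(sinS)) / std::max(1, ntot);
  vec Si = n_intra > 0 ? vec(sqrt(square(cosI) + square(sinI)) / n_intra)
                       : vec(M, fill::zeros);
  vec Se = n_extra > 0 ? vec(sqrt(square(cosE) + square(sinE)) / n_extra)
                       : vec(M, fill::zeros);
  return Rcpp::List::create(Rcpp::Named("signal") = S,
                            Rcpp::Named("intra") = Si,
                            Rcpp::Named("extra") = Se);
}
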