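# Real even-degree spherical harmonics: basis evaluation and per-shell
# regularized fits.

#' Real even-degree spherical-harmonics basis
#'
#' Evaluates the real orthonormal SH basis restricted to even degrees
#' (sufficient for the antipodally symmetric diffusion signal) at the given
#' unit directions.  Columns are ordered by ascending degree l, with order
#' m running from -l to l within each degree; negative orders carry
#' sin(|m| phi), positive orders cos(m phi).  At lmax = 12 the basis has 91
#' functions.
#'
#' @param dirs n x 3 matrix of unit vectors.
#' @param lmax maximum (even) degree.
#' @return n x sum(2l+1) basis matrix.
#' @export
realEvenShBasis <- function(dirs, lmax = 12) {
  if (lmax %% 2 != 0) stop("lmax must be even")
  dirs <- matrix(as.numeric(dirs), ncol = 3)
  if (!.unitRows(dirs, tol = 1e-6)) stop("directions must be unit vectors")
  ct <- pmin(pmax(dirs[, 3], -1), 1)
  phi <- atan2(dirs[, 2], dirs[, 1])
  n <- nrow(dirs)
  cols <- list()
  for (l in seq(0, lmax, by = 2)) {
    P <- pracma::legendre(l, ct)           # (l+1) x n, orders m = 0..l
    if (l == 0) P <- matrix(P, 1, n)
    for (m in -l:l) {
      am <- abs(m)
      # orthonormal normalization; pracma::legendre includes the
      # Condon-Shortley phase
      nrmc <- sqrt((2 * l + 1) / (4 * pi) *
                     exp(lgamma(l - am + 1) - lgamma(l + am + 1)))
      base <- nrmc * P[am + 1, ]
      y <- if (m < 0) sqrt(2) * base * sin(am * phi)
      else if (m == 0) base
      else sqrt(2) * base * cos(m * phi)
      cols[[length(cols) + 1]] <- y
    }
  }
  B <- do.call(cbind, cols)
  colnames(B) <- unlist(lapply(seq(0, lmax, by = 2), function(l)
    paste0("l", l, "m", -l:l)))
  B
}

# Laplace-Beltrami penalty diagonal l^2 (l+1)^2 in basis column order
.shPenalty <- function(lmax) {
  unlist(lapply(seq(0, lmax, by = 2), function(l) rep(l^2 * (l + 1)^2, 2 * l + 1)))
}

# per-shell ridge solvers for a scheme: list of n_coef x n_dirs matrices
.shSolvers <- function(scheme, lmax, lambda) {
  shells <- sort(unique(scheme@shellIds[scheme@bvalues > 0]))
  solvers <- list()
  for (s in shells) {
    idx <- which(scheme@shellIds == s & scheme@bvalues > 0)
    if (length(idx) < 6)
      stop(sprintf("shell %d has fewer than 6 directions", s))
    B <- realEvenShBasis(scheme@directions[idx, , drop = FALSE], lmax)
    Lp <- diag(lambda * .shPenalty(lmax), ncol(B))
    solvers[[as.character(s)]] <-
      list(idx = idx, solve = solve(crossprod(B) + Lp, t(B)),
           b = stats::median(scheme@bvalues[idx]))
  }
  solvers[order(vapply(solvers, `[[`, numeric(1), "b"))]
}

#' Per-shell spherical-harmonics representation of a voxel signal
#'
#' Fits real even-degree SH coefficients to each nonzero shell separately by
#' ridge-regularized least squares with a Laplace-Beltrami smoothness
#' penalty of weight \code{lambda * l^2 (l+1)^2}.  Shells with fewer
#' directions than coefficients (e.g. 64 directions against 91 coefficients
#' at lmax = 12) are underdetermined and rely on the penalty; the default
#' lambda keeps those fits well-posed.  b = 0 measurements are excluded
#' after being used to normalize the signal.
#'
#' @param y numeric(M) voxel signal.
#' @param scheme an \linkS4class{AcquisitionScheme}.
#' @param lmax maximum even degree (91 coefficients per shell at 12).
#' @param lambda Laplace-Beltrami penalty weight.
#' @return An \linkS4class{SHFeatures} with one coefficient column per
#'   shell, shells ordered by ascending b.
#' @export
fitShPerShell <- function(y, scheme, lmax = 12, lambda = 1e-3) {
  y <- .b0normalize(as.numeric(y), scheme)
  solvers <- .shSolvers(scheme, lmax, lambda)
  co <- vapply(solvers, function(sv) drop(sv$solve %*% y[sv$idx]),
               numeric(sum(2 * seq(0, lmax, 2) + 1)))
  co <- matrix(co, ncol = length(solvers))
  new("SHFeatures", coefficients = co, lmax = as.integer(lmax),
      shellB = vapply(solvers, `[[`, numeric(1), "b"), lambda = lambda)
}

# SH feature matrix for a whole voxel set: n x (n_coef * n_shells),
# shells concatenated in ascending-b order
.shFeatureMatrix <- function(Y, scheme, lmax, lambda) {
  solvers <- .shSolvers(scheme, lmax, lambda)
  b0 <- scheme@bvalues == 0
  Yn <- if (any(b0)) sweep(Y, 2, colMeans(Y[b0, , drop = FALSE]), `/`) else Y
  do.call(cbind, lapply(solvers, function(sv)
    t(sv$solve %*% Yn[sv$idx, , drop = FALSE])))
}
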