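# Analytic single-fascicle forward model and the fingerprint dictionary.
#
# A fascicle is a packing of parallel impermeable cylinders (axis u) with
# gamma-distributed radii inside a hindered extra-axonal space.  The voxel
# signal of one fascicle is the volume-fraction-weighted compartment sum
#   S = fvf * S_in + (1 - fvf) * S_ex.
# S_in combines free diffusion along the axis, exp(-b D_in cos^2 theta),
# with the Gaussian-phase-approximation (GPA, finite-pulse van Gelderen
# series) signal of restricted diffusion across the cylinder section,
# volume-averaged over the radius distribution.  S_ex is a tortuosity-scaled
# axially symmetric tensor: ADC_par = Dex, ADC_perp = Dex * (1 - fvf).

# roots of J1'(x) = 0 used by the GPA series (J1' = J0 - J1/x)
.besselRoots <- function(n = 10) {
  if (!is.null(.pkgEnv$besselRoots) && length(.pkgEnv$besselRoots) >= n)
    return(.pkgEnv$besselRoots[seq_len(n)])
  f <- function(x) besselJ(x, 0) - besselJ(x, 1) / x
  xs <- seq(0.5, 5 + pi * (n + 2), by = 0.01)
  fx <- f(xs)
  sgn <- which(fx[-1] * fx[-length(fx)] < 0)
  roots <- vapply(sgn, function(i)
    stats::uniroot(f, c(xs[i], xs[i + 1]), tol = 1e-12)$root, numeric(1))
  .pkgEnv$besselRoots <- roots
  roots[seq_len(n)]
}

# GPA log-attenuation factor for a cylinder of radius r (um), diffusivity D
# (um^2/ms) under a rectangular PGSE lobe pair of amplitude G (mT/m),
# duration delta and separation Delta (ms), for a gradient fully
# perpendicular to the axis.  The actual exponent at angle theta is
# beta * sin^2(theta).
.gpaBeta <- function(G, delta, Delta, r, D, nroots = 10) {
  mu <- .besselRoots(nroots)
  sapply(r, function(ri) {
    a2 <- (mu / ri)^2                       # alpha_m^2
    e <- function(t) exp(-D * a2 * t)
    num <- 2 * D * a2 * delta - 2 + 2 * e(delta) + 2 * e(Delta) -
      e(Delta - delta) - e(Delta + delta)
    den <- D^2 * a2^3 * (a2 * ri^2 - 1)
    2 * .gammaEff^2 * G^2 * sum(num / den)
  })
}

# volume-weighted (r^2) quadrature of the gamma radius law
.radiusQuadrature <- function(radiusMean, radiusSd, n = 24) {
  shape <- radiusMean^2 / radiusSd^2
  scale <- radiusSd^2 / radiusMean
  lo <- qgamma(1e-4, shape, scale = scale)
  hi <- qgamma(1 - 1e-4, shape, scale = scale)
  gl <- pracma::gaussLegendre(n, lo, hi)
  w <- gl$w * dgamma(gl$x, shape, scale = scale) * gl$x^2
  list(r = gl$x, w = w / sum(w))
}

# Per-scheme precomputation shared by all atom evaluations: b in ms/um^2,
# the GPA beta table (M x n_radii) and the radius quadrature weights.
.schemePrecomp <- function(scheme, radiusMean = 0.5, radiusSd = 0.3,
                           dIn = 2.2, nRadii = 24) {
  key <- sprintf("pre|%s|%g|%g|%g|%d", .dataFingerprint(scheme@bvalues),
                 radiusMean, radiusSd, dIn, nRadii)
  key <- paste0(key, "|", .dataFingerprint(scheme@gradientStrengths),
                "|", scheme@delta, "|", scheme@Delta)
  hit <- .pkgEnv$precomp
  if (!is.null(hit) && identical(hit$key, key)) return(hit)
  q <- .radiusQuadrature(radiusMean, radiusSd)
  G <- scheme@gradientStrengths
  uG <- sort(unique(G[G > 0]))
  Btab <- matrix(0, length(uG), length(q$r))
  for (i in seq_along(uG))
    Btab[i, ] <- .gpaBeta(uG[i], scheme@delta, scheme@Delta, q$r, dIn)
  B <- matrix(0, length(G), length(q$r))
  for (i in seq_along(uG)) B[G == uG[i], ] <- rep(Btab[i, ], each = sum(G == uG[i]))
  pre <- list(key = key, b = .bToMsUm2(scheme@bvalues), dirs = scheme@directions,
              b0 = scheme@bvalues == 0, B = B, wr = q$w, dIn = dIn)
  .pkgEnv$precomp <- pre
  pre
}

# All-atom signal matrix (M x N) for fascicle orientation u, given the grid
# of (fvf, Dex) pairs.  The intra-axonal signal is atom-independent (fixed
# D_in and radius law), so it is evaluated once per orientation.
.fingerprintMatrix <- function(pre, fvf, dex, u) {
  .designBlockCpp(pre$b, pre$B, pre$wr, pre$dirs, pre$b0, pre$dIn,
                  as.numeric(fvf), as.numeric(dex), as.numeric(u))
}

#' Substrate configuration constructor
#'
#' @param radiusMean,radiusSd gamma radius distribution mean and sd (um).
#' @param dIn intra-axonal diffusivity (um^2/ms).
#' @param fvf fiber volume fraction in (0, 0.9].
#' @param dEx extra-axonal diffusivity (um^2/ms).
#' @return A \linkS4class{SubstrateConfig}.
#' @export
substrateConfig <- function(radiusMean = 0.5, radiusSd = 0.3, dIn = 2.2,
                            fvf = 0.5, dEx = 1.5) {
  new("SubstrateConfig", radiusMean = radiusMean, radiusSd = radiusSd,
      dIn = dIn, fvf = fvf, dEx = dEx)
}

#' Dictionary parameter grid
#'
#' Cartesian product of equally spaced fvf and Dex values (fvf-major,
#' endpoints inclusive); the default 38 x 10 grid over fvf in [0.06, 0.8]
#' and Dex in [0.6, 2.4] um^2/ms yields the canonical 380-atom dictionary.
#'
#' @param nFvf,fvfLo,fvfHi fvf grid size and range.
#' @param nDex,dexLo,dexHi Dex grid size and range (um^2/ms).
#' @return data.frame with columns \code{fvf} and \code{dex}.
#' @export
buildParameterGrid <- function(nFvf = 38, fvfLo = 0.06, fvfHi = 0.8,
                               nDex = 10, dexLo = 0.6, dexHi = 2.4) {
  stopifnot(nFvf >= 1, nDex >= 1, fvfLo < fvfHi, dexLo < dexHi)
  fvf <- if (nFvf == 1) fvfLo else seq(fvfLo, fvfHi, length.out = nFvf)
  dex <- if (nDex == 1) dexLo else seq(dexLo, dexHi, length.out = nDex)
  g <- expand.grid(dex = dex, fvf = fvf)[, c(2, 1)]
  rownames(g) <- NULL
  g
}

#' Analytic single-fascicle fingerprint
#'
#' Closed-form compartment-sum signal for one substrate configuration under
#' a PGSE scheme, for a fascicle oriented along \code{u}: GPA cylinder
#' signal (volume-averaged over the gamma radius law) plus a
#' tortuosity-scaled extra-axonal tensor.  b = 0 entries equal 1.
#'
#' @param config a \linkS4class{SubstrateConfig}.
#' @param scheme an \linkS4class{AcquisitionScheme}.
#' @param u unit 3-vector fascicle orientation.
#' @return numeric(M) signal vector in (0, 1].
#' @export
analyticFingerprint <- function(config, scheme, u) {
  validObject(config)
  u <- as.numeric(u)
  if (abs(sqrt(sum(u^2)) - 1) > 1e-6) stop("u must be a unit vector")
  pre <- .schemePrecomp(scheme, config@radiusMean, config@radiusSd, config@dIn)
  drop(.fingerprintMatrix(pre, config@fvf, config@dEx, u))
}

#' Build the single-fascicle fingerprint dictionary
#'
#' One atom per grid row, simulated at the canonical orientation (cylinder
#' axis = z) and normalized to 1 at b = 0.  The default analytic generator
#' evaluates the GPA cylinder + tortuosity-tensor model; the Monte Carlo
#' generator runs the random-walk simulator on a cylinder packing per fvf
#' level (reduced fidelity, intended for cross-checks).
#'
#' @param grid data.frame of (fvf, dex) rows, see
#'   \code{\link{buildParameterGrid}}.
#' @param scheme an \linkS4class{AcquisitionScheme}.
#' @param generator \code{"analytic"} or \code{"montecarlo"}.
#' @param seed RNG seed (Monte Carlo generator).
#' @param substrate base \linkS4class{SubstrateConfig} fixing the radius law
#'   and intra-axonal diffusivity.
#' @param nSpins,dt,nCylinders Monte Carlo dials: walkers per atom, time step
#'   (ms), cylinders per packing.
#' @return A \linkS4class{FingerprintDictionary}.
#' @export
buildDictionary <- function(grid = buildParameterGrid(), scheme,
                            generator = c("analytic", "montecarlo"), seed = 1,
                            substrate = substrateConfig(),
                            nSpins = 10000, dt = 5e-3, nCylinders = 40) {
  generator <- match.arg(generator)
  M <- nMeasurements(scheme)
  if (generator == "analytic") {
    pre <- .schemePrecomp(scheme, substrate@radiusMean, substrate@radiusSd,
                          substrate@dIn)
    A <- .fingerprintMatrix(pre, grid$fvf, grid$dex, c(0, 0, 1))
    atoms <- t(A)
  } else {
    atoms <- matrix(NA_real_, nrow(grid), M)
    for (fv in unique(grid$fvf)) {
      cfg <- substrateConfig(substrate@radiusMean, substrate@radiusSd,
                             substrate@dIn, fvf = fv, dEx = substrate@dEx)
      packing <- packCylinders(cfg, nCylinders, seed = seed)
      rows <- which(grid$fvf == fv)
      for (i in rows) {
        cfg@dEx <- grid$dex[i]
        atoms[i, ] <- mcFingerprint(packing, cfg, scheme, nSpins = nSpins,
                                    dt = dt, seed = seed + i)
      }
    }
    atoms <- pmin(pmax(atoms, 1e-6), 1)
    atoms[, scheme@bvalues == 0] <- 1
  }
  new("FingerprintDictionary", atoms = atoms, params = grid, scheme = scheme,
      generator = generator,
      substrate = list(radiusMean = substrate@radiusMean,
                       radiusSd = substrate@radiusSd, dIn = substrate@dIn))
}

#' @export
setMethod("atoms", "FingerprintDictionary", function(x) x@atoms)
#' @export
setMethod("dictParams", "FingerprintDictionary", function(x) x@params)
#' @export
setMethod("nAtoms", "FingerprintDictionary", function(x) nrow(x@atoms))
#' @export
setMethod("generatorTag", "FingerprintDictionary", function(x) x@generator)
#' @export
setMethod("acquisitionScheme", "FingerprintDictionary", function(x) x@scheme)

setMethod("show", "FingerprintDictionary", function(object) {
  cat(sprintf("FingerprintDictionary: %d atoms x %d measurements (%s)\n",
              nrow(object@atoms), ncol(object@atoms), object@generator))
  cat(sprintf("  fvf in [%g, %g] (%d values), Dex in [%g, %g] um^2/ms (%d values)\n",
              min(object@params$fvf), max(object@params$fvf),
              length(unique(object@params$fvf)),
              min(object@params$dex), max(object@params$dex),
              length(unique(object@params$dex))))
})

#' Rotate the dictionary to a fascicle orientation
#'
#' Returns the M x N sub-dictionary for a fascicle oriented along \code{u}.
#' Analytic atoms are re-evaluated in closed form (exact).  Monte Carlo
#' atoms exploit axial symmetry: within each shell the canonical atom is a
#' function of |g . z| only, which is interpolated (monotone cubic) at the
#' new |g . u| abscissae.
#'
#' @param dict a \linkS4class{FingerprintDictionary}.
#' @param u unit 3-vector.
#' @return M x N matrix of rotated atoms.
#' @export
rotateDictionary <- function(dict, u) {
  u <- as.numeric(u)
  if (abs(sqrt(sum(u^2)) - 1) > 1e-6) stop("u must be a unit vector")
  scheme <- dict@scheme
  if (dict@generator == "analytic") {
    pre <- .schemePrecomp(scheme, dict@substrate$radiusMean,
                          dict@substrate$radiusSd, dict@substrate$dIn)
    return(.fingerprintMatrix(pre, dict@params$fvf, dict@params$dex, u))
  }
  M <- nMeasurements(scheme)
  N <- nrow(dict@atoms)
  out <- matrix(1, M, N)
  ctNew <- abs(drop(scheme@directions %*% u))
  ctOld <- abs(scheme@directions[, 3])
  for (s in unique(scheme@shellIds[scheme@bvalues > 0])) {
    idx <- which(scheme@shellIds == s & scheme@bvalues > 0)
    xs <- ctOld[idx]
    ux <- sort(unique(round(xs, 10)))
    if (length(ux) < 4)
      stop(sprintf("shell %d has fewer than 4 distinct |g.z| samples; cannot interpolate", s))
    for (a in seq_len(N)) {
      ys <- dict@atoms[a, idx]
      ym <- vapply(ux, function(v) mean(ys[abs(xs - v) < 1e-9]), numeric(1))
      f <- splinefun(ux, ym, method = "monoH.FC")
      out[idx, a] <- pmin(pmax(f(pmin(pmax(ctNew[idx], min(ux)), max(ux))), 1e-6), 1)
    }
  }
  out
}

#' Fascicle-specific rotated design
#'
#' Stacks K rotated sub-dictionaries (one per fascicle orientation) into a
#' \linkS4class{RotatedDesign} consumed by \code{\link{mfExhaustive}} and
#' \code{\link{nnlsProjection}}.
#'
#' @param dict a \linkS4class{FingerprintDictionary}.
#' @param orientations K x 3 matrix of unit fascicle orientations.
#' @return A \linkS4class{RotatedDesign}.
#' @export
rotatedDesign <- function(dict, orientations) {
  orientations <- matrix(as.numeric(orientations), ncol = 3)
  blocks <- lapply(seq_len(nrow(orientations)), function(k)
    rotateDictionary(dict, orientations[k, ]))
  new("RotatedDesign", blocks = blocks, orientations = orientations,
      params = dict@params, scheme = dict@scheme)
}
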