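# Synthetic voxel generation: orientation sampling, the magnitude noise
# model, training datasets and the structured test set.

#' Synthetic data configuration
#'
#' Sampling laws for the voxel generator.  Defaults follow the training
#' recipe: crossing angles uniform on [15, 90] degrees, volume fractions
#' uniform on [0.05, 0.95] for two fascicles (Dirichlet(alpha = 1) for
#' three), SNR uniform on [10, 100].
#'
#' @param K number of fascicles (2 or 3).
#' @param angleLo,angleHi crossing-angle range in degrees.
#' @param alpha Dirichlet concentration for K >= 3.
#' @param nuLo,nuHi uniform volume-fraction range for K = 2.
#' @param snrLo,snrHi uniform SNR range, used when \code{snrSet} is NULL.
#' @param snrSet optional fixed set of SNR values sampled uniformly.
#' @return list of configuration values.
#' @export
synthConfig <- function(K = 2, angleLo = 15, angleHi = 90, alpha = 1,
                        nuLo = 0.05, nuHi = 0.95, snrLo = 10, snrHi = 100,
                        snrSet = NULL) {
  stopifnot(K %in% c(2, 3), angleLo < angleHi, alpha > 0)
  list(K = K, angleLo = angleLo, angleHi = angleHi, alpha = alpha,
       nuLo = nuLo, nuHi = nuHi, snrLo = snrLo, snrHi = snrHi,
       snrSet = snrSet)
}

.randUnit <- function() {
  z <- runif(1, -1, 1)
  phi <- runif(1, 0, 2 * pi)
  r <- sqrt(1 - z^2)
  c(r * cos(phi), r * sin(phi), z)
}

# unit vector at angle `ang` (radians) from u, uniform in azimuth
.vectorAtAngle <- function(u, ang) {
  a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- a - sum(a * u) * u
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2], u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  psi <- runif(1, 0, 2 * pi)
  cos(ang) * u + sin(ang) * (cos(psi) * e1 + sin(psi) * e2)
}

#' Sample fascicle orientations with constrained crossing angles
#'
#' The first orientation is uniform on the sphere; each subsequent one is
#' placed at a crossing angle (arccos of the absolute dot product) drawn
#' uniformly from the configured range, by rejection for K = 3 so that all
#' pairwise angles stay in range.  Uses the current RNG stream.
#'
#' @param K number of fascicles (2 or 3).
#' @param config see \code{\link{synthConfig}}.
#' @param maxRetries rejection budget for K = 3.
#' @return K x 3 matrix of unit vectors.
#' @export
sampleOrientations <- function(K = 2, config = synthConfig(K = K),
                               maxRetries = 1000) {
  stopifnot(K %in% c(2, 3))
  lo <- config$angleLo * pi / 180
  hi <- config$angleHi * pi / 180
  u1 <- .randUnit()
  u2 <- .vectorAtAngle(u1, runif(1, lo, hi))
  if (K == 2) return(rbind(u1, u2, deparse.level = 0))
  for (i in seq_len(maxRetries)) {
    u3 <- .vectorAtAngle(u1, runif(1, lo, hi))
    a23 <- acos(pmin(abs(sum(u2 * u3)), 1))
    if (a23 >= lo && a23 <= hi)
      return(rbind(u1, u2, u3, deparse.level = 0))
  }
  stop("could not place third fascicle within the crossing-angle range")
}

#' Jitter orientations with von Mises-Fisher noise
#'
#' Replaces each orientation by a draw from a von Mises-Fisher distribution
#' centred on it.  Used as the stand-in for an external orientation
#' estimator: at the default concentration the mean angular error is about
#' 7.4 degrees (kappa ~ pi / (2 * err_rad^2) for small errors).
#'
#' @param U n x 3 x K array (or K x 3 matrix) of unit orientations.
#' @param kappa concentration parameter.
#' @return array of the same shape.
#' @export
jitterOrientations <- function(U, kappa = 94) {
  one <- function(u) {
    # Wood-style inversion for vMF about the z axis, rotated onto u
    uu <- runif(1)
    w <- 1 + log(uu + (1 - uu) * exp(-2 * kappa)) / kappa
    w <- max(min(w, 1), -1)
    v <- .vectorAtAngle(u, acos(w))
    v
  }
  if (is.matrix(U)) return(t(apply(U, 1, one)))
  out <- U
  for (v in seq_len(dim(U)[1]))
    for (k in seq_len(dim(U)[3]))
      out[v, , k] <- one(U[v, , k])
  out
}

#' Magnitude (Rician-style) noise model
#'
#' Default mode applies s = sqrt(s_clean^2 + eps^2) with a single i.i.d.
#' Gaussian draw eps of standard deviation sigma = b0 / SNR per measurement.
#' Mode \code{"rician2"} applies the two-channel magnitude form
#' sqrt((s + eps1)^2 + eps2^2) for sensitivity checks.
#'
#' @param yClean noiseless signal vector.
#' @param snr signal-to-noise ratio (> 0).
#' @param b0Value noiseless b = 0 amplitude defining sigma.
#' @param mode \code{"default"} or \code{"rician2"}.
#' @return noisy signal vector (uses the current RNG stream).
#' @export
addNoise <- function(yClean, snr, b0Value = 1, mode = c("default", "rician2")) {
  mode <- match.arg(mode)
  stopifnot(snr > 0)
  sigma <- b0Value / snr
  if (mode == "default") {
    eps <- rnorm(length(yClean), 0, sigma)
    sqrt(yClean^2 + eps^2)
  } else {
    e1 <- rnorm(length(yClean), 0, sigma)
    e2 <- rnorm(length(yClean), 0, sigma)
    sqrt((yClean + e1)^2 + e2^2)
  }
}

.newVoxelSet <- function(Y, Yc, nu, fvf, dex, U, snr, scheme, config, seed) {
  cd <- S4Vectors::DataFrame(snr = snr, row.names = NULL)
  cd$nu <- nu; cd$fvf <- fvf; cd$dex <- dex
  cd$orientations <- matrix(U, nrow = ncol(Y))   # n x 3K, fascicle-major
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(signal = Y, signalClean = Yc), colData = cd,
    metadata = list(scheme = scheme, config = config, seed = seed,
                    K = ncol(nu)))
  new("VoxelSet", se)
}

#' @export
setMethod("signals", "VoxelSet", function(x)
  SummarizedExperiment::assay(x, "signal"))
#' @export
setMethod("signalsClean", "VoxelSet", function(x)
  SummarizedExperiment::assay(x, "signalClean"))
#' @export
setMethod("trueNu", "VoxelSet", function(x)
  as.matrix(SummarizedExperiment::colData(x)$nu))
#' @export
setMethod("trueFvf", "VoxelSet", function(x)
  as.matrix(SummarizedExperiment::colData(x)$fvf))
#' @export
setMethod("trueDex", "VoxelSet", function(x)
  as.matrix(SummarizedExperiment::colData(x)$dex))
#' @export
setMethod("voxelSnr", "VoxelSet", function(x)
  SummarizedExperiment::colData(x)$snr)
#' @export
setMethod("nFascicles", "VoxelSet", function(x)
  S4Vectors::metadata(x)$K)
#' @export
setMethod("trueOrientations", "VoxelSet", function(x) {
  m <- as.matrix(SummarizedExperiment::colData(x)$orientations)
  K <- S4Vectors::metadata(x)$K
  array(m, dim = c(nrow(m), 3, K))
})
#' @export
setMethod("acquisitionScheme", "VoxelSet", function(x)
  S4Vectors::metadata(x)$scheme)

#' Generate a synthetic training dataset
#'
#' Per voxel: fascicle orientations with constrained crossing angles;
#' volume fractions from the configured law; one (fvf, Dex) dictionary grid
#' row per fascicle; the noiseless signal as the convex atom combination
#' sum_k nu_k C(fvf_k, Dex_k, u_k); magnitude noise at an SNR drawn from
#' the configured law.  Fully reproducible from \code{seed}.
#'
#' @param n number of voxels.
#' @param dict a \linkS4class{FingerprintDictionary}.
#' @param config see \code{\link{synthConfig}}.
#' @param seed RNG seed.
#' @return A \linkS4class{VoxelSet}.
#' @export
generateDataset <- function(n, dict, config = synthConfig(), seed = 1) {
  stopifnot(n >= 1)
  scheme <- dict@scheme
  K <- config$K
  pre <- if (dict@generator == "analytic")
    .schemePrecomp(scheme, dict@substrate$radiusMean, dict@substrate$radiusSd,
                   dict@substrate$dIn) else NULL
  grid <- dict@params
  M <- nMeasurements(scheme)
  Y <- Yc <- matrix(NA_real_, M, n)
  nu <- fvf <- dex <- matrix(NA_real_, n, K)
  U <- array(NA_real_, dim = c(n, 3, K))
  snr <- numeric(n)
  withSeed(seed, {
    for (v in seq_len(n)) {
      Uv <- sampleOrientations(K, config)
      nuv <- if (K == 2) {
        a <- runif(1, config$nuLo, config$nuHi); c(a, 1 - a)
      } else {
        g <- rgamma(K, shape = config$alpha); g / sum(g)
      }
      rows <- sample.int(nrow(grid), K, replace = TRUE)
      yc <- numeric(M)
      for (k in seq_len(K)) {
        atom <- if (!is.null(pre))
          drop(.fingerprintMatrix(pre, grid$fvf[rows[k]], grid$dex[rows[k]],
                                  Uv[k, ]))
        else drop(rotateDictionary(dict, Uv[k, ])[, rows[k]])
        yc <- yc + nuv[k] * atom
      }
      sv <- if (!is.null(config$snrSet)) sample(config$snrSet, 1)
      else runif(1, config$snrLo, config$snrHi)
      Y[, v] <- addNoise(yc, sv, b0Value = 1)
      Yc[, v] <- yc
      nu[v, ] <- nuv; fvf[v, ] <- grid$fvf[rows]; dex[v, ] <- grid$dex[rows]
      U[v, , ] <- t(Uv)
      snr[v] <- sv
    }
  })
  .newVoxelSet(Y, Yc, nu, fvf, dex, U, snr, scheme, config, seed)
}

#' Structured two/three-fascicle test set
#'
#' Balanced grid over the dominant volume fraction nu1 in {0.5, ..., 0.9}
#' (K = 2; Dirichlet(alpha = 1) fractions for K = 3) and SNR in
#' {20, 30, 50}, with crossing angles uniform on [15, 90] degrees and
#' (fvf, Dex) pairs drawn from the dictionary grid.  Fascicle 1 always
#' carries the larger volume fraction.
#'
#' @param dict a \linkS4class{FingerprintDictionary}.
#' @param K number of fascicles.
#' @param seed RNG seed.
#' @param n total number of voxels (split evenly over the strata).
#' @param nu1Set dominant-fraction levels (K = 2).
#' @param snrSet SNR levels.
#' @param noiseless generate without noise (for identifiability checks).
#' @return A \linkS4class{VoxelSet}.
#' @export
buildTestSetExp1 <- function(dict, K = 2, seed = 1, n = 15000,
                             nu1Set = c(0.5, 0.6, 0.7, 0.8, 0.9),
                             snrSet = c(20, 30, 50), noiseless = FALSE) {
  stopifnot(K %in% c(2, 3))
  scheme <- dict@scheme
  config <- synthConfig(K = K, snrSet = snrSet)
  pre <- if (dict@generator == "analytic")
    .schemePrecomp(scheme, dict@substrate$radiusMean, dict@substrate$radiusSd,
                   dict@substrate$dIn) else NULL
  grid <- dict@params
  M <- nMeasurements(scheme)
  cells <- if (K == 2) expand.grid(nu1 = nu1Set, snr = snrSet)
  else expand.grid(nu1 = NA_real_, snr = snrSet)
  per <- ceiling(n / nrow(cells))
  ntot <- per * nrow(cells)
  Y <- Yc <- matrix(NA_real_, M, ntot)
  nu <- fvf <- dex <- matrix(NA_real_, ntot, K)
  U <- array(NA_real_, dim = c(ntot, 3, K))
  snr <- numeric(ntot)
  withSeed(seed, {
    v <- 0
    for (ci in seq_len(nrow(cells))) {
      for (r in seq_len(per)) {
        v <- v + 1
        Uv <- sampleOrientations(K, config)
        nuv <- if (K == 2) c(cells$nu1[ci], 1 - cells$nu1[ci])
        else { g <- rgamma(K, 1); g <- g / sum(g); sort(g, decreasing = TRUE) }
        rows <- sample.int(nrow(grid), K, replace = TRUE)
        yc <- numeric(M)
        for (k in seq_len(K)) {
          atom <- if (!is.null(pre))
            drop(.fingerprintMatrix(pre, grid$fvf[rows[k]], grid$dex[rows[k]],
                                    Uv[k, ]))
          else drop(rotateDictionary(dict, Uv[k, ])[, rows[k]])
          yc <- yc + nuv[k] * atom
        }
        Y[, v] <- if (noiseless) yc else addNoise(yc, cells$snr[ci], b0Value = 1)
        Yc[, v] <- yc
        nu[v, ] <- nuv; fvf[v, ] <- grid$fvf[rows]; dex[v, ] <- grid$dex[rows]
        U[v, , ] <- t(Uv)
        snr[v] <- cells$snr[ci]
      }
    }
  })
  .newVoxelSet(Y, Yc, nu, fvf, dex, U, snr, scheme, config, seed)
}
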