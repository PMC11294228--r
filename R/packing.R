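# Cylinder packings and the reduced-fidelity Monte Carlo signal simulator.

#' Sample axon radii from the gamma law
#'
#' Radii are gamma distributed with the given mean and standard deviation
#' (shape = mean^2/sd^2, scale = sd^2/mean).
#'
#' @param n number of draws.
#' @param radiusMean,radiusSd mean and sd in um.
#' @param seed RNG seed.
#' @return numeric(n) radii in um.
#' @export
sampleAxonRadii <- function(n, radiusMean = 0.5, radiusSd = 0.3, seed = 1) {
  shape <- radiusMean^2 / radiusSd^2
  scale <- radiusSd^2 / radiusMean
  withSeed(seed, rgamma(n, shape = shape, scale = scale))
}

#' Random periodic packing of cylinders
#'
#' Random-sequential-addition packing of \code{nCyl} non-overlapping
#' cylinders (circles in cross-section) in a periodic square cell whose size
#' is chosen so the achieved fiber volume fraction equals the requested one.
#' Radii follow the configured gamma law; larger cylinders are placed first.
#'
#' @param config a \linkS4class{SubstrateConfig} (its \code{fvf} is the
#'   target packing density; RSA saturates near 0.55 for disks, so dense
#'   requests may fail).
#' @param nCyl number of cylinders.
#' @param seed RNG seed.
#' @param maxAttempts placement attempts per cylinder before giving up.
#' @return A \linkS4class{CylinderPacking}.
#' @export
packCylinders <- function(config, nCyl, seed = 1, maxAttempts = 5000) {
  stopifnot(nCyl >= 1)
  if (config@fvf > 0.8) stop("requested fvf too dense to pack")
  radii <- sort(sampleAxonRadii(nCyl, config@radiusMean, config@radiusSd,
                                seed = seed), decreasing = TRUE)
  L <- sqrt(sum(pi * radii^2) / config@fvf)
  centers <- matrix(NA_real_, nCyl, 2)
  withSeed(seed + 1, {
    for (i in seq_len(nCyl)) {
      placed <- FALSE
      for (att in seq_len(maxAttempts)) {
        p <- runif(2, 0, L)
        ok <- TRUE
        if (i > 1) {
          dx <- abs(centers[1:(i - 1), 1] - p[1]); dx <- pmin(dx, L - dx)
          dy <- abs(centers[1:(i - 1), 2] - p[2]); dy <- pmin(dy, L - dy)
          ok <- all(dx^2 + dy^2 >= (radii[1:(i - 1)] + radii[i])^2)
        }
        if (ok) { centers[i, ] <- p; placed <- TRUE; break }
      }
      if (!placed)
        stop("could not place cylinder ", i,
             ": try a lower fvf or fewer cylinders")
    }
  })
  new("CylinderPacking", centers = centers, radii = radii, cellSize = L,
      achievedFvf = sum(pi * radii^2) / L^2)
}

setMethod("show", "CylinderPacking", function(object) {
  cat(sprintf("CylinderPacking: %d cylinders, cell %.2f um, fvf = %.3f\n",
              length(object@radii), object@cellSize, object@achievedFvf))
})

#' Monte Carlo PGSE fingerprint
#'
#' Random-walk solution of restricted/hindered diffusion in the packing
#' under rectangular-lobe PGSE encoding.  Spins are seeded in the intra- and
#' extra-axonal compartments in proportion to the fiber volume fraction,
#' walk with Gaussian steps and reflect elastically at the impermeable
#' membranes; each measurement's signal is the modulus of the mean phase
#' factor, and equals 1 at b = 0 by construction.  This is a reduced-fidelity
#' desk-scale simulator intended for validating the analytic generator, not
#' for production dictionaries.
#'
#' @param packing a \linkS4class{CylinderPacking}; a packing with zero
#'   cylinders yields free diffusion at \code{config@dEx}.
#' @param config a \linkS4class{SubstrateConfig} (dIn, dEx, fvf).
#' @param scheme an \linkS4class{AcquisitionScheme}.
#' @param nSpins total number of walkers.
#' @param dt time step in ms; a warning is issued when the rms step exceeds
#'   a quarter of the smallest radius.
#' @param seed RNG seed for the C++ generator.
#' @param compartment \code{"both"}, \code{"intra"} or \code{"extra"}:
#'   which compartment signal to return.
#' @return numeric(M) signal vector.
#' @export
mcFingerprint <- function(packing, config, scheme, nSpins = 10000, dt = 5e-3,
                          seed = 1, compartment = c("both", "intra", "extra")) {
  compartment <- match.arg(compartment)
  ncyl <- length(packing@radii)
  if (ncyl > 0) {
    step <- sqrt(2 * max(config@dIn, config@dEx) * dt)
    if (step > min(packing@radii) / 4)
      warning(sprintf(paste("rms step %.3f um exceeds min radius/4 = %.3f um;",
                            "reduce dt for accurate restriction"),
                      step, min(packing@radii) / 4))
  }
  nIntra <- if (ncyl > 0) round(nSpins * config@fvf) else 0L
  if (compartment == "intra") { nIntra <- nSpins }
  if (compartment == "extra") { nIntra <- 0L }
  if (nIntra > 0 && ncyl == 0) stop("intra-axonal spins require cylinders")
  res <- .mcWalkCpp(packing@centers, packing@radii, packing@cellSize,
                    config@dIn, config@dEx, scheme@directions,
                    scheme@gradientStrengths, scheme@delta, scheme@Delta,
                    dt, as.integer(nIntra), as.integer(nSpins - nIntra),
                    as.integer(seed), .gammaEff)
  s <- switch(compartment, both = res$signal, intra = res$intra,
              extra = res$extra)
  if (any(!is.finite(s))) stop("Monte Carlo walk produced non-finite signal")
  s
}
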