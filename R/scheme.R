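# PGSE acquisition schemes: construction, shell structure, FSL-dialect IO.

#' Construct an acquisition scheme
#'
#' Builds an \linkS4class{AcquisitionScheme} from a gradient table.  b-values
#' are in s/mm^2 (numerically 1000 x ms/um^2); timing in ms.  Gradient
#' strengths default to the value implied by
#' b = gamma^2 G^2 delta^2 (Delta - delta/3).
#'
#' @param directions M x 3 matrix of unit gradient directions (zero rows
#'   allowed at b = 0).
#' @param bvalues numeric(M) b-values in s/mm^2.
#' @param delta,Delta gradient duration and diffusion time (ms).
#' @param gradientStrengths optional numeric(M) in mT/m.
#' @param te,tr optional echo/repetition times (ms).
#' @param shellTol b-value tolerance used to group shells (s/mm^2).
#' @return An \linkS4class{AcquisitionScheme}.
#' @export
makeScheme <- function(directions, bvalues, delta, Delta,
                       gradientStrengths = NULL, te = NA_real_, tr = NA_real_,
                       shellTol = 50) {
  directions <- as.matrix(directions)
  storage.mode(directions) <- "double"
  if (is.null(gradientStrengths)) {
    bms <- .bToMsUm2(bvalues)
    gradientStrengths <- sqrt(bms / (.gammaEff^2 * delta^2 * (Delta - delta / 3)))
  }
  new("AcquisitionScheme", directions = directions, bvalues = as.numeric(bvalues),
      gradientStrengths = as.numeric(gradientStrengths),
      delta = delta, Delta = Delta, te = te, tr = tr,
      shellIds = groupShells(bvalues, tol = shellTol))
}

#' @describeIn makeScheme number of measurements M.
#' @param x an \code{AcquisitionScheme}.
#' @export
setMethod("nMeasurements", "AcquisitionScheme", function(x) nrow(x@directions))
#' @export
setMethod("directions", "AcquisitionScheme", function(x) x@directions)
#' @export
setMethod("bValues", "AcquisitionScheme", function(x) x@bvalues)
#' @export
setMethod("gradientStrengths", "AcquisitionScheme", function(x) x@gradientStrengths)
#' @export
setMethod("shellIds", "AcquisitionScheme", function(x) x@shellIds)
#' @export
setMethod("pulseDuration", "AcquisitionScheme", function(x) x@delta)
#' @export
setMethod("diffusionTime", "AcquisitionScheme", function(x) x@Delta)

setMethod("show", "AcquisitionScheme", function(object) {
  b <- object@bvalues
  sh <- object@shellIds
  cat(sprintf("AcquisitionScheme: %d measurements (%d at b = 0)\n",
              length(b), sum(b == 0)))
  for (s in sort(unique(sh[b > 0]))) {
    idx <- sh == s
    cat(sprintf("  shell %d: %3d directions, b = %g s/mm^2, G = %.0f mT/m\n",
                s, sum(idx), stats::median(b[idx]),
                stats::median(object@gradientStrengths[idx])))
  }
  cat(sprintf("  delta = %g ms, Delta = %g ms, TE/TR = %g/%g ms\n",
              object@delta, object@Delta, object@te, object@tr))
})

#' Group measurements into b-value shells
#'
#' Measurements whose b-values differ by at most \code{tol} share a shell id;
#' b = 0 receives id 0 and ids increase with b.
#'
#' @param bvalues numeric vector of b-values (s/mm^2).
#' @param tol grouping tolerance (s/mm^2), must be positive.
#' @return integer vector of shell ids.
#' @export
groupShells <- function(bvalues, tol = 50) {
  stopifnot(tol > 0)
  ord <- order(bvalues)
  bs <- bvalues[ord]
  cl <- cumsum(c(0, diff(bs) > tol))
  ids <- integer(length(bvalues))
  ids[ord] <- cl
  as.integer(ids)
}

#' Approximately uniform unit directions by electrostatic repulsion
#'
#' Generates \code{n} unit vectors by minimizing a Coulomb-type energy over
#' the point set together with its antipodes, the standard construction for
#' diffusion gradient tables.  Deterministic given the seed.
#'
#' @param n number of directions.
#' @param seed RNG seed for the random initialization.
#' @param iterations number of repulsion updates.
#' @return n x 3 matrix of unit vectors.
#' @export
sphereDirections <- function(n, seed = 1, iterations = 200) {
  X <- withSeed(seed, {
    m <- matrix(rnorm(3 * n), n, 3)
    m / sqrt(rowSums(m^2))
  })
  step <- 0.1
  for (it in seq_len(iterations)) {
    F <- matrix(0, n, 3)
    for (sgn in c(1, -1)) {
      # pairwise differences against points (sgn = 1) and antipodes (-1)
      D1 <- outer(X[, 1], sgn * X[, 1], "-")
      D2 <- outer(X[, 2], sgn * X[, 2], "-")
      D3 <- outer(X[, 3], sgn * X[, 3], "-")
      r2 <- D1^2 + D2^2 + D3^2
      diag(r2) <- Inf
      r2[r2 < 1e-12] <- 1e-12
      inv <- r2^(-1.5)
      F <- F + cbind(rowSums(D1 * inv), rowSums(D2 * inv), rowSums(D3 * inv))
    }
    # project force onto the tangent plane and take a small step
    F <- F - X * rowSums(F * X)
    nf <- sqrt(rowSums(F^2))
    nf[nf < 1e-12] <- 1e-12
    X <- X + step * F / nf
    X <- X / sqrt(rowSums(X^2))
    step <- step * 0.98
  }
  X
}

.interleaveB0 <- function(dirs, bvals, G, blockLen = 13) {
  # one b = 0 volume leading every block of `blockLen` diffusion-weighted
  # volumes
  M <- nrow(dirs)
  nb <- ceiling(M / blockLen)
  outD <- matrix(0, 0, 3); outB <- numeric(0); outG <- numeric(0)
  for (i in seq_len(nb)) {
    idx <- ((i - 1) * blockLen + 1):min(i * blockLen, M)
    outD <- rbind(outD, c(0, 0, 0), dirs[idx, , drop = FALSE])
    outB <- c(outB, 0, bvals[idx])
    outG <- c(outG, 0, G[idx])
  }
  list(directions = outD, bvalues = outB, G = outG)
}

#' HCP-MGH style multi-shell acquisition scheme
#'
#' Four PGSE shells of 64, 64, 128 and 256 directions at b = 1000, 3000,
#' 5000 and 10000 s/mm^2 (G = 69, 120, 155, 219 mT/m), delta = 12.9 ms,
#' Delta = 21.8 ms, TE/TR = 57/8800 ms, with one b = 0 volume leading every
#' block of 13 diffusion-weighted volumes: 552 volumes in total.  Direction
#' sets are seeded electrostatic point sets; the released gradient tables
#' are not redistributed here, and any bvec file can be substituted via
#' \code{\link{readScheme}}.
#'
#' @param seed RNG seed for the direction sets.
#' @return An \linkS4class{AcquisitionScheme} with 552 measurements.
#' @export
hcpMghScheme <- function(seed = 1) {
  nd <- c(64, 64, 128, 256)
  bs <- c(1000, 3000, 5000, 10000)
  Gs <- c(69, 120, 155, 219)
  dirs <- NULL; bv <- NULL; G <- NULL
  for (i in seq_along(nd)) {
    dirs <- rbind(dirs, sphereDirections(nd[i], seed = seed + i))
    bv <- c(bv, rep(bs[i], nd[i]))
    G <- c(G, rep(Gs[i], nd[i]))
  }
  iv <- .interleaveB0(dirs, bv, G, blockLen = 13)
  makeScheme(iv$directions, iv$bvalues, delta = 12.9, Delta = 21.8,
             gradientStrengths = iv$G, te = 57, tr = 8800)
}

#' Clinical-style acquisition scheme
#'
#' Three shells of 64, 64 and 128 directions at b = 1000, 2000 and 5000
#' s/mm^2 (G = 31, 44, 69 mT/m) plus 4 b = 0 volumes; delta = 22.9 ms,
#' Delta = 35.7 ms, TE/TR = 77.4/4842 ms: 260 measurements in total.
#'
#' @param seed RNG seed for the direction sets.
#' @return An \linkS4class{AcquisitionScheme} with 260 measurements.
#' @export
clinicalScheme <- function(seed = 1) {
  nd <- c(64, 64, 128)
  bs <- c(1000, 2000, 5000)
  Gs <- c(31, 44, 69)
  dirs <- NULL; bv <- NULL; G <- NULL
  for (i in seq_along(nd)) {
    dirs <- rbind(dirs, sphereDirections(nd[i], seed = seed + 10 * i))
    bv <- c(bv, rep(bs[i], nd[i]))
    G <- c(G, rep(Gs[i], nd[i]))
  }
  # deterministic layout: b0, shell1, b0, shell2, b0, shell3, b0
  outD <- rbind(c(0, 0, 0), dirs[1:64, ], c(0, 0, 0), dirs[65:128, ],
                c(0, 0, 0), dirs[129:256, ], c(0, 0, 0))
  outB <- c(0, bv[1:64], 0, bv[65:128], 0, bv[129:256], 0)
  outG <- c(0, G[1:64], 0, G[65:128], 0, G[129:256], 0)
  makeScheme(outD, outB, delta = 22.9, Delta = 35.7,
             gradientStrengths = outG, te = 77.4, tr = 4842)
}

#' Read / write FSL-dialect bval/bvec scheme files
#'
#' \code{readScheme} parses whitespace-separated bval (one row) and bvec
#' (three rows) files; directions off unit norm by more than 1e-3 are
#' renormalized with a warning.  \code{writeScheme} writes the same dialect;
#' the two are inverse up to float formatting.
#'
#' @param bvalPath,bvecPath file paths.
#' @param delta,Delta,te,tr pulse timing (ms) to attach to the scheme.
#' @param gradientStrengths optional per-measurement G (mT/m); derived from
#'   the b-values and timing when absent.
#' @return \code{readScheme} returns an \linkS4class{AcquisitionScheme};
#'   \code{writeScheme} returns the paths invisibly.
#' @export
readScheme <- function(bvalPath, bvecPath, delta, Delta, te = NA_real_,
                       tr = NA_real_, gradientStrengths = NULL) {
  bval <- scan(bvalPath, quiet = TRUE)
  bvec <- as.matrix(read.table(bvecPath))
  if (nrow(bvec) != 3)
    stop("bvec file must contain exactly three rows")
  if (ncol(bvec) != length(bval))
    stop(sprintf("bval/bvec count mismatch: %d vs %d", length(bval), ncol(bvec)))
  dirs <- t(bvec)
  nrm <- sqrt(rowSums(dirs^2))
  off <- abs(nrm - 1) > 1e-3 & !(bval == 0 & nrm < 1e-3)
  if (any(off)) {
    warning(sprintf("%d direction(s) off unit norm by > 1e-3; renormalizing",
                    sum(off)))
  }
  fix <- nrm > 1e-3
  dirs[fix, ] <- dirs[fix, , drop = FALSE] / nrm[fix]
  dirs[!fix, ] <- 0
  makeScheme(dirs, bval, delta = delta, Delta = Delta, te = te, tr = tr,
             gradientStrengths = gradientStrengths)
}

#' @rdname readScheme
#' @param scheme an \linkS4class{AcquisitionScheme} to serialize.
#' @export
writeScheme <- function(scheme, bvalPath, bvecPath) {
  cat(paste(format(scheme@bvalues, trim = TRUE, scientific = FALSE),
            collapse = " "), "\n", file = bvalPath)
  bv <- t(scheme@directions)
  write.table(format(bv, digits = 10, trim = TRUE), file = bvecPath,
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(c(bvalPath, bvecPath))
}
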