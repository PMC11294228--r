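# Reference Microstructure Fingerprinting: exhaustive combinatorial matching.

.b0normalize <- function(y, scheme) {
  b0 <- scheme@bvalues == 0
  if (any(b0)) {
    m <- mean(y[b0])
    if (m <= 0) stop("non-positive b = 0 signal; cannot normalize")
    y / m
  } else y
}

.newEstimates <- function(nu, fvf, dex, orientations, residual, method,
                          nSolves) {
  nu <- pmax(nu, 0)
  nu <- nu / rowSums(nu)
  new("FascicleEstimates", nu = nu, fvf = fvf, dex = dex,
      orientations = orientations, residual = residual, method = method,
      nSolves = nSolves)
}

#' Exhaustive fingerprint matching (reference estimator)
#'
#' Scans all N^K combinations of one atom per fascicle-specific
#' sub-dictionary, solving the K-variable NNLS sub-problem of each
#' combination, and returns the minimal-residual combination.  Relative
#' volume fractions are the normalized NNLS weights; fvf and Dex are read
#' from the dictionary labels of the selected atoms.  Exactly N^K NNLS
#' sub-problems are solved (reported in the \code{nSolves} slot).  Residual
#' ties resolve to the lowest combined atom index.  The input signal is
#' b0-normalized before matching.
#'
#' @param y numeric(M) voxel signal.
#' @param design a \linkS4class{RotatedDesign} with K blocks.
#' @return A \linkS4class{FascicleEstimates} with one row.
#' @export
mfExhaustive <- function(y, design) {
  y <- as.numeric(y)
  if (all(y == 0)) stop("all-zero signal: fractions undefined")
  y <- .b0normalize(y, design@scheme)
  K <- length(design@blocks)
  yty <- sum(y^2)
  if (K == 1) {
    C1 <- design@blocks[[1]]
    a1 <- drop(crossprod(C1, y)); n1 <- colSums(C1^2)
    q <- ifelse(a1 > 0, a1^2 / n1, 0)
    i <- which.max(q)
    sol <- list(idx = i, w = max(a1[i] / n1[i], 0),
                residual = sqrt(max(yty - q[i], 0)), nSolves = length(a1))
  } else if (K == 2) {
    C1 <- design@blocks[[1]]; C2 <- design@blocks[[2]]
    sol <- .exhaustivePairsCpp(crossprod(C1, C2), drop(crossprod(C1, y)),
                               drop(crossprod(C2, y)), colSums(C1^2),
                               colSums(C2^2), yty)
  } else if (K == 3) {
    C1 <- design@blocks[[1]]; C2 <- design@blocks[[2]]; C3 <- design@blocks[[3]]
    sol <- .exhaustiveTriplesCpp(crossprod(C1, C2), crossprod(C1, C3),
                                 crossprod(C2, C3), drop(crossprod(C1, y)),
                                 drop(crossprod(C2, y)), drop(crossprod(C3, y)),
                                 colSums(C1^2), colSums(C2^2), colSums(C3^2),
                                 yty)
  } else stop("K > 3 fascicles not supported")
  # polish the winning combination: the Gram-based scan suffers benign
  # cancellation in the residual, so re-solve the selected small NNLS
  idx0 <- as.integer(sol$idx)
  A <- vapply(seq_len(K), function(k) design@blocks[[k]][, idx0[k]],
              numeric(length(y)))
  fit <- nnlsFit(A, y)
  sol$w <- fit$w
  sol$residual <- fit$residual
  w <- as.numeric(sol$w)
  if (sum(w) <= 0) {
    warning("all NNLS weights zero at optimum; returning uniform fractions")
    nu <- matrix(1 / K, 1, K)
  } else nu <- matrix(w / sum(w), 1, K)
  idx <- as.integer(sol$idx)
  ors <- array(t(design@orientations), dim = c(1, 3, K))
  .newEstimates(nu, matrix(design@params$fvf[idx], 1, K),
                matrix(design@params$dex[idx], 1, K), ors,
                sol$residual, "mf_exhaustive", sol$nSolves)
}

#' Batch reference fit over a voxel set
#'
#' Runs \code{\link{mfExhaustive}} voxel-by-voxel, rotating the dictionary
#' to the supplied orientations (the ground-truth ones by default, or
#' jittered stand-ins for an external orientation estimator, see
#' \code{\link{jitterOrientations}}).
#'
#' @param voxels a \linkS4class{VoxelSet}.
#' @param dict a \linkS4class{FingerprintDictionary}.
#' @param orientations either \code{"truth"} or an n x 3 x K array.
#' @param label method label stored in the result.
#' @return A \linkS4class{FascicleEstimates}.
#' @export
mfFit <- function(voxels, dict, orientations = "truth",
                  label = "mf_exhaustive") {
  U <- .resolveOrientations(voxels, orientations)
  Y <- signals(voxels)
  n <- ncol(Y)
  K <- dim(U)[3]
  nu <- fvf <- dex <- matrix(NA_real_, n, K)
  resid <- solves <- numeric(n)
  for (v in seq_len(n)) {
    des <- rotatedDesign(dict, t(U[v, , ]))
    est <- mfExhaustive(Y[, v], des)
    nu[v, ] <- est@nu; fvf[v, ] <- est@fvf; dex[v, ] <- est@dex
    resid[v] <- est@residual; solves[v] <- est@nSolves
  }
  .newEstimates(nu, fvf, dex, aperm(array(U, dim(U)), c(1, 2, 3)), resid,
                label, solves)
}

# orientations argument -> n x 3 x K array
.resolveOrientations <- function(voxels, orientations) {
  if (is.character(orientations) && identical(orientations, "truth"))
    return(trueOrientations(voxels))
  stopifnot(is.array(orientations), length(dim(orientations)) == 3)
  orientations
}
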