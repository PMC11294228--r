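# The fully-learned accelerated estimator: per-shell SH coefficients feed
# an MLP that jointly predicts tissue parameters and fascicle orientations.

#' Fully-learned method configuration
#'
#' @param hidden shared-trunk hidden layer sizes.
#' @param keep dropout retention probability.
#' @param lr,lrDecay Adam learning rate and its per-epoch decay factor.
#' @param epochs,batch training schedule.
#' @param lmax,lambda spherical-harmonics feature settings (see
#'   \code{\link{fitShPerShell}}).
#' @param orientWeight weight of the orientation loss term relative to the
#'   scalar MSE at the end of training; \code{orientWeightStart} (optional)
#'   sets the starting weight of a linear schedule.
#' @param branch width of the separate scalar / orientation head branches
#'   (0 collapses them into a single output layer).
#' @param pitFrom fraction of the schedule after which per-sample
#'   permutation-invariant target assignment replaces the fixed
#'   nu-descending ordering.
#' @param orientHead \code{"tensor"} (rank-2 orientation tensor output,
#'   default) or \code{"vector"} (direct half-sphere vector output).
#' @param orientWeightStart optional starting orientation-loss weight.
#' @param augmentRotations augment each minibatch with exact rotations
#'   applied in the spherical-harmonics domain.
#' @return list of configuration values.
#' @export
flConfig <- function(hidden = c(256, 256, 128), keep = 0.9, lr = 1e-3,
                     lrDecay = 0.97, epochs = 60, batch = 128, lmax = 12,
                     lambda = 1e-3, orientWeight = 0.5, branch = 128,
                     pitFrom = 0.5, orientHead = c("tensor", "vector"),
                     orientWeightStart = NULL, augmentRotations = TRUE) {
  orientHead <- match.arg(orientHead)
  list(hidden = hidden, keep = keep, lr = lr, lrDecay = lrDecay,
       epochs = epochs, batch = batch, lmax = lmax, lambda = lambda,
       orientWeight = orientWeight, orientWeightStart = orientWeightStart,
       branch = branch, pitFrom = pitFrom,
       orientHead = orientHead, augmentRotations = augmentRotations)
}

#' Train the fully-learned regressor
#'
#' Fits per-shell SH features for every training voxel and trains an MLP
#' whose sigmoid head regresses min-max-scaled (nu, fvf, Dex) per fascicle
#' and whose orientation head predicts each fascicle orientation on the
#' unit half-sphere (z >= 0).  The loss is the scalar MSE plus the
#' antipodally symmetric orientation term 1 - (u_hat . u)^2 summed over
#' fascicles.  Ground-truth fascicles are ordered by descending nu and
#' flipped to the half-sphere.  Deterministic given \code{seed}.
#'
#' @param voxels a \linkS4class{VoxelSet}.
#' @param grid dictionary parameter grid (fixes the output scaling ranges).
#' @param config see \code{\link{flConfig}}.
#' @param seed RNG seed.
#' @return A \linkS4class{TrainedRegressor} of kind \code{"fully_learned"}.
#' @export
trainFullyLearned <- function(voxels, grid = buildParameterGrid(),
                              config = flConfig(), seed = 1) {
  if (ncol(voxels) == 0) stop("empty training dataset")
  scheme <- S4Vectors::metadata(voxels)$scheme
  X <- .shFeatureMatrix(signals(voxels), scheme, config$lmax, config$lambda)
  truth <- .orderedTruth(voxels)
  K <- ncol(truth$nu)
  scaling <- .targetScaling(K, grid)
  Tm <- .scaleTargets(cbind(truth$nu, truth$fvf, truth$dex), scaling)
  # orientation targets on the half-sphere, flattened n x 3K
  Ut <- matrix(NA_real_, nrow(Tm), 3 * K)
  for (k in seq_len(K)) {
    u <- truth$U[, , k]
    flip <- u[, 3] < 0
    u[flip, ] <- -u[flip, , drop = FALSE]
    Ut[, (k - 1) * 3 + (1:3)] <- u
  }
  featStats <- .featStats(X)
  nShells <- ncol(X) / sum(2 * seq(0, config$lmax, 2) + 1)
  net <- .trainFlNet(X, Tm, Ut, K, config, seed, featStats,
                     lmax = config$lmax, nShells = nShells)
  new("TrainedRegressor", kind = "fully_learned", par = net$par,
      config = config, scaling = scaling, K = as.integer(K),
      meta = list(seed = seed, epochs = config$epochs, lr = config$lr,
                  lossHist = net$lossHist, nIn = ncol(X),
                  featStats = featStats,
                  shellB = sort(unique(scheme@bvalues[scheme@bvalues > 0])),
                  datasetFingerprint = .dataFingerprint(X[1, ]),
                  nTrain = ncol(voxels)))
}

# per-sample permutation-invariant target assignment: near nu ~ 1/K the
# ground-truth fascicle ordering is arbitrary, so each sample's targets may
# be permuted before the gradient is taken.  The assignment minimizes the
# orientation-head cost alone (crossing angles are >= 15 deg, so geometry
# identifies the fascicle slots once the orientation head is rough); the
# scalar targets follow the same permutation, keeping the heads consistent.
# O is the raw orientation-head output, Tor its target, with `bs` numbers
# per fascicle (3 for the direct head, 6 for the tensor head, where the
# Euclidean cost equals the Frobenius tensor distance).
.flPermuteTargets <- function(O, Tm, Tor, K, bs) {
  perms <- if (K == 2) list(1:2, 2:1)
  else list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L), c(2L, 3L, 1L),
            c(3L, 1L, 2L), c(3L, 2L, 1L))
  n <- nrow(O)
  best <- rep(Inf, n)
  Tsel <- Tm; Osel <- Tor
  scalCols <- function(p) c(p, K + p, 2 * K + p)
  orCols <- function(p) as.vector(vapply(p, function(k)
    as.integer((k - 1) * bs + (1:bs)), integer(bs)))
  for (p in perms) {
    Tp <- Tm[, scalCols(p), drop = FALSE]
    Op <- Tor[, orCols(p), drop = FALSE]
    cost <- rowSums((O - Op)^2)
    sel <- cost < best
    if (any(sel)) {
      best[sel] <- cost[sel]
      Tsel[sel, ] <- Tp[sel, , drop = FALSE]
      Osel[sel, ] <- Op[sel, , drop = FALSE]
    }
  }
  list(Tm = Tsel, Tor = Osel)
}

# (l, m) bookkeeping of the concatenated per-shell SH feature layout,
# used by the rotation augmentation
.shLayout <- function(lmax, nShells) {
  l <- unlist(lapply(seq(0, lmax, 2), function(li) rep(li, 2 * li + 1)))
  m <- unlist(lapply(seq(0, lmax, 2), function(li) -li:li))
  nc <- length(l)
  plus <- integer(0); minus <- integer(0); mm <- integer(0)
  for (sh in seq_len(nShells) - 1) {
    for (i in seq_len(nc)) {
      if (m[i] > 0) {
        j <- which(l == l[i] & m == -m[i])
        plus <- c(plus, sh * nc + i)
        minus <- c(minus, sh * nc + j)
        mm <- c(mm, m[i])
      }
    }
  }
  list(plus = plus, minus = minus, m = mm)
}

# rotate SH features and orientation targets by per-sample azimuths phi
# about z (an exact symmetry of the forward model: free training-data
# augmentation)
.shRotateZ <- function(X, lay, phi) {
  Xr <- X
  for (i in seq_along(lay$m)) {
    cp <- cos(lay$m[i] * phi); sp <- sin(lay$m[i] * phi)
    a <- X[, lay$plus[i]]; b <- X[, lay$minus[i]]
    Xr[, lay$plus[i]] <- a * cp - b * sp
    Xr[, lay$minus[i]] <- a * sp + b * cp
  }
  Xr
}

.rotateUz <- function(Ut, K, phi) {
  Ur <- Ut
  cp <- cos(phi); sp <- sin(phi)
  for (k in seq_len(K)) {
    i3 <- (k - 1) * 3
    u1 <- Ut[, i3 + 1]; u2 <- Ut[, i3 + 2]
    Ur[, i3 + 1] <- cp * u1 - sp * u2
    Ur[, i3 + 2] <- sp * u1 + cp * u2
  }
  Ur
}

.trainFlNet <- function(X, Tm, Ut, K, config, seed, featStats,
                        lmax = 12, nShells = 4) {
  br <- if (is.null(config$branch)) 0 else config$branch
  tensor <- identical(config$orientHead, "tensor")
  bs <- if (tensor) 6L else 3L
  # orientation targets in head space
  Tor <- matrix(NA_real_, nrow(Tm), bs * K)
  for (k in seq_len(K)) {
    u <- Ut[, (k - 1) * 3 + (1:3), drop = FALSE]
    Tor[, (k - 1) * bs + (1:bs)] <- if (tensor) .tensorEmbed(u) else u
  }
  par <- withSeed(seed, .initFlPar(ncol(X), config$hidden, (3 + bs) * K, br,
                                   3 * K))
  pitEpoch <- ceiling((if (is.null(config$pitFrom)) 0.5 else config$pitFrom) *
                        config$epochs)
  owEnd <- if (is.null(config$orientWeight)) 1 else config$orientWeight
  owStart <- if (is.null(config$orientWeightStart)) owEnd
  else config$orientWeightStart
  augment <- isTRUE(config$augmentRotations)
  lay <- if (augment) .shLayout(lmax, nShells) else NULL
  rotPre <- if (augment) {
    # fixed quadrature set for building exact band-limited SO(3) rotation
    # operators in SH space
    dirs0 <- sphereDirections(400, seed = 17)
    B0 <- realEvenShBasis(dirs0, lmax)
    list(dirs0 = dirs0, P = solve(crossprod(B0), t(B0)))
  } else NULL
  nc1 <- if (augment) ncol(rotPre$P) else 0
  ncoef <- sum(2 * seq(0, lmax, 2) + 1)
  step <- function(par, state, idx, ep) {
    Xb <- X[idx, , drop = FALSE]
    Ub <- Ut[idx, , drop = FALSE]
    Torb <- Tor[idx, , drop = FALSE]
    if (augment) {
      # per-sample azimuthal spin + one shared random rotation per batch:
      # together an (approximately per-sample) uniform SO(3) augmentation,
      # exact for the band-limited signal representation
      phi <- runif(length(idx), 0, 2 * pi)
      Xb <- .shRotateZ(Xb, lay, phi)
      Ub <- .rotateUz(Ub, K, phi)
      Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
      if (det(Q) < 0) Q[, 1] <- -Q[, 1]
      D <- rotPre$P %*% realEvenShBasis(rotPre$dirs0 %*% Q, lmax)
      for (sh in seq_len(nShells))
        Xb[, (sh - 1) * ncoef + seq_len(ncoef)] <-
          Xb[, (sh - 1) * ncoef + seq_len(ncoef), drop = FALSE] %*% t(D)
      for (k in seq_len(K)) {
        i3 <- (k - 1) * 3
        Ub[, i3 + (1:3)] <- Ub[, i3 + (1:3), drop = FALSE] %*% t(Q)
      }
      for (k in seq_len(K)) {
        u <- Ub[, (k - 1) * 3 + (1:3), drop = FALSE]
        if (!tensor) {
          flip <- u[, 3] < 0
          u[flip, ] <- -u[flip, , drop = FALSE]
        }
        Torb[, (k - 1) * bs + (1:bs)] <- if (tensor) .tensorEmbed(u) else u
      }
    }
    Xb <- .standardize(Xb, featStats)
    fw <- .flForward(par, Xb, K, config, train = TRUE)
    Ohead <- if (tensor) fw$O else fw$U
    # curriculum: fixed nu-descending targets first, then per-sample
    # permutation-invariant assignment once the orientation head is rough
    tg <- if (ep > pitEpoch)
      .flPermuteTargets(Ohead, Tm[idx, , drop = FALSE], Torb, K, bs)
    else list(Tm = Tm[idx, , drop = FALSE], Tor = Torb)
    ow <- owStart + (owEnd - owStart) * (ep - 1) / max(config$epochs - 1, 1)
    D <- fw$S - tg$Tm
    lossS <- mean(D^2)
    dS <- 2 * D / length(D)
    if (tensor) {
      Do <- fw$O - tg$Tor
      lossO <- mean(rowSums(Do^2))
      dU <- 2 * Do / nrow(Do)
    } else {
      or <- .orientationLoss(fw$U, tg$Tor, K)
      lossO <- or$loss
      dU <- or$dU
    }
    grads <- .flBackward(par, fw$cache, dS, ow * dU, K, config)
    list(loss = lossS + ow * lossO, grads = grads, state = state)
  }
  res <- .trainLoop(par, NULL, nrow(X), config, seed, step)
  res
}

#' Predict tissue parameters and orientations from SH features
#'
#' Evaluation-mode forward pass of a trained fully-learned network.  No
#' NNLS solve and no dictionary search is involved: the per-voxel cost is
#' independent of the dictionary size.
#'
#' @param model a \linkS4class{TrainedRegressor} of kind
#'   \code{"fully_learned"}.
#' @param features an \linkS4class{SHFeatures} (one voxel) or an n x nIn
#'   feature matrix (shells concatenated in ascending-b order).
#' @return A \linkS4class{FascicleEstimates} with estimated orientations on
#'   the unit half-sphere.
#' @export
flPredict <- function(model, features) {
  stopifnot(is(model, "TrainedRegressor"))
  if (model@kind != "fully_learned") stop("model is not a fully-learned regressor")
  X <- if (is(features, "SHFeatures"))
    matrix(as.numeric(features@coefficients), 1) else as.matrix(features)
  if (ncol(X) != model@meta$nIn) stop("feature layout mismatch with model")
  K <- model@K
  X <- .standardize(X, model@meta$featStats)
  fw <- .flForward(model@par, X, K, model@config, train = FALSE)
  P <- .unscaleTargets(fw$S, model@scaling)
  nu <- P[, 1:K, drop = FALSE]
  nu <- nu / rowSums(nu)
  ors <- array(NA_real_, dim = c(nrow(X), 3, K))
  if (identical(model@config$orientHead, "tensor")) {
    for (k in seq_len(K)) {
      blk <- fw$O[, (k - 1) * 6 + (1:6), drop = FALSE]
      ors[, , k] <- t(apply(blk, 1, .tensorToUnit))
    }
  } else {
    for (k in seq_len(K)) ors[, , k] <- fw$U[, (k - 1) * 3 + (1:3)]
  }
  .newEstimates(nu, P[, K + (1:K), drop = FALSE],
                P[, 2 * K + (1:K), drop = FALSE], ors,
                rep(NA_real_, nrow(X)), "fully_learned", rep(0, nrow(X)))
}

#' Fit a voxel set with the fully-learned method
#'
#' @param model a trained fully-learned \linkS4class{TrainedRegressor}.
#' @param voxels a \linkS4class{VoxelSet} acquired with a scheme whose shell
#'   structure matches the training scheme.
#' @return A \linkS4class{FascicleEstimates}.
#' @export
fitFullyLearned <- function(model, voxels) {
  scheme <- S4Vectors::metadata(voxels)$scheme
  X <- .shFeatureMatrix(signals(voxels), scheme, model@config$lmax,
                        model@config$lambda)
  flPredict(model, X)
}
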