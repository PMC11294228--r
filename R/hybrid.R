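# The hybrid accelerated estimator: one K*N-variable NNLS projection onto
# all rotated atoms, then a split-arm MLP mapping the weights to tissue
# parameters.

#' Hybrid method configuration
#'
#' @param armWidth output width of each per-fascicle arm.
#' @param hidden hidden layer sizes of the common MLP.
#' @param keep dropout retention probability.
#' @param lr,lrDecay Adam learning rate and its per-epoch decay factor.
#' @param epochs,batch training schedule.
#' @param shareArms use one set of arm weights for all fascicle blocks
#'   (a test-oriented symmetric configuration; the default trains separate
#'   arms as in the split architecture).
#' @param orientKappa optional von Mises-Fisher concentration used to jitter
#'   the training orientations (emulating an external orientation
#'   estimator); \code{NULL} trains on ground-truth orientations.
#' @return list of configuration values.
#' @export
hybridConfig <- function(armWidth = 64, hidden = c(256, 128), keep = 0.9,
                         lr = 1e-3, lrDecay = 0.97, epochs = 40, batch = 128,
                         shareArms = FALSE, orientKappa = NULL) {
  list(armWidth = armWidth, hidden = hidden, keep = keep, lr = lr,
       lrDecay = lrDecay, epochs = epochs, batch = batch,
       shareArms = shareArms, orientKappa = orientKappa)
}

#' NNLS projection of a voxel signal onto the rotated dictionary
#'
#' Solves the single relaxed NNLS problem with all K*N rotated atoms as
#' columns (no combinatorial search and no explicit sparsity constraint:
#' the nonnegativity itself produces sparse weights).  Exactly one NNLS
#' solve is performed.  The signal is b0-normalized first.
#'
#' @param y numeric(M) voxel signal.
#' @param design a \linkS4class{RotatedDesign}.
#' @return An \linkS4class{NNLSWeights}.
#' @export
nnlsProjection <- function(y, design) {
  y <- .b0normalize(as.numeric(y), design@scheme)
  A <- do.call(cbind, design@blocks)
  fit <- nnlsFit(A, y)
  new("NNLSWeights", w = fit$w,
      layout = c(K = length(design@blocks), N = ncol(design@blocks[[1]])),
      residual = fit$residual, nSolves = 1)
}

# min-max scaling metadata for targets (nu, fvf, Dex) x K, in column order
# nu_1..nu_K, fvf_1..fvf_K, dex_1..dex_K
.targetScaling <- function(K, grid) {
  lo <- c(rep(0, K), rep(min(grid$fvf), K), rep(min(grid$dex), K))
  hi <- c(rep(1, K), rep(max(grid$fvf), K), rep(max(grid$dex), K))
  list(lo = lo, hi = hi,
       names = c(paste0("nu", 1:K), paste0("fvf", 1:K), paste0("dex", 1:K)))
}

.scaleTargets <- function(T, scaling) {
  sweep(sweep(T, 2, scaling$lo, `-`), 2, scaling$hi - scaling$lo, `/`)
}

.unscaleTargets <- function(S, scaling) {
  sweep(sweep(S, 2, scaling$hi - scaling$lo, `*`), 2, scaling$lo, `+`)
}

# ground-truth targets ordered so fascicle 1 carries the larger nu
.orderedTruth <- function(voxels) {
  nu <- trueNu(voxels); fvf <- trueFvf(voxels); dex <- trueDex(voxels)
  U <- trueOrientations(voxels)
  K <- ncol(nu)
  ord <- t(apply(nu, 1, order, decreasing = TRUE))
  n <- nrow(nu)
  for (v in seq_len(n)) {
    o <- ord[v, ]
    if (!identical(o, seq_len(K))) {
      nu[v, ] <- nu[v, o]; fvf[v, ] <- fvf[v, o]; dex[v, ] <- dex[v, o]
      U[v, , ] <- U[v, , o]
    }
  }
  list(nu = nu, fvf = fvf, dex = dex, U = U)
}

# NNLS weight features for every voxel (n x K*N), given per-voxel
# orientations (n x 3 x K)
.hybridFeatures <- function(voxels, dict, U) {
  Y <- signals(voxels)
  n <- ncol(Y)
  K <- dim(U)[3]
  N <- nAtoms(dict)
  X <- matrix(0, n, K * N)
  resid <- numeric(n)
  for (v in seq_len(n)) {
    des <- rotatedDesign(dict, t(U[v, , ]))
    w <- nnlsProjection(Y[, v], des)
    X[v, ] <- w@w
    resid[v] <- w@residual
  }
  list(X = X, resid = resid)
}

#' Train the hybrid regressor
#'
#' Computes the stage-1 NNLS weights of every training voxel (using the
#' ground-truth orientations, optionally jittered) and trains the split-arm
#' MLP to regress min-max-scaled (nu, fvf, Dex) per fascicle with an MSE
#' loss and the Adam optimizer.  Fascicles are ordered by descending nu.
#' Deterministic given \code{seed}.
#'
#' @param voxels a \linkS4class{VoxelSet} of training samples.
#' @param dict the \linkS4class{FingerprintDictionary} defining the latent
#'   space.
#' @param config see \code{\link{hybridConfig}}.
#' @param seed RNG seed covering jitter, initialization, shuffling, dropout.
#' @return A \linkS4class{TrainedRegressor} of kind \code{"hybrid"}.
#' @export
trainHybrid <- function(voxels, dict, config = hybridConfig(), seed = 1) {
  if (ncol(voxels) == 0) stop("empty training dataset")
  truth <- .orderedTruth(voxels)
  U <- truth$U
  if (!is.null(config$orientKappa))
    U <- withSeed(seed + 1000,
                  jitterOrientations(U, kappa = config$orientKappa))
  feats <- .hybridFeatures(voxels, dict, U)
  K <- ncol(truth$nu)
  N <- nAtoms(dict)
  scaling <- .targetScaling(K, dictParams(dict))
  Tm <- .scaleTargets(cbind(truth$nu, truth$fvf, truth$dex), scaling)
  featStats <- if (isTRUE(config$shareArms)) {
    # pooled over fascicle blocks so the tied pipeline stays symmetric
    stacked <- do.call(rbind, lapply(seq_len(K), function(k)
      feats$X[, (k - 1) * N + seq_len(N), drop = FALSE]))
    st <- .featStats(stacked)
    list(mu = rep(st$mu, K), sd = rep(st$sd, K))
  } else .featStats(feats$X)
  net <- .trainHybridNet(.standardize(feats$X, featStats), Tm, K, N, config,
                         seed)
  new("TrainedRegressor", kind = "hybrid", par = net$par,
      config = config, scaling = scaling, K = as.integer(K),
      meta = list(seed = seed, epochs = config$epochs, lr = config$lr,
                  lossHist = net$lossHist, bnState = net$state,
                  featStats = featStats,
                  datasetFingerprint = .dataFingerprint(feats$X[1, ]),
                  nTrain = ncol(voxels)))
}

.trainHybridNet <- function(X, Tm, K, N, config, seed) {
  par <- withSeed(seed,
    .initHybridPar(K, N, config$armWidth, config$hidden, ncol(Tm),
                   config$shareArms))
  state <- .bnStateInit(if (isTRUE(config$shareArms)) config$armWidth
                        else K * config$armWidth)
  nOutTot <- length(Tm)
  step <- function(par, state, idx, ep) {
    fw <- .hybridForward(par, state, X[idx, , drop = FALSE], K, N, config,
                         train = TRUE)
    D <- fw$Y - Tm[idx, , drop = FALSE]
    loss <- mean(D^2)
    dY <- 2 * D / length(D)
    grads <- .hybridBackward(par, fw$cache, dY, K, N, config)
    list(loss = loss, grads = grads, state = fw$state)
  }
  .trainLoop(par, state, nrow(X), config, seed, step)
}

#' Predict tissue parameters from NNLS weights
#'
#' Evaluation-mode forward pass of a trained hybrid network: sigmoid outputs
#' are affinely unscaled to (nu, fvf, Dex) and nu is renormalized to sum 1.
#'
#' @param model a \linkS4class{TrainedRegressor} of kind \code{"hybrid"}.
#' @param w an \linkS4class{NNLSWeights}, or an n x (K*N) matrix of weights.
#' @return A \linkS4class{FascicleEstimates} (no orientations: the hybrid
#'   method consumes externally supplied orientations).
#' @export
hybridPredict <- function(model, w) {
  stopifnot(is(model, "TrainedRegressor"))
  if (model@kind != "hybrid") stop("model is not a hybrid regressor")
  X <- if (is(w, "NNLSWeights")) matrix(w@w, 1) else as.matrix(w)
  K <- model@K
  N <- ncol(X) / K
  if (N != round(N)) stop("weight length inconsistent with model layout")
  cfg <- model@config
  X <- .standardize(X, model@meta$featStats)
  fw <- .hybridForward(model@par, model@meta$bnState, X, K, as.integer(N),
                       cfg, train = FALSE)
  P <- .unscaleTargets(fw$Y, model@scaling)
  nu <- P[, 1:K, drop = FALSE]
  nu <- nu / rowSums(nu)
  ors <- array(NA_real_, dim = c(nrow(X), 3, K))
  .newEstimates(nu, P[, K + (1:K), drop = FALSE],
                P[, 2 * K + (1:K), drop = FALSE], ors,
                rep(NA_real_, nrow(X)), "hybrid", rep(1, nrow(X)))
}

#' Fit a voxel set with the hybrid method
#'
#' Stage-1 NNLS projection per voxel followed by the network forward pass.
#' Exactly one NNLS solve per voxel.
#'
#' @param model a trained hybrid \linkS4class{TrainedRegressor}.
#' @param voxels a \linkS4class{VoxelSet}.
#' @param dict the dictionary to rotate (may differ in acquisition scheme
#'   from the training dictionary: the weight space only depends on K and
#'   N, which is what gives the hybrid method its protocol-transfer
#'   ability).
#' @param orientations \code{"truth"} or an n x 3 x K array of fascicle
#'   orientations to use in the projection.
#' @return A \linkS4class{FascicleEstimates}.
#' @export
fitHybrid <- function(model, voxels, dict, orientations = "truth") {
  U <- .resolveOrientations(voxels, orientations)
  if (dim(U)[3] != model@K) stop("fascicle count mismatch with model")
  feats <- .hybridFeatures(voxels, dict, U)
  est <- hybridPredict(model, feats$X)
  est@orientations <- U
  est@residual <- feats$resid
  est@method <- "hybrid"
  est
}
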