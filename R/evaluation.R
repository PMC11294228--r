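# Metrics and the two synthetic experiments: accuracy of the four
# estimators on a structured test set, and protocol transfer of the hybrid
# method.

#' Angular error between orientations
#'
#' arccos(|u . v|) in degrees, antipodally symmetric, clipped to [0, 90].
#' Accepts single vectors or row-wise matrices.
#'
#' @param u,v unit 3-vectors or n x 3 matrices.
#' @return numeric vector of angles in degrees.
#' @export
angularError <- function(u, v) {
  u <- matrix(as.numeric(u), ncol = 3); v <- matrix(as.numeric(v), ncol = 3)
  nu_ <- sqrt(rowSums(u^2)); nv <- sqrt(rowSums(v^2))
  if (any(nu_ < 1e-12) || any(nv < 1e-12)) stop("zero vector in angularError")
  d <- abs(rowSums(u * v)) / (nu_ * nv)
  pmin(pmax(acos(pmin(d, 1)) * 180 / pi, 0), 90)
}

#' Match estimated fascicles to ground truth
#'
#' Returns the permutation of the estimated fascicles that minimizes the
#' summed angular error against the true orientations (brute force over the
#' K! <= 6 permutations).  When the estimate carries no orientations the
#' labels are taken at face value (identity).
#'
#' @param estU K x 3 matrix of estimated orientations (may be all NA).
#' @param trueU K x 3 matrix of true orientations.
#' @return integer permutation p such that estU[p, ] aligns with trueU.
#' @export
matchFascicles <- function(estU, trueU) {
  K <- nrow(trueU)
  if (anyNA(estU)) return(seq_len(K))
  perms <- if (K == 1) list(1L) else if (K == 2) list(1:2, 2:1)
  else list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L), c(2L, 3L, 1L),
            c(3L, 1L, 2L), c(3L, 2L, 1L))
  best <- perms[[1]]; bestCost <- Inf
  for (p in perms) {
    cost <- sum(angularError(estU[p, , drop = FALSE], trueU))
    if (cost < bestCost) { bestCost <- cost; best <- p }
  }
  best
}

# per-voxel label matching: returns the estimate with columns permuted to
# align with the truth
.matchEstimates <- function(est, voxels) {
  Ut <- trueOrientations(voxels)
  K <- ncol(est@nu)
  if (all(is.na(est@orientations))) return(est)
  for (v in seq_len(nrow(est@nu))) {
    p <- matchFascicles(t(est@orientations[v, , ]), t(Ut[v, , ]))
    if (!identical(p, seq_len(K))) {
      est@nu[v, ] <- est@nu[v, p]
      est@fvf[v, ] <- est@fvf[v, p]
      est@dex[v, ] <- est@dex[v, p]
      est@orientations[v, , ] <- est@orientations[v, , p]
    }
  }
  est
}

.paramMatrix <- function(x, parameter) {
  switch(parameter, nu = if (is(x, "VoxelSet")) trueNu(x) else x@nu,
         fvf = if (is(x, "VoxelSet")) trueFvf(x) else x@fvf,
         dex = if (is(x, "VoxelSet")) trueDex(x) else x@dex,
         stop("unknown parameter ", parameter))
}

#' Mean absolute error of a parameter
#'
#' Pools all fascicles (after permutation matching when the estimator
#' reports orientations) and averages |estimate - truth|.
#'
#' @param est a \linkS4class{FascicleEstimates}.
#' @param voxels the ground-truth \linkS4class{VoxelSet}.
#' @param parameter one of \code{"nu"}, \code{"fvf"}, \code{"dex"}.
#' @param subset optional logical/integer voxel subset.
#' @return mean absolute error (same units as the parameter).
#' @export
mae <- function(est, voxels, parameter = "nu", subset = NULL) {
  est <- .matchEstimates(est, voxels)
  E <- .paramMatrix(est, parameter)
  T_ <- .paramMatrix(voxels, parameter)
  if (!is.null(subset)) { E <- E[subset, , drop = FALSE]; T_ <- T_[subset, , drop = FALSE] }
  if (nrow(E) == 0) stop("empty collection")
  mean(abs(E - T_))
}

#' Coefficient of determination of a parameter
#'
#' R^2 = 1 - SS_res / SS_tot over all pooled fascicles; may be negative for
#' predictors worse than the truth mean.
#'
#' @inheritParams mae
#' @return R^2 (unitless, <= 1).
#' @export
rSquared <- function(est, voxels, parameter = "nu", subset = NULL) {
  est <- .matchEstimates(est, voxels)
  E <- .paramMatrix(est, parameter)
  T_ <- .paramMatrix(voxels, parameter)
  if (!is.null(subset)) { E <- E[subset, , drop = FALSE]; T_ <- T_[subset, , drop = FALSE] }
  sst <- sum((T_ - mean(T_))^2)
  if (sst < 1e-300) stop("zero-variance truth: R^2 undefined")
  1 - sum((E - T_)^2) / sst
}

#' Normalized histogram of signed estimate differences
#'
#' Density histogram (integrating to 1) of per-voxel signed differences
#' between two estimators for one parameter/fascicle, the comparison used
#' to contrast accelerated methods against the reference.
#'
#' @param estA,estB two \linkS4class{FascicleEstimates} on the same voxels.
#' @param parameter,fascicle what to compare.
#' @param breaks passed to \code{hist}.
#' @return object of class \code{histogram} (densities integrate to 1).
#' @export
differenceHistogram <- function(estA, estB, parameter = "fvf", fascicle = 1,
                                breaks = 50) {
  d <- .paramMatrix(estA, parameter)[, fascicle] -
    .paramMatrix(estB, parameter)[, fascicle]
  graphics::hist(d, breaks = breaks, plot = FALSE)
}

# combined per-voxel loop: exhaustive MF and/or the NNLS projection on a
# shared rotated design (the expensive part of the experiments)
.batchFit <- function(voxels, dict, U, doMF = TRUE, doProj = TRUE) {
  Y <- signals(voxels)
  n <- ncol(Y); K <- dim(U)[3]; N <- nAtoms(dict)
  out <- list()
  if (doMF) {
    nu <- fvf <- dex <- matrix(NA_real_, n, K)
    resid <- solves <- numeric(n)
  }
  if (doProj) { X <- matrix(0, n, K * N); presid <- numeric(n) }
  for (v in seq_len(n)) {
    des <- rotatedDesign(dict, t(U[v, , ]))
    if (doMF) {
      est <- mfExhaustive(Y[, v], des)
      nu[v, ] <- est@nu; fvf[v, ] <- est@fvf; dex[v, ] <- est@dex
      resid[v] <- est@residual; solves[v] <- est@nSolves
    }
    if (doProj) {
      w <- nnlsProjection(Y[, v], des)
      X[v, ] <- w@w; presid[v] <- w@residual
    }
  }
  if (doMF)
    out$mf <- .newEstimates(nu, fvf, dex, U, resid, "mf_exhaustive", solves)
  if (doProj) out$proj <- list(X = X, resid = presid)
  out
}

.maeRow <- function(est, voxels, method, stratum, value, idx = NULL) {
  data.frame(method = method,
             parameter = c("nu", "fvf", "dex"),
             stratum = stratum, value = value,
             mae = vapply(c("nu", "fvf", "dex"), function(p)
               mae(est, voxels, p, subset = idx), numeric(1)),
             row.names = NULL)
}

.summarizeMethods <- function(ests, voxels) {
  snr <- voxelSnr(voxels)
  nu1 <- trueNu(voxels)[, 1]
  nu1Bins <- sort(unique(round(nu1, 3)))
  useNuStrata <- length(nu1Bins) <= 8
  metrics <- list()
  for (m in names(ests)) {
    est <- ests[[m]]
    metrics[[length(metrics) + 1]] <- .maeRow(est, voxels, m, "all", NA_real_)
    for (s in sort(unique(snr)))
      metrics[[length(metrics) + 1]] <-
        .maeRow(est, voxels, m, "snr", s, idx = which(snr == s))
    if (useNuStrata)
      for (b in nu1Bins)
        metrics[[length(metrics) + 1]] <-
          .maeRow(est, voxels, m, "nu1", b, idx = which(round(nu1, 3) == b))
    r2 <- data.frame(method = m, parameter = c("nu", "fvf", "dex"),
                     stratum = "r2", value = NA_real_,
                     mae = vapply(c("nu", "fvf", "dex"), function(p)
                       rSquared(est, voxels, p), numeric(1)))
    metrics[[length(metrics) + 1]] <- r2
  }
  do.call(rbind, metrics)
}

.angularSummary <- function(ests, voxels, extra = NULL) {
  Ut <- trueOrientations(voxels)
  rows <- list()
  addRow <- function(method, U) {
    errs <- unlist(lapply(seq_len(dim(Ut)[3]), function(k)
      angularError(U[, , k], Ut[, , k])))
    rows[[length(rows) + 1]] <<- data.frame(method = method,
                                            meanAngularError = mean(errs),
                                            medianAngularError = stats::median(errs))
  }
  for (m in names(ests)) {
    U <- ests[[m]]@orientations
    if (!all(is.na(U))) {
      est <- .matchEstimates(ests[[m]], voxels)
      addRow(m, est@orientations)
    }
  }
  if (!is.null(extra)) for (m in names(extra)) addRow(m, extra[[m]])
  do.call(rbind, rows)
}

#' Experiment I: accuracy of the four estimators on a structured test set
#'
#' Trains the hybrid and fully-learned regressors on a freshly generated
#' training set, builds the structured test set, and evaluates four
#' methods: reference exhaustive MF with true orientations, reference MF
#' with jittered orientations (the stand-in for an external orientation
#' estimator such as CSD, calibrated to about 7.4 degrees mean error at the
#' default concentration), the hybrid method and the fully-learned method.
#' Reports MAE per parameter (overall, by SNR, by nu1), R^2, angular
#' errors, and keeps per-voxel absolute errors.
#'
#' @param dict a \linkS4class{FingerprintDictionary}.
#' @param K number of fascicles.
#' @param seed master seed; all stages derive their seeds from it.
#' @param nTrain,nTest training/test sizes.
#' @param nTrainHybrid number of training voxels (a leading subset of the
#'   shared training set) whose NNLS features are computed for the hybrid
#'   regressor; the stage-1 projections dominate training cost while the
#'   hybrid method needs comparatively little data, so a subset keeps
#'   desk-scale runs affordable.  Defaults to all of them.
#' @param hybridCfg,flCfg network configurations.
#' @param csdKappa von Mises-Fisher concentration of the jittered
#'   orientations.
#' @param methods subset of
#'   \code{c("mf_true", "mf_csd", "hybrid", "fully_learned")}.
#' @return An \linkS4class{EvalReport}.
#' @export
runExperiment1 <- function(dict, K = 2, seed = 1, nTrain = 100000,
                           nTest = 15000, hybridCfg = hybridConfig(),
                           flCfg = flConfig(), csdKappa = 94,
                           nTrainHybrid = nTrain,
                           methods = c("mf_true", "mf_csd", "hybrid",
                                       "fully_learned")) {
  train <- generateDataset(nTrain, dict, synthConfig(K = K), seed = seed)
  test <- buildTestSetExp1(dict, K = K, seed = seed + 1,
                           n = nTest)
  Utrue <- trueOrientations(test)
  ests <- list()
  models <- list()
  if ("hybrid" %in% methods)
    models$hybrid <- trainHybrid(train[, seq_len(min(nTrainHybrid, ncol(train)))],
                                 dict, hybridCfg, seed = seed + 2)
  if ("fully_learned" %in% methods)
    models$fl <- trainFullyLearned(train, grid = dictParams(dict),
                                   config = flCfg, seed = seed + 3)
  doMF <- "mf_true" %in% methods
  doHyb <- "hybrid" %in% methods
  if (doMF || doHyb) {
    bf <- .batchFit(test, dict, Utrue, doMF = doMF, doProj = doHyb)
    if (doMF) { bf$mf@method <- "mf_true"; ests$mf_true <- bf$mf }
    if (doHyb) {
      est <- hybridPredict(models$hybrid, bf$proj$X)
      est@orientations <- Utrue
      est@residual <- bf$proj$resid
      ests$hybrid <- est
      # hybrid consumes supplied orientations; do not score them as its own
      ests$hybrid@orientations <- array(NA_real_, dim(Utrue))
    }
  }
  Ujit <- NULL
  if ("mf_csd" %in% methods) {
    Ujit <- withSeed(seed + 4, jitterOrientations(Utrue, kappa = csdKappa))
    bf <- .batchFit(test, dict, Ujit, doMF = TRUE, doProj = FALSE)
    bf$mf@method <- "mf_csd"
    # score against the truth labels; orientations used are the jittered ones
    ests$mf_csd <- bf$mf
    ests$mf_csd@orientations <- array(NA_real_, dim(Utrue))
  }
  if ("fully_learned" %in% methods)
    ests$fully_learned <- fitFullyLearned(models$fl, test)

  metrics <- .summarizeMethods(ests, test)
  extra <- if (!is.null(Ujit)) list(csd_standin = Ujit) else NULL
  angular <- .angularSummary(ests, test, extra = extra)
  errors <- lapply(ests, function(e) {
    em <- .matchEstimates(e, test)
    list(nu = abs(em@nu - trueNu(test)), fvf = abs(em@fvf - trueFvf(test)),
         dex = abs(em@dex - trueDex(test)),
         nSolves = em@nSolves)
  })
  new("EvalReport", metrics = metrics, angular = angular, errors = errors,
      config = list(experiment = 1, K = K, seed = seed, nTrain = nTrain,
                    nTest = nTest, csdKappa = csdKappa,
                    scheme = .dataFingerprint(bValues(acquisitionScheme(dict))),
                    models = lapply(models, function(m) m@meta),
                    modelObjects = models))
}

#' Experiment II: protocol transfer of the hybrid method
#'
#' Regenerates the dictionary and test set under the clinical acquisition
#' scheme and compares (a) the source-trained hybrid model applied without
#' retraining (its stage-1 NNLS runs on the clinical design; the weight
#' space K*N is scheme-independent), (b) a hybrid model retrained on the
#' clinical scheme, and (c, d) reference MF with true and jittered
#' orientations.
#'
#' @param hybridModel hybrid \linkS4class{TrainedRegressor} trained on the
#'   source (HCP-style) scheme.
#' @param dict the source dictionary (grid and substrate are reused).
#' @param seed master seed.
#' @param nTrain,nTest clinical-scheme training/test sizes.
#' @param hybridCfg configuration for the retrained model.
#' @param csdKappa jitter concentration for the external-orientation
#'   stand-in.
#' @return An \linkS4class{EvalReport}.
#' @export
runExperiment2 <- function(hybridModel, dict, seed = 1, nTrain = 30000,
                           nTest = 3000, hybridCfg = hybridConfig(),
                           csdKappa = 94) {
  stopifnot(is(hybridModel, "TrainedRegressor"), hybridModel@kind == "hybrid")
  K <- hybridModel@K
  scheme2 <- clinicalScheme(seed = seed)
  sub <- dict@substrate
  dict2 <- buildDictionary(dictParams(dict), scheme2, generator = "analytic",
                           substrate = substrateConfig(sub$radiusMean,
                                                       sub$radiusSd, sub$dIn))
  train2 <- generateDataset(nTrain, dict2, synthConfig(K = K), seed = seed + 10)
  test2 <- buildTestSetExp1(dict2, K = K, seed = seed + 11, n = nTest)
  Utrue <- trueOrientations(test2)

  bf <- .batchFit(test2, dict2, Utrue, doMF = TRUE, doProj = TRUE)
  bf$mf@method <- "mf_true"
  ests <- list(mf_true = bf$mf)

  estSrc <- hybridPredict(hybridModel, bf$proj$X)
  estSrc@method <- "hybrid_transfer"
  ests$hybrid_transfer <- estSrc

  retrained <- trainHybrid(train2, dict2, hybridCfg, seed = seed + 12)
  estRe <- hybridPredict(retrained, bf$proj$X)
  estRe@method <- "hybrid_retrained"
  ests$hybrid_retrained <- estRe

  Ujit <- withSeed(seed + 13, jitterOrientations(Utrue, kappa = csdKappa))
  bfj <- .batchFit(test2, dict2, Ujit, doMF = TRUE, doProj = FALSE)
  bfj$mf@method <- "mf_csd"
  bfj$mf@orientations <- array(NA_real_, dim(Utrue))
  ests$mf_csd <- bfj$mf

  metrics <- .summarizeMethods(ests, test2)
  angular <- .angularSummary(ests, test2,
                             extra = list(csd_standin = Ujit))
  new("EvalReport", metrics = metrics, angular = angular,
      errors = lapply(ests, function(e) list(nSolves = e@nSolves)),
      config = list(experiment = 2, K = K, seed = seed, nTrain = nTrain,
                    nTest = nTest,
                    sourceScheme = .dataFingerprint(bValues(acquisitionScheme(dict))),
                    targetScheme = .dataFingerprint(bValues(scheme2)),
                    retrainedMeta = retrained@meta))
}

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport (experiment %s)\n", object@config$experiment))
  ov <- object@metrics[object@metrics$stratum == "all", ]
  if (nrow(ov)) {
    w <- stats::reshape(ov[, c("method", "parameter", "mae")],
                        idvar = "method", timevar = "parameter",
                        direction = "wide")
    colnames(w) <- sub("mae\\.", "MAE ", colnames(w))
    print(w, row.names = FALSE, digits = 4)
  }
  if (nrow(object@angular)) {
    cat("angular errors (degrees):\n")
    print(object@angular, row.names = FALSE, digits = 4)
  }
})

#' Extract an overall MAE from an evaluation report
#'
#' @param report an \linkS4class{EvalReport}.
#' @param method,parameter which entry to read.
#' @param stratum,value optional stratum filter (e.g. \code{"snr"}, 20).
#' @return numeric MAE.
#' @export
reportMae <- function(report, method, parameter, stratum = "all",
                      value = NULL) {
  m <- report@metrics
  sel <- m$method == method & m$parameter == parameter & m$stratum == stratum
  if (!is.null(value)) sel <- sel & !is.na(m$value) & m$value == value
  out <- m$mae[sel]
  if (length(out) != 1) stop("no unique matching report entry")
  out
}
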