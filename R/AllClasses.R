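#' PGSE acquisition scheme
#'
#' Gradient table and pulse timing for a pulsed-gradient spin-echo (PGSE)
#' acquisition.  Each of the M measurements has a unit gradient direction
#' (the zero vector for b = 0 measurements), a b-value in s/mm^2, a gradient
#' strength in mT/m, and a shell id grouping measurements that share a
#' b-value.  The gradient duration delta and diffusion time Delta (ms) are
#' shared by all measurements; TE and TR are carried as metadata.
#'
#' @slot directions M x 3 matrix of unit gradient directions.
#' @slot bvalues numeric(M), b-values in s/mm^2.
#' @slot gradientStrengths numeric(M), gradient amplitudes in mT/m.
#' @slot delta,Delta gradient duration and diffusion time in ms.
#' @slot te,tr echo and repetition time in ms (may be NA).
#' @slot shellIds integer(M), 0 for b = 0, then ascending with b.
#' @export
setClass("AcquisitionScheme",
  representation(directions = "matrix", bvalues = "numeric",
                 gradientStrengths = "numeric", delta = "numeric",
                 Delta = "numeric", te = "numeric", tr = "numeric",
                 shellIds = "integer"))

setValidity("AcquisitionScheme", function(object) {
  M <- nrow(object@directions)
  msg <- character()
  if (ncol(object@directions) != 3) msg <- c(msg, "directions must be M x 3")
  if (length(object@bvalues) != M || length(object@shellIds) != M ||
      length(object@gradientStrengths) != M)
    msg <- c(msg, "per-measurement fields must all have length M")
  if (any(object@bvalues < 0)) msg <- c(msg, "b-values must be nonnegative")
  nrm <- sqrt(rowSums(object@directions^2))
  bad <- abs(nrm - 1) > 1e-9 & !(object@bvalues == 0 & nrm < 1e-9)
  if (any(bad)) msg <- c(msg, "directions must be unit vectors (or zero at b = 0)")
  for (s in unique(object@shellIds)) {
    bs <- object@bvalues[object@shellIds == s]
    if (diff(range(bs)) > 100)
      msg <- c(msg, sprintf("shell %d mixes distinct b-values", s))
  }
  if (length(msg)) msg else TRUE
})

#' Single-fascicle substrate description
#'
#' Microstructural configuration of one fascicle: cylinders with
#' gamma-distributed radii, an intra-axonal diffusivity, a fiber volume
#' fraction and an extra-axonal diffusivity (um and um^2/ms).
#'
#' @export
setClass("SubstrateConfig",
  representation(radiusMean = "numeric", radiusSd = "numeric",
                 dIn = "numeric", fvf = "numeric", dEx = "numeric"))

setValidity("SubstrateConfig", function(object) {
  msg <- character()
  if (object@radiusMean <= 0 || object@radiusSd <= 0)
    msg <- c(msg, "radius mean and sd must be positive")
  if (object@dIn <= 0 || object@dEx <= 0)
    msg <- c(msg, "diffusivities must be positive")
  if (object@fvf <= 0 || object@fvf > 0.9)
    msg <- c(msg, "fvf must lie in (0, 0.9]")
  if (length(msg)) msg else TRUE
})

#' Periodic 2D cylinder packing
#'
#' Random sequential addition packing of non-overlapping circles in a
#' periodic square cell, used as the substrate of the Monte Carlo signal
#' simulator.
#' @export
setClass("CylinderPacking",
  representation(centers = "matrix", radii = "numeric", cellSize = "numeric",
                 achievedFvf = "numeric"))

setValidity("CylinderPacking", function(object) {
  msg <- character()
  if (nrow(object@centers) != length(object@radii))
    msg <- c(msg, "one radius per center required")
  if (any(object@radii <= 0)) msg <- c(msg, "radii must be positive")
  if (length(msg)) msg else TRUE
})

#' Single-fascicle fingerprint dictionary
#'
#' N canonical (cylinder axis = z) b0-normalized signal atoms with their
#' (fvf, Dex) labels, tied to the acquisition scheme they were simulated
#' under.  Atoms are stored one per row (N x M).
#' @export
setClass("FingerprintDictionary",
  representation(atoms = "matrix", params = "data.frame",
                 scheme = "AcquisitionScheme", generator = "character",
                 substrate = "list"))

setValidity("FingerprintDictionary", function(object) {
  msg <- character()
  if (nrow(object@atoms) != nrow(object@params))
    msg <- c(msg, "params table must align with atom rows")
  if (ncol(object@atoms) != nrow(object@scheme@directions))
    msg <- c(msg, "atom length must equal scheme measurement count")
  if (any(object@atoms <= 0) || any(object@atoms > 1 + 1e-9))
    msg <- c(msg, "atom values must lie in (0, 1]")
  b0 <- object@scheme@bvalues == 0
  if (any(b0) && any(abs(object@atoms[, b0, drop = FALSE] - 1) > 1e-9))
    msg <- c(msg, "atoms must equal 1 at b = 0 measurements")
  if (!object@generator %in% c("analytic", "montecarlo"))
    msg <- c(msg, "generator must be 'analytic' or 'montecarlo'")
  if (length(msg)) msg else TRUE
})

#' Fascicle-specific rotated design
#'
#' K sub-dictionaries, each the canonical dictionary rotated to one fascicle
#' orientation; block k is an M x N matrix.
#' @export
setClass("RotatedDesign",
  representation(blocks = "list", orientations = "matrix",
                 params = "data.frame", scheme = "AcquisitionScheme"))

# structural checks only: the (0, 1] signal-range invariant of the block
# columns is exercised in the test suite, not on every construction (designs
# are built once per voxel in the experiment loops)
setValidity("RotatedDesign", function(object) {
  msg <- character()
  if (length(object@blocks) != nrow(object@orientations))
    msg <- c(msg, "one orientation per block required")
  if (!.unitRows(object@orientations, tol = 1e-6))
    msg <- c(msg, "orientations must be unit vectors")
  if (length(msg)) msg else TRUE
})

#' Non-negative projection weights
#'
#' Weight vector of the single K*N-variable NNLS projection of a voxel
#' signal onto all rotated dictionary atoms (the hybrid method's latent
#' representation).
#' @export
setClass("NNLSWeights",
  representation(w = "numeric", layout = "integer", residual = "numeric",
                 nSolves = "numeric"))

setValidity("NNLSWeights", function(object) {
  msg <- character()
  if (any(object@w < 0)) msg <- c(msg, "weights must be nonnegative")
  if (length(object@w) != prod(object@layout))
    msg <- c(msg, "weight length must equal K * N")
  if (length(msg)) msg else TRUE
})

#' Per-fascicle estimates for a set of voxels
#'
#' Relative volume fractions nu (rows sum to 1), fiber volume fractions,
#' extra-axonal diffusivities and (when estimated) orientations, one row per
#' voxel and one column per fascicle.  `orientations` is an n x 3 x K array
#' with all-NA entries when the method does not estimate orientations.
#' @export
setClass("FascicleEstimates",
  representation(nu = "matrix", fvf = "matrix", dex = "matrix",
                 orientations = "array", residual = "numeric",
                 method = "character", nSolves = "numeric"))

setValidity("FascicleEstimates", function(object) {
  msg <- character()
  if (any(object@nu < -1e-12)) msg <- c(msg, "nu must be nonnegative")
  if (nrow(object@nu) > 0 && any(abs(rowSums(object@nu) - 1) > 1e-9))
    msg <- c(msg, "nu rows must sum to 1")
  if (any(object@residual < 0, na.rm = TRUE))
    msg <- c(msg, "residuals must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' Trained regressor (hybrid or fully-learned)
#'
#' Network parameters plus the affine output-scaling metadata used to map
#' sigmoid outputs back to physical parameter ranges.
#' @export
setClass("TrainedRegressor",
  representation(kind = "character", par = "list", config = "list",
                 scaling = "list", K = "integer", meta = "list"))

setValidity("TrainedRegressor", function(object) {
  msg <- character()
  if (!object@kind %in% c("hybrid", "fully_learned"))
    msg <- c(msg, "kind must be 'hybrid' or 'fully_learned'")
  sc <- object@scaling
  if (!all(c("lo", "hi") %in% names(sc)) || any(!is.finite(sc$lo)) ||
      any(!is.finite(sc$hi)) || any(sc$lo >= sc$hi))
    msg <- c(msg, "scaling ranges must be finite with lo < hi")
  if (length(msg)) msg else TRUE
})

#' Synthetic voxel collection
#'
#' A SummarizedExperiment with measurements as rows and voxels as columns.
#' Assays `signal` (noisy) and `signalClean`; per-voxel ground truth (K, nu,
#' fvf, Dex, orientations, SNR) in `colData`; the acquisition scheme,
#' generating configuration and seed in `metadata`.
#' @import SummarizedExperiment
#' @export
setClass("VoxelSet", contains = "SummarizedExperiment")

setValidity("VoxelSet", function(object) {
  msg <- character()
  cd <- SummarizedExperiment::colData(object)
  need <- c("snr", "nu", "fvf", "dex", "orientations")
  if (!all(need %in% colnames(cd)))
    msg <- c(msg, paste("colData must contain", paste(need, collapse = ", ")))
  if (!"scheme" %in% names(S4Vectors::metadata(object)))
    msg <- c(msg, "metadata must carry the acquisition scheme")
  if ("nu" %in% colnames(cd) && ncol(object) > 0) {
    if (any(abs(rowSums(cd$nu) - 1) > 1e-9))
      msg <- c(msg, "nu rows must sum to 1")
  }
  if (length(msg)) msg else TRUE
})

#' Per-shell spherical-harmonics features
#'
#' Real even-degree SH coefficients fitted per shell (ascending b); 91
#' coefficients per shell at lmax = 12.
#' @export
setClass("SHFeatures",
  representation(coefficients = "matrix", lmax = "integer",
                 shellB = "numeric", lambda = "numeric"))

setValidity("SHFeatures", function(object) {
  l <- seq(0, object@lmax, by = 2)
  nc <- sum(2 * l + 1)
  if (nrow(object@coefficients) != nc)
    return(sprintf("expected %d coefficients per shell", nc))
  if (ncol(object@coefficients) != length(object@shellB))
    return("one coefficient column per shell required")
  TRUE
})

#' Evaluation report
#'
#' Long-format metric table (method x parameter x stratum), angular-error
#' summaries, and the configuration snapshot of an experiment run.
#' @export
setClass("EvalReport",
  representation(metrics = "data.frame", angular = "data.frame",
                 errors = "list", config = "list"))
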