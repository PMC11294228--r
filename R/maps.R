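# Voxel-wise parameter maps from 4D volumes (NIfTI plumbing).

#' Fit an estimator voxel-wise over a 4D volume
#'
#' Applies a per-voxel estimator inside a binary mask and assembles one 3D
#' map per parameter per fascicle (and per orientation component when the
#' estimator reports orientations).  Voxels outside the mask are
#' zero-filled.
#'
#' @param image 4D numeric array (X x Y x Z x M) with the 4th dimension
#'   matching the scheme's measurement count.
#' @param mask 3D binary array.
#' @param scheme the \linkS4class{AcquisitionScheme} of the acquisition.
#' @param fitFun function taking a numeric(M) signal and returning a
#'   single-row \linkS4class{FascicleEstimates} (e.g. a closure around
#'   \code{\link{mfExhaustive}}, \code{\link{fitHybrid}} stages or
#'   \code{\link{flPredict}}).
#' @return named list of 3D arrays (\code{nu1}, \code{fvf1}, \code{dex1},
#'   ..., \code{u1x}, ... when available).
#' @export
fitVolume <- function(image, mask, scheme, fitFun) {
  di <- dim(image)
  if (length(di) != 4 || di[4] != nMeasurements(scheme))
    stop("image 4th dimension must equal the scheme measurement count")
  if (!all(dim(mask) == di[1:3]))
    stop("mask dimensions must match the image")
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    warning("empty mask: returning all-zero maps")
    return(list(nu1 = array(0, di[1:3])))
  }
  first <- fitFun(image[idx[1, 1], idx[1, 2], idx[1, 3], ])
  K <- ncol(first@nu)
  hasU <- !all(is.na(first@orientations))
  nm <- c(paste0("nu", 1:K), paste0("fvf", 1:K), paste0("dex", 1:K))
  if (hasU) nm <- c(nm, as.vector(outer(c("x", "y", "z"), 1:K,
                                        function(a, k) paste0("u", k, a))))
  maps <- stats::setNames(lapply(nm, function(x) array(0, di[1:3])), nm)
  fill <- function(est, i) {
    for (k in 1:K) {
      maps[[paste0("nu", k)]][idx[i, 1], idx[i, 2], idx[i, 3]] <<- est@nu[1, k]
      maps[[paste0("fvf", k)]][idx[i, 1], idx[i, 2], idx[i, 3]] <<- est@fvf[1, k]
      maps[[paste0("dex", k)]][idx[i, 1], idx[i, 2], idx[i, 3]] <<- est@dex[1, k]
      if (hasU) for (ci in 1:3)
        maps[[paste0("u", k, c("x", "y", "z")[ci])]][idx[i, 1], idx[i, 2],
                                                     idx[i, 3]] <<-
          est@orientations[1, ci, k]
    }
  }
  fill(first, 1)
  for (i in seq_len(nrow(idx))[-1])
    fill(fitFun(image[idx[i, 1], idx[i, 2], idx[i, 3], ]), i)
  maps
}
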