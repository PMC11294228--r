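#' @import methods
#' @importFrom stats rnorm runif rgamma dgamma qgamma approx splinefun sd
#' @importFrom utils head read.table write.table
NULL

#' @export
setGeneric("directions", function(x) standardGeneric("directions"))
#' @export
setGeneric("bValues", function(x) standardGeneric("bValues"))
#' @export
setGeneric("gradientStrengths", function(x) standardGeneric("gradientStrengths"))
#' @export
setGeneric("shellIds", function(x) standardGeneric("shellIds"))
#' @export
setGeneric("nMeasurements", function(x) standardGeneric("nMeasurements"))
#' @export
setGeneric("pulseDuration", function(x) standardGeneric("pulseDuration"))
#' @export
setGeneric("diffusionTime", function(x) standardGeneric("diffusionTime"))

#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))
#' @export
setGeneric("dictParams", function(x) standardGeneric("dictParams"))
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))
#' @export
setGeneric("generatorTag", function(x) standardGeneric("generatorTag"))
#' @export
setGeneric("acquisitionScheme", function(x) standardGeneric("acquisitionScheme"))

#' @export
setGeneric("nFascicles", function(x) standardGeneric("nFascicles"))
#' @export
setGeneric("signals", function(x) standardGeneric("signals"))
#' @export
setGeneric("signalsClean", function(x) standardGeneric("signalsClean"))
#' @export
setGeneric("trueNu", function(x) standardGeneric("trueNu"))
#' @export
setGeneric("trueFvf", function(x) standardGeneric("trueFvf"))
#' @export
setGeneric("trueDex", function(x) standardGeneric("trueDex"))
#' @export
setGeneric("trueOrientations", function(x) standardGeneric("trueOrientations"))
#' @export
setGeneric("voxelSnr", function(x) standardGeneric("voxelSnr"))

#' @export
setGeneric("estNu", function(x) standardGeneric("estNu"))
#' @export
setGeneric("estFvf", function(x) standardGeneric("estFvf"))
#' @export
setGeneric("estDex", function(x) standardGeneric("estDex"))
#' @export
setGeneric("estOrientations", function(x) standardGeneric("estOrientations"))
#' @export
setGeneric("fitResiduals", function(x) standardGeneric("fitResiduals"))
#' @export
setGeneric("nnlsSolves", function(x) standardGeneric("nnlsSolves"))
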