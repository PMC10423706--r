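#' @include AllClasses.R
NULL

#' @export
setGeneric("pBar", function(object) standardGeneric("pBar"))

#' @export
setGeneric("strandRatio", function(object) standardGeneric("strandRatio"))

#' @export
setGeneric("rtEfficiency", function(object) standardGeneric("rtEfficiency"))

#' @export
setGeneric("inputCase", function(object) standardGeneric("inputCase"))

#' @export
setGeneric("meanInput", function(object) standardGeneric("meanInput"))

#' @export
setGeneric("varInput", function(object) standardGeneric("varInput"))

#' @export
setGeneric("inputFamily", function(object) standardGeneric("inputFamily"))

#' @export
setGeneric("dispersion", function(object) standardGeneric("dispersion"))

#' @export
setGeneric("nCycles", function(object) standardGeneric("nCycles"))

#' @export
setGeneric("meanCounts", function(object) standardGeneric("meanCounts"))

#' @export
setGeneric("varCounts", function(object) standardGeneric("varCounts"))

#' @export
setGeneric("covWithInitial", function(object, strand = c("forward", "reverse"))
    standardGeneric("covWithInitial"))

#' @export
setGeneric("probeState", function(object) standardGeneric("probeState"))

#' @export
setGeneric("probeConcentration", function(object)
    standardGeneric("probeConcentration"))

#' @export
setGeneric("plateId", function(object) standardGeneric("plateId"))

#' @export
setGeneric("background", function(object) standardGeneric("background"))

#' @export
setGeneric("incremental", function(object) standardGeneric("incremental"))

#' @export
setGeneric("detectionLimit", function(object) standardGeneric("detectionLimit"))

#' @export
setGeneric("maxDetectableCV", function(object)
    standardGeneric("maxDetectableCV"))
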