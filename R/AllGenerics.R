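NULL

#' @export
setGeneric("probeInfo", function(x) standardGeneric("probeInfo"))

#' @export
setGeneric("probeClass", function(x) standardGeneric("probeClass"))

#' @export
setGeneric("sampleInfo", function(x) standardGeneric("sampleInfo"))

#' @export
setGeneric("stageTag", function(x) standardGeneric("stageTag"))

#' @export
setGeneric("normFactors", function(x) standardGeneric("normFactors"))

#' @export
setGeneric("truthRecord", function(x) standardGeneric("truthRecord"))

#' @export
setGeneric("backgroundCorrect", function(x, ...) standardGeneric("backgroundCorrect"))

#' @export
setGeneric("spikeinNormalize", function(x, ...) standardGeneric("spikeinNormalize"))

#' @export
setGeneric("contentNormalize", function(x, ...) standardGeneric("contentNormalize"))

#' @export
setGeneric("quantileNormalize", function(x, ...) standardGeneric("quantileNormalize"))

#' @export
setGeneric("normalizePipeline", function(x, ...) standardGeneric("normalizePipeline"))
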