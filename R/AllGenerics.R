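#' @rdname AcousticRecording-class
#' @param object,x an object.
#' @export
setGeneric("samples", function(x) standardGeneric("samples"))

#' @rdname AcousticRecording-class
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))

#' @rdname AcousticRecording-class
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname AcousticRecording-class
#' @export
setGeneric("durationSec", function(x) standardGeneric("durationSec"))

#' @rdname PowerSpectrum-class
#' @export
setGeneric("freqHz", function(x) standardGeneric("freqHz"))

#' @rdname PowerSpectrum-class
#' @export
setGeneric("powerDb", function(x) standardGeneric("powerDb"))

#' @rdname SpectralExperiment-class
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' @rdname SpectralExperiment-class
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' @rdname SpectralExperiment-class
#' @export
setGeneric("dataPartition", function(x) standardGeneric("dataPartition"))

#' @rdname SpectralExperiment-class
#' @param value replacement value.
#' @export
setGeneric("dataPartition<-",
           function(x, value) standardGeneric("dataPartition<-"))

#' @rdname GroupingSolution-class
#' @export
setGeneric("assignment", function(x) standardGeneric("assignment"))

#' @rdname GroupingSolution-class
#' @export
setGeneric("grouping", function(x) standardGeneric("grouping"))

#' @rdname GroupingSolution-class
#' @export
setGeneric("fitness", function(x) standardGeneric("fitness"))

#' @rdname GroupingSolution-class
#' @export
setGeneric("bestGroup", function(x) standardGeneric("bestGroup"))

#' @rdname GroupingSolution-class
#' @param id group id.
#' @export
setGeneric("groupMembers", function(x, id) standardGeneric("groupMembers"))

#' @rdname GGAResult-class
#' @export
setGeneric("selectedFeatures",
           function(x) standardGeneric("selectedFeatures"))

#' @rdname GGAResult-class
#' @export
setGeneric("fitnessHistory", function(x) standardGeneric("fitnessHistory"))
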