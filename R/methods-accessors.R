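#' @rdname AcousticRecording-class
#' @export
setMethod("samples", "AcousticRecording", function(x) x@samples)

#' @rdname AcousticRecording-class
#' @export
setMethod("sampleRate", "AcousticRecording", function(x) x@sampleRate)

#' @rdname AcousticRecording-class
#' @export
setMethod("nSamples", "AcousticRecording", function(x) length(x@samples))

#' @rdname AcousticRecording-class
#' @export
setMethod("durationSec", "AcousticRecording",
          function(x) length(x@samples) / x@sampleRate)

setMethod("show", "AcousticRecording", function(object) {
  cat(sprintf("AcousticRecording: %d samples @ %g Hz (%.3f s)\n",
              nSamples(object), sampleRate(object), durationSec(object)))
})

#' @rdname PowerSpectrum-class
#' @export
setMethod("freqHz", "PowerSpectrum", function(x) x@freq)

#' @rdname PowerSpectrum-class
#' @export
setMethod("powerDb", "PowerSpectrum", function(x) x@power)

setMethod("show", "PowerSpectrum", function(object) {
  cat(sprintf("PowerSpectrum (%s grid): %d bins, %.2f-%.2f Hz\n",
              object@gridKind, length(object@freq),
              min(object@freq), max(object@freq)))
})

#' @rdname SpectralExperiment-class
#' @export
setMethod("featureMatrix", "SpectralExperiment",
          function(x) t(SummarizedExperiment::assay(x, "intensity")))

#' @rdname SpectralExperiment-class
#' @export
setMethod("classLabels", "SpectralExperiment",
          function(x) SummarizedExperiment::colData(x)$label)

#' @rdname SpectralExperiment-class
#' @export
setMethod("dataPartition", "SpectralExperiment", function(x) {
  cd <- SummarizedExperiment::colData(x)
  if ("partition" %in% colnames(cd)) cd$partition
  else rep(NA_character_, ncol(x))
})

#' @rdname SpectralExperiment-class
#' @export
setReplaceMethod("dataPartition", "SpectralExperiment", function(x, value) {
  SummarizedExperiment::colData(x)$partition <- as.character(value)
  validObject(x)
  x
})

#' @rdname GroupingSolution-class
#' @export
setMethod("assignment", "GroupingSolution", function(x) x@assignment)

#' @rdname GroupingSolution-class
#' @export
setMethod("grouping", "GroupingSolution", function(x) x@grouping)

#' @rdname GroupingSolution-class
#' @export
setMethod("fitness", "GroupingSolution", function(x) x@fitness)

#' @rdname GroupingSolution-class
#' @export
setMethod("bestGroup", "GroupingSolution", function(x) x@bestGroup)

#' @rdname GroupingSolution-class
#' @export
setMethod("groupMembers", "GroupingSolution",
          function(x, id) which(x@assignment == id))

setMethod("show", "GroupingSolution", function(object) {
  sizes <- tabulate(match(object@assignment, object@grouping),
                    nbins = length(object@grouping))
  cat(sprintf("GroupingSolution: E=%d, %d groups (ids %s; sizes %s)\n",
              length(object@assignment), length(object@grouping),
              paste(object@grouping, collapse = ","),
              paste(sizes, collapse = ",")))
  if (!is.na(object@fitness))
    cat(sprintf("  fitness %.4f (best group %d)\n", object@fitness,
                object@bestGroup))
})

#' @rdname GGAResult-class
#' @export
setMethod("selectedFeatures", "GGAResult", function(x) x@selectedFeatures)

#' @rdname GGAResult-class
#' @export
setMethod("fitnessHistory", "GGAResult", function(x) x@history)

#' @rdname GGAResult-class
#' @export
setMethod("fitness", "GGAResult", function(x) x@bestSolution@fitness)

setMethod("show", "GGAResult", function(object) {
  cat(sprintf(
    "GGAResult: %d generations (%s), best fitness %.4f, %d features, %d ELM fits\n",
    object@generationsRun, object@stopReason, fitness(object),
    length(object@selectedFeatures), object@elmFits))
})
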