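#' @import methods
#' @importFrom stats fft rnorm runif sd cor predict approx nextn aggregate
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<- colData rowData
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom utils head read.csv write.csv
NULL

#' AcousticRecording: a mono audio recording
#'
#' Holds a sampled pressure signal \eqn{x_n = x(n \Delta t)} together with its
#' sampling rate. Duration is derived as \code{nSamples / sampleRate}.
#'
#' @slot samples numeric vector of amplitudes.
#' @slot sampleRate sampling rate in Hz.
#' @export
setClass("AcousticRecording",
  representation(samples = "numeric", sampleRate = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@sampleRate) != 1L || !is.finite(object@sampleRate) ||
        object@sampleRate <= 0)
      msg <- c(msg, "sampleRate must be a single positive number")
    if (anyNA(object@samples))
      msg <- c(msg, "samples must not contain NA")
    if (is.null(msg)) TRUE else msg
  })

#' Construct an AcousticRecording
#'
#' @param samples numeric vector of amplitudes.
#' @param sampleRate sampling rate in Hz.
#' @return An \linkS4class{AcousticRecording}.
#' @examples
#' rec <- AcousticRecording(sin(2 * pi * 440 * (0:999) / 8000), 8000)
#' durationSec(rec)
#' @export
AcousticRecording <- function(samples, sampleRate) {
  new("AcousticRecording", samples = as.numeric(samples),
      sampleRate = as.numeric(sampleRate))
}

#' PowerSpectrum: power spectral density on a frequency grid
#'
#' Values are stored in dB/Hz. \code{gridKind} distinguishes the raw
#' one-sided FFT grid from the decimated linear grid used for feature
#' vectors.
#'
#' @slot freq frequency grid in Hz, strictly increasing.
#' @slot power power spectral density in dB/Hz.
#' @slot gridKind either \code{"fft"} or \code{"decimated"}.
#' @export
setClass("PowerSpectrum",
  representation(freq = "numeric", power = "numeric", gridKind = "character"),
  validity = function(object) {
    msg <- NULL
    if (length(object@freq) != length(object@power))
      msg <- c(msg, "freq and power must have the same length")
    if (length(object@freq) > 1L && any(diff(object@freq) <= 0))
      msg <- c(msg, "freq must be strictly increasing")
    if (!object@gridKind %in% c("fft", "decimated"))
      msg <- c(msg, "gridKind must be 'fft' or 'decimated'")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a PowerSpectrum
#'
#' @param freq frequency grid in Hz.
#' @param power PSD values in dB/Hz.
#' @param gridKind \code{"fft"} (raw one-sided FFT grid) or
#'   \code{"decimated"}.
#' @return A \linkS4class{PowerSpectrum}.
#' @export
PowerSpectrum <- function(freq, power, gridKind = "fft") {
  new("PowerSpectrum", freq = as.numeric(freq), power = as.numeric(power),
      gridKind = gridKind)
}

#' SpectralExperiment: labeled spectral feature dataset
#'
#' A \linkS4class{SummarizedExperiment} subclass in which rows are spectral
#' features (frequency bins, \code{rowData()$freqHz}) and columns are
#' measurements. \code{colData()$label} carries the integer class label of
#' each measurement; the optional \code{colData()$partition} marks
#' membership in the train/test/validation split.
#'
#' @export
setClass("SpectralExperiment",
  contains = "SummarizedExperiment",
  validity = function(object) {
    msg <- NULL
    cd <- SummarizedExperiment::colData(object)
    if (!"label" %in% colnames(cd))
      msg <- c(msg, "colData must contain a 'label' column")
    else if (anyNA(cd$label))
      msg <- c(msg, "labels must not contain NA")
    if ("partition" %in% colnames(cd)) {
      ok <- cd$partition %in% c("train", "test", "validation") |
        is.na(cd$partition)
      if (!all(ok))
        msg <- c(msg, "partition values must be train/test/validation or NA")
    }
    rd <- SummarizedExperiment::rowData(object)
    if ("freqHz" %in% colnames(rd) && is.unsorted(rd$freqHz, strictly = TRUE))
      msg <- c(msg, "rowData$freqHz must be strictly increasing")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a SpectralExperiment
#'
#' @param features numeric matrix, measurements in rows and spectral
#'   features in columns (the natural orientation for classifiers); it is
#'   transposed into the assay so that container rows are features.
#' @param labels integer class labels, one per measurement.
#' @param freqHz optional frequency (Hz) of each feature.
#' @param partition optional character vector of
#'   \code{"train"}/\code{"test"}/\code{"validation"} per measurement.
#' @param metadata optional list stored as container metadata.
#' @return A \linkS4class{SpectralExperiment}.
#' @examples
#' x <- matrix(rnorm(40), nrow = 8)
#' se <- SpectralExperiment(x, labels = rep(2:3, each = 4))
#' dim(se)          # 5 features x 8 measurements
#' classLabels(se)
#' @export
SpectralExperiment <- function(features, labels, freqHz = NULL,
                               partition = NULL, metadata = list()) {
  features <- as.matrix(features)
  dimnames(features) <- NULL
  if (nrow(features) != length(labels))
    stop("number of feature rows must equal number of labels")
  cd <- S4Vectors::DataFrame(label = as.integer(labels))
  if (!is.null(partition)) cd$partition <- as.character(partition)
  rd <- S4Vectors::DataFrame(row.names = seq_len(ncol(features)))
  if (!is.null(freqHz)) {
    stopifnot(length(freqHz) == ncol(features))
    rd$freqHz <- as.numeric(freqHz)
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = t(features)), colData = cd, rowData = rd,
    metadata = metadata)
  new("SpectralExperiment", se)
}

#' ELMModel: an Extreme Learning Machine classifier
#'
#' Single-hidden-layer feedforward network with L hidden nodes whose input
#' weights \code{a} and biases \code{b} are random and fixed; only the
#' output weights \code{beta} are learned, as the minimum-norm
#' least-squares solution of \eqn{H \beta = Y} via the Moore-Penrose
#' pseudoinverse.
#'
#' @slot L hidden-node count.
#' @slot a L x d matrix of hidden-layer input weights.
#' @slot b length-L bias vector.
#' @slot activation activation name (\code{"sigmoid"}).
#' @slot beta L x m output weight matrix; 0 x 0 until fitted.
#' @slot classes ordered integer label set defining the one-hot columns.
#' @export
setClass("ELMModel",
  representation(L = "integer", a = "matrix", b = "numeric",
                 activation = "character", beta = "matrix",
                 classes = "integer"),
  validity = function(object) {
    msg <- NULL
    if (object@L < 1L) msg <- c(msg, "L must be >= 1")
    if (nrow(object@a) != object@L || length(object@b) != object@L)
      msg <- c(msg, "a must be L x d and b length L")
    if (!object@activation %in% "sigmoid")
      msg <- c(msg, "unsupported activation")
    if (is.null(msg)) TRUE else msg
  })

#' GroupingSolution: two-part grouping chromosome
#'
#' The chromosome of the grouping genetic algorithm: an assignment array
#' over the E features (0 = unassigned, otherwise a group id) and a
#' strictly ascending grouping array listing the distinct group ids in
#' use. Fitness and the id of the group achieving it are attached after
#' evaluation.
#'
#' @slot assignment integer vector of length E.
#' @slot grouping strictly ascending integer vector of group ids.
#' @slot fitness classification rate in [0,1]; NA before evaluation.
#' @slot bestGroup group id achieving the fitness; NA before evaluation.
#' @export
setClass("GroupingSolution",
  representation(assignment = "integer", grouping = "integer",
                 fitness = "numeric", bestGroup = "integer"),
  validity = function(object) {
    msg <- NULL
    g <- object@grouping
    if (length(g) > 1L && any(diff(g) <= 0))
      msg <- c(msg, "grouping must be strictly ascending")
    if (any(g <= 0L)) msg <- c(msg, "group ids must be positive")
    used <- unique(object@assignment[object@assignment != 0L])
    if (!all(used %in% g))
      msg <- c(msg, "every nonzero assignment value must appear in grouping")
    if (!all(g %in% used))
      msg <- c(msg, "every group id must have at least one assigned element")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a GroupingSolution
#'
#' @param assignment integer assignment array (0 = unassigned).
#' @param grouping strictly ascending distinct group ids; derived from
#'   \code{assignment} when omitted.
#' @param fitness,bestGroup optional evaluation results.
#' @return A \linkS4class{GroupingSolution}.
#' @export
GroupingSolution <- function(assignment, grouping = NULL,
                             fitness = NA_real_, bestGroup = NA_integer_) {
  assignment <- as.integer(assignment)
  if (is.null(grouping))
    grouping <- sort(unique(assignment[assignment != 0L]))
  new("GroupingSolution", assignment = assignment,
      grouping = as.integer(grouping), fitness = as.numeric(fitness),
      bestGroup = as.integer(bestGroup))
}

#' GGAResult: outcome of a grouping-GA feature-selection run
#'
#' @slot bestSolution the best-ever \linkS4class{GroupingSolution}.
#' @slot selectedFeatures sorted feature indices of its best group.
#' @slot history per-generation data.frame with columns
#'   \code{generation}, \code{bestEver}, \code{bestInPop}, \code{meanFitness}.
#' @slot generationsRun number of generations executed.
#' @slot stopReason \code{"converged"} or \code{"g_max"}.
#' @slot elmFits total number of ELM fits performed.
#' @export
setClass("GGAResult",
  representation(bestSolution = "GroupingSolution",
                 selectedFeatures = "integer", history = "data.frame",
                 generationsRun = "integer", stopReason = "character",
                 elmFits = "integer"),
  validity = function(object) {
    msg <- NULL
    if (length(object@selectedFeatures) == 0L)
      msg <- c(msg, "selectedFeatures must be non-empty")
    if (is.unsorted(object@history$bestEver))
      msg <- c(msg, "best-ever fitness must be non-decreasing")
    if (!object@stopReason %in% c("converged", "g_max"))
      msg <- c(msg, "stopReason must be 'converged' or 'g_max'")
    if (is.null(msg)) TRUE else msg
  })
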