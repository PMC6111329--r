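#' Specification of a synthetic spectral dataset
#'
#' Describes a planted-truth feature dataset emulating the structure of
#' acoustic-resonance spectra of liquid mixtures: a shared baseline
#' spectrum, class-specific offsets of controlled magnitude at a small
#' set of informative frequencies, and independent Gaussian measurement
#' noise whose standard deviation is a fraction of the signal range
#' (defaults: 23 classes x 24 replicates x 1310 features, 5% relative
#' noise).
#'
#' @param nClasses number of mixture classes (>= 2).
#' @param nReps replicate measurements per class.
#' @param nFeatures spectral features per measurement.
#' @param informativeIndices distinct feature indices carrying class
#'   signal; default 36 indices spread evenly across the grid.
#' @param effectSize dimensionless separation between class means at the
#'   informative indices, as a fraction of the baseline signal range.
#'   The default 0.35 keeps class offsets within +-17.5% of the spectral
#'   dynamic range -- several times the 5% within-class noise, so that
#'   spectra of different classes remain visually similar and no single
#'   frequency separates all classes, yet a group of informative
#'   frequencies classifies reliably.
#' @param noiseSd within-class standard deviation relative to the signal
#'   range.
#' @param seed RNG seed freezing baseline, offsets and noise.
#' @return A validated list of class \code{"syntheticSpec"}.
#' @examples
#' sp <- syntheticSpec(nClasses = 4, nReps = 6, nFeatures = 50,
#'                     informativeIndices = c(5, 17, 33))
#' se <- simulateFeatureDataset(sp)
#' dim(se)
#' @export
syntheticSpec <- function(nClasses = 23, nReps = 24, nFeatures = 1310,
                          informativeIndices = NULL, effectSize = 0.35,
                          noiseSd = 0.05, seed = 1) {
  if (is.null(informativeIndices))
    informativeIndices <- unique(round(seq(20, nFeatures - 19,
                                           length.out = 36)))
  informativeIndices <- as.integer(informativeIndices)
  if (nClasses < 2) stop("nClasses must be >= 2")
  if (nReps < 1 || nFeatures < 1) stop("nReps and nFeatures must be >= 1")
  if (anyDuplicated(informativeIndices) ||
      any(informativeIndices < 1 | informativeIndices > nFeatures))
    stop("informativeIndices must be distinct indices within 1..nFeatures")
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  structure(list(nClasses = as.integer(nClasses), nReps = as.integer(nReps),
                 nFeatures = as.integer(nFeatures),
                 informativeIndices = informativeIndices,
                 effectSize = effectSize, noiseSd = noiseSd,
                 seed = as.integer(seed)),
            class = "syntheticSpec")
}

# shared baseline: 1/f-like decay with a few common resonance bumps, in dB
syntheticBaseline <- function(freq) {
  bumpsAt <- c(300, 800, 1500, 3000, 7000, 12000)
  height <- c(14, 10, 12, 8, 9, 6)
  width <- c(60, 120, 200, 350, 600, 900)
  base <- 40 - 25 * log10(freq / 20)
  for (k in seq_along(bumpsAt))
    base <- base + height[k] * exp(-0.5 * ((freq - bumpsAt[k]) / width[k])^2)
  base
}

#' Generate a planted-truth spectral feature dataset
#'
#' Builds a labeled feature matrix in which every class shares a common
#' baseline spectrum (smooth 1/f-like decay plus shared resonance bumps)
#' and differs only by frozen class-specific offsets at the informative
#' indices, plus i.i.d. Gaussian noise scaled to the baseline range.
#' Labels run 2..(nClasses+1), matching the numbering convention in which
#' label 1 would be the pure-solvent sample. The planted truth
#' (informative indices and the class-offset matrix) is stored in the
#' container metadata so recovery can be scored.
#'
#' @param spec a \code{\link{syntheticSpec}}.
#' @return A \linkS4class{SpectralExperiment} with
#'   \code{metadata()$informativeIndices}, \code{$classOffsets} (nClasses
#'   x n informative), \code{$signalRange} and \code{$spec}.
#' @export
simulateFeatureDataset <- function(spec) {
  stopifnot(inherits(spec, "syntheticSpec"))
  if (spec$effectSize <= 0)
    stop("effectSize must be > 0; a non-positive effect gives a degenerate dataset")
  set.seed(spec$seed)
  edges <- seq(20, 22050, length.out = spec$nFeatures + 1L)
  freq <- (edges[-1L] + edges[-length(edges)]) / 2
  base <- syntheticBaseline(freq)
  sRange <- diff(range(base))
  nInf <- length(spec$informativeIndices)
  # frozen per-class offsets at informative indices, +- effectSize/2 range
  offsets <- matrix(runif(spec$nClasses * nInf, -0.5, 0.5) * spec$effectSize *
                      sRange, nrow = spec$nClasses)
  n <- spec$nClasses * spec$nReps
  X <- matrix(rep(base, each = n), nrow = n)
  cls <- rep(seq_len(spec$nClasses), each = spec$nReps)
  X[, spec$informativeIndices] <- X[, spec$informativeIndices] +
    offsets[cls, , drop = FALSE]
  if (spec$noiseSd > 0)
    X <- X + matrix(rnorm(n * spec$nFeatures, 0, spec$noiseSd * sRange),
                    nrow = n)
  SpectralExperiment(
    X, labels = cls + 1L, freqHz = freq,
    metadata = list(informativeIndices = spec$informativeIndices,
                    classOffsets = offsets, signalRange = sRange,
                    spec = spec))
}

#' Synthesize a ticking-excited resonance recording
#'
#' Emulates a mechanical clock exciting a resonant cavity: a periodic
#' impulse train at \code{tickRate} is convolved with the cavity impulse
#' response, a sum of exponentially decaying sinusoids (the resonance
#' modes), and low-level white noise is added.
#'
#' @param modes matrix or data.frame with columns \code{freq} (Hz, must
#'   be below fs/2), \code{damping} (1/s) and \code{amplitude}; may have
#'   zero rows.
#' @param durationS duration in seconds (>= 6).
#' @param fs sampling rate in Hz.
#' @param tickRate impulses per second.
#' @param noiseSd standard deviation of the additive white noise.
#' @param seed RNG seed for the noise.
#' @return An \linkS4class{AcousticRecording} of exactly
#'   \code{round(durationS * fs)} samples.
#' @export
simulateRecording <- function(modes, durationS = 30, fs = 44100,
                              tickRate = 2, noiseSd = 1e-4, seed = 1) {
  modes <- as.data.frame(modes)
  if (nrow(modes) > 0) {
    stopifnot(all(c("freq", "damping", "amplitude") %in% names(modes)))
    if (any(modes$freq >= fs / 2))
      stop("mode frequency at or above the Nyquist rate fs/2 would alias")
    if (any(modes$damping <= 0)) stop("damping must be positive")
  }
  if (durationS < 6) stop("durationS must be >= 6 s")
  set.seed(seed)
  N <- round(durationS * fs)
  x <- numeric(N)
  if (nrow(modes) > 0) {
    # impulse response long enough for the slowest mode to decay to ~3e-4
    hLen <- min(N, ceiling(8 / min(modes$damping) * fs))
    t <- (seq_len(hLen) - 1L) / fs
    h <- numeric(hLen)
    for (k in seq_len(nrow(modes)))
      h <- h + modes$amplitude[k] * exp(-modes$damping[k] * t) *
        sin(2 * pi * modes$freq[k] * t)
    ticks <- numeric(N)
    ticks[seq(1L, N, by = max(1L, round(fs / tickRate)))] <- 1
    x <- fftConvolve(ticks, h)[seq_len(N)]
  }
  if (noiseSd > 0) x <- x + rnorm(N, 0, noiseSd)
  AcousticRecording(x, fs)
}

# linear ("open") convolution via zero-padded FFTs
fftConvolve <- function(a, b) {
  n <- length(a) + length(b) - 1L
  nf <- stats::nextn(n, c(2, 3, 5))
  Re(fft(fft(c(a, numeric(nf - length(a)))) *
           fft(c(b, numeric(nf - length(b)))), inverse = TRUE))[seq_len(n)] / nf
}
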