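#' One-sided periodogram power spectral density
#'
#' Estimates the PSD of a window as
#' \deqn{\tilde S_{xx}(\omega) = \frac{(\Delta t)^2}{T}
#'   \left| \sum_{n=1}^{N} x_n e^{-i \omega n \Delta t} \right|^2}
#' over the real-FFT frequency grid, folded to one side so that
#' \eqn{\sum \tilde S_{xx} \Delta f} equals the mean squared amplitude
#' (Parseval). Values are returned in dB/Hz with a floor for zero power.
#'
#' @param window an \linkS4class{AcousticRecording} with >= 2 samples.
#' @param taper \code{"none"} (default, plain periodogram) or
#'   \code{"hann"}.
#' @param floorDb dB floor substituted for zero-power bins.
#' @return A \linkS4class{PowerSpectrum} on the raw FFT grid.
#' @export
powerSpectrum <- function(window, taper = c("none", "hann"),
                          floorDb = DB_FLOOR) {
  stopifnot(is(window, "AcousticRecording"))
  taper <- match.arg(taper)
  x <- samples(window)
  N <- length(x)
  if (N < 2) stop("window must contain at least 2 samples")
  fs <- sampleRate(window)
  if (taper == "hann") {
    w <- 0.5 - 0.5 * cos(2 * pi * seq_len(N) / (N + 1))
    x <- x * w / sqrt(mean(w^2))  # preserve power
  }
  X <- fft(x)
  # two-sided PSD: dt^2/T |X|^2 = |X|^2 / (N fs)
  S2 <- Mod(X)^2 / (N * fs)
  half <- floor(N / 2) + 1L
  S1 <- S2[seq_len(half)]
  # double interior bins (not DC; not Nyquist when N even)
  last_interior <- if (N %% 2 == 0) half - 1L else half
  if (last_interior >= 2L)
    S1[2:last_interior] <- 2 * S1[2:last_interior]
  freq <- (seq_len(half) - 1L) * fs / N
  PowerSpectrum(freq, powerToDb(S1, floorDb), gridKind = "fft")
}

#' Cepstral smoothing of a power spectrum
#'
#' The log-spectrum (dB values) is carried to the cepstral domain by an
#' inverse Fourier transform; quefrency components above the cutoff
#' \eqn{q_c = 1 / \mathrm{bandwidthHz}} are removed by a lifter and the
#' result transformed back, producing a smooth spectral envelope. Spectral
#' ripple with period finer than the bandwidth lives above the cutoff and
#' is suppressed; the zero-quefrency (constant) component always passes.
#' When the cutoff reaches beyond the maximum representable quefrency
#' \eqn{1/(2\Delta f)} the lifter is the identity and the input is
#' returned unchanged.
#'
#' @param spec a \linkS4class{PowerSpectrum} on the raw (uniform) FFT grid.
#' @param bandwidthHz smoothing bandwidth in Hz; spectral detail finer
#'   than this is removed.
#' @param lifter \code{"cosine"} (raised-cosine rolloff ending at the
#'   cutoff quefrency) or \code{"rect"} (hard cutoff).
#' @return A \linkS4class{PowerSpectrum} on the same grid.
#' @export
cepstralSmooth <- function(spec, bandwidthHz = 100,
                           lifter = c("cosine", "rect")) {
  stopifnot(is(spec, "PowerSpectrum"), bandwidthHz > 0)
  lifter <- match.arg(lifter)
  f <- freqHz(spec)
  M <- length(f)
  if (M < 3) stop("spectrum too short for cepstral smoothing")
  df <- diff(f)
  if (max(abs(df - df[1])) > 1e-6 * df[1])
    stop("cepstral smoothing requires a uniform frequency grid")
  df <- df[1]
  qmax <- 1 / (2 * df)
  qc <- 1 / bandwidthHz
  if (qc >= qmax) return(spec)

  # even extension -> real cepstrum via FFT
  L <- powerDb(spec)
  v <- c(L, rev(L[2:(M - 1L)]))
  n2 <- length(v)                       # 2(M-1)
  q <- c(0:(M - 1L), (M - 2L):1) / (n2 * df)  # quefrency of each FFT bin
  w <- if (lifter == "rect") {
    as.numeric(q < qc)
  } else {
    ifelse(q <= qc / 2, 1,
           ifelse(q < qc, 0.5 * (1 + cos(pi * (q - qc / 2) / (qc / 2))), 0))
  }
  ceps <- fft(v)
  sm <- Re(fft(w * ceps, inverse = TRUE)) / n2
  PowerSpectrum(f, sm[seq_len(M)], gridKind = "fft")
}

#' Decimate a spectrum onto a fixed linear frequency grid
#'
#' Block-averages PSD values onto \code{nPoints} contiguous equal-width
#' bins spanning [\code{fLo}, \code{fHi}], reducing the raw FFT grid to a
#' fixed-length feature vector while preserving the main peak structure.
#' With the defaults (1310 points over 20 Hz-22.05 kHz) the bin width is
#' about 16.8 Hz.
#'
#' @param spec a \linkS4class{PowerSpectrum} covering [fLo, fHi].
#' @param nPoints number of output bins.
#' @param fLo,fHi band edges in Hz.
#' @return A \linkS4class{PowerSpectrum} with \code{gridKind
#'   "decimated"}, frequencies at the bin centers.
#' @export
decimateToGrid <- function(spec, nPoints = 1310, fLo = 20, fHi = 22050) {
  stopifnot(is(spec, "PowerSpectrum"), nPoints >= 1, fHi > fLo)
  f <- freqHz(spec)
  if (min(f) > fLo || max(f) < fHi)
    stop(sprintf("spectrum band [%g, %g] does not cover [%g, %g] Hz",
                 min(f), max(f), fLo, fHi))
  edges <- seq(fLo, fHi, length.out = nPoints + 1L)
  centers <- (edges[-1L] + edges[-(nPoints + 1L)]) / 2
  inband <- f >= fLo & f <= fHi
  idx <- findInterval(f[inband], edges, rightmost.closed = TRUE)
  p <- powerDb(spec)[inband]
  vals <- as.numeric(tapply(p, factor(idx, levels = seq_len(nPoints)), mean))
  if (anyNA(vals)) {
    # grids coarser than the bin width: fill empty bins by interpolation
    empty <- which(is.na(vals))
    vals[empty] <- approx(f, powerDb(spec), xout = centers[empty])$y
  }
  PowerSpectrum(centers, vals, gridKind = "decimated")
}

#' Min-max normalization fitted on training data
#'
#' Fits a single affine map on the global minimum and maximum of the
#' training matrix so training values span [-1, 1], then applies the same
#' map to any further matrices. Values outside the fitted range are not
#' clipped. A global (matrix-wide) map is used rather than per-feature
#' scaling so that magnitudes remain comparable across frequencies.
#'
#' @param train numeric training matrix (fits the map).
#' @param ... further matrices to transform with the fitted map.
#' @return If no extra matrices are given, the scaled training matrix
#'   (with attribute \code{"range"} = fitted c(min, max)); otherwise a
#'   list with the scaled \code{train} followed by each scaled extra
#'   matrix, carrying the same attribute.
#' @export
normalizeFeatures <- function(train, ...) {
  train <- as.matrix(train)
  if (length(train) == 0) stop("training matrix is empty")
  mn <- min(train); mx <- max(train)
  if (mx == mn) stop("training matrix is constant; min-max range is zero")
  f <- function(m) 2 * (as.matrix(m) - mn) / (mx - mn) - 1
  others <- list(...)
  if (length(others) == 0) {
    out <- f(train)
    attr(out, "range") <- c(mn, mx)
    return(out)
  }
  out <- c(list(train = f(train)), lapply(others, f))
  attr(out, "range") <- c(mn, mx)
  out
}

#' Preprocess one recording into feature vectors
#'
#' Runs the full per-recording chain: segmentation into overlapping
#' windows, periodogram PSD, cepstral smoothing and decimation onto the
#' fixed linear grid. Normalization is a dataset-level step applied after
#' the train/test/validation split (see \code{\link{normalizeSpectra}}).
#'
#' @param rec an \linkS4class{AcousticRecording} (>= windowS seconds).
#' @param windowS,hopS,maxWindows segmentation parameters.
#' @param smoothHz cepstral smoothing bandwidth in Hz.
#' @param nPoints,fLo,fHi decimation grid parameters.
#' @param taper periodogram taper, see \code{\link{powerSpectrum}}.
#' @return A numeric matrix (windows x nPoints) with attribute
#'   \code{"freqHz"} holding the shared bin-center grid.
#' @export
preprocessRecording <- function(rec, windowS = 6, hopS = 1, maxWindows = 24,
                                smoothHz = 100, nPoints = 1310, fLo = 20,
                                fHi = 22050, taper = "none") {
  wins <- segmentRecording(rec, windowS, hopS, maxWindows)
  rows <- lapply(wins, function(w) {
    sp <- decimateToGrid(cepstralSmooth(powerSpectrum(w, taper = taper),
                                        bandwidthHz = smoothHz),
                         nPoints = nPoints, fLo = fLo, fHi = fHi)
    sp
  })
  out <- do.call(rbind, lapply(rows, powerDb))
  attr(out, "freqHz") <- freqHz(rows[[1L]])
  out
}

#' Preprocess a set of labeled recordings into a SpectralExperiment
#'
#' @param recs list of \linkS4class{AcousticRecording} objects, one per
#'   physical sample.
#' @param labels integer class label per recording; each recording's
#'   windows inherit its label.
#' @param ... passed to \code{\link{preprocessRecording}}.
#' @return A \linkS4class{SpectralExperiment} with one column per window.
#' @export
preprocessRecordings <- function(recs, labels, ...) {
  stopifnot(length(recs) == length(labels))
  mats <- lapply(recs, preprocessRecording, ...)
  nwin <- vapply(mats, nrow, integer(1))
  SpectralExperiment(do.call(rbind, mats),
                     labels = rep(as.integer(labels), nwin),
                     freqHz = attr(mats[[1L]], "freqHz"))
}

#' Normalize a partitioned SpectralExperiment
#'
#' Fits the global min-max map of \code{\link{normalizeFeatures}} on the
#' training partition only and applies it to the whole assay.
#'
#' @param se a \linkS4class{SpectralExperiment} whose \code{partition}
#'   column marks a training set.
#' @return The normalized \linkS4class{SpectralExperiment}; the fitted
#'   range is recorded in \code{metadata(se)$normRange}.
#' @export
normalizeSpectra <- function(se) {
  part <- dataPartition(se)
  if (!any(part == "train", na.rm = TRUE))
    stop("no training partition; call splitData()/dataPartition<- first")
  X <- featureMatrix(se)
  tr <- X[which(part == "train"), , drop = FALSE]
  mn <- min(tr); mx <- max(tr)
  if (mx == mn) stop("training partition is constant; min-max range is zero")
  SummarizedExperiment::assay(se, "intensity") <-
    2 * (SummarizedExperiment::assay(se, "intensity") - mn) / (mx - mn) - 1
  S4Vectors::metadata(se)$normRange <- c(mn, mx)
  se
}
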