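#' Read a WAV file into an AcousticRecording
#'
#' Supports RIFF/WAVE files holding 16- or 24-bit integer PCM or 32-bit
#' float samples, mono or stereo. Stereo is downmixed by averaging the
#' two channels; integer samples are rescaled to [-1, 1). The sampling
#' rate is taken from the file header.
#'
#' @param path path to a WAV file.
#' @return An \linkS4class{AcousticRecording}.
#' @seealso \code{\link{writeRecording}}, \code{\link{segmentRecording}}
#' @export
readRecording <- function(path) {
  if (!file.exists(path) || file.size(path) == 0)
    stop("cannot read WAV file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF"))
    stop("not a RIFF/WAVE file: ", path)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE"))
    stop("not a RIFF/WAVE file: ", path)

  fmt <- NULL; raw_data <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", sz)
      fmt <- list(
        audioFormat = readBin(body[1:2], "integer", 1, 2, signed = FALSE,
                              endian = "little"),
        channels = readBin(body[3:4], "integer", 1, 2, signed = FALSE,
                           endian = "little"),
        sampleRate = readBin(body[5:8], "integer", 1, 4, endian = "little"),
        bits = readBin(body[15:16], "integer", 1, 2, signed = FALSE,
                       endian = "little"))
    } else if (identical(id, "data")) {
      raw_data <- readBin(con, "raw", sz)
    } else {
      invisible(readBin(con, "raw", sz))
    }
    if (sz %% 2 == 1) invisible(readBin(con, "raw", 1))  # chunk padding
    if (!is.null(fmt) && !is.null(raw_data)) break
  }
  if (is.null(fmt) || is.null(raw_data) || length(raw_data) == 0)
    stop("WAV file has no usable fmt/data chunks: ", path)

  x <- if (fmt$audioFormat == 1 && fmt$bits == 16) {
    readBin(raw_data, "integer", length(raw_data) / 2, size = 2,
            signed = TRUE, endian = "little") / 32768
  } else if (fmt$audioFormat == 1 && fmt$bits == 24) {
    n <- length(raw_data) / 3
    b <- matrix(as.integer(raw_data), nrow = 3)
    v <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ]
    v <- ifelse(v >= 8388608, v - 16777216, v)
    v / 8388608
  } else if (fmt$audioFormat == 3 && fmt$bits == 32) {
    readBin(raw_data, "double", length(raw_data) / 4, size = 4,
            endian = "little")
  } else {
    stop("unsupported WAV encoding (format ", fmt$audioFormat, ", ",
         fmt$bits, " bit)")
  }
  if (fmt$channels == 2) {
    x <- (x[seq(1, length(x), 2)] + x[seq(2, length(x), 2)]) / 2
  } else if (fmt$channels != 1) {
    stop("unsupported channel count: ", fmt$channels)
  }
  if (length(x) == 0) stop("WAV file contains no samples: ", path)
  AcousticRecording(x, fmt$sampleRate)
}

#' Write an AcousticRecording to a 16-bit PCM mono WAV file
#'
#' Samples are clipped to [-1, 1] and quantized to 16-bit integers.
#'
#' @param rec an \linkS4class{AcousticRecording}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeRecording <- function(rec, path) {
  stopifnot(is(rec, "AcousticRecording"))
  x <- pmin(pmax(samples(rec), -1), 1)
  pcm <- as.integer(round(x * 32767))
  fs <- as.integer(round(sampleRate(rec)))
  dataSize <- 2L * length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + dataSize), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")      # PCM
  writeBin(1L, con, size = 2, endian = "little")      # mono
  writeBin(fs, con, size = 4, endian = "little")
  writeBin(fs * 2L, con, size = 4, endian = "little") # byte rate
  writeBin(2L, con, size = 2, endian = "little")      # block align
  writeBin(16L, con, size = 2, endian = "little")     # bits
  writeChar("data", con, eos = NULL)
  writeBin(dataSize, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Segment a recording into overlapping analysis windows
#'
#' Cuts windows of \code{windowS} seconds starting at t = 0, spaced
#' \code{hopS} seconds apart, keeping at most \code{maxWindows}. With the
#' defaults a 30-s recording yields exactly 24 windows of 6 s
#' ([0-6], [1-7], ..., [23-29]), so 23 samples x 24 windows give the 552
#' measurements the classifier consumes.
#'
#' @param rec an \linkS4class{AcousticRecording} of duration >= windowS.
#' @param windowS window length in seconds.
#' @param hopS hop between window starts in seconds.
#' @param maxWindows cap on the number of windows returned.
#' @return A list of \linkS4class{AcousticRecording} windows, each of
#'   exactly \code{round(windowS * sampleRate)} samples.
#' @export
segmentRecording <- function(rec, windowS = 6, hopS = 1, maxWindows = 24) {
  stopifnot(is(rec, "AcousticRecording"), windowS > 0, hopS > 0)
  fs <- sampleRate(rec)
  wlen <- round(windowS * fs)
  hop <- round(hopS * fs)
  n <- nSamples(rec)
  if (n < wlen)
    stop("recording shorter than one window (", n, " < ", wlen, " samples)")
  starts <- seq(1L, n - wlen + 1L, by = hop)
  if (length(starts) > maxWindows) starts <- starts[seq_len(maxWindows)]
  lapply(starts, function(s)
    AcousticRecording(rec@samples[s:(s + wlen - 1L)], fs))
}
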