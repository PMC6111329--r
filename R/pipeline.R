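#' Train/test/validation split
#'
#' Splits n measurements into disjoint, exhaustive train/test/validation
#' sets. Sizes follow the rounding rule \code{validation = ceiling(fv *
#' n)}, \code{test = round(ft * n)}, \code{train = remainder}, which
#' reproduces the reference bookkeeping: 552 measurements at 80/15/5
#' give a validation set of exactly 28, test 83, train 441. When labels
#' are available the split is stratified by class (largest-remainder
#' allocation per class) so every class appears in training.
#'
#' @param x either a single integer n, or a
#'   \linkS4class{SpectralExperiment} (split stratified by its labels and
#'   returned with the \code{partition} column filled).
#' @param fractions length-3 numeric c(train, test, validation), summing
#'   to 1.
#' @param stratified stratify by class label when labels are available.
#' @param labels optional labels when \code{x} is an integer.
#' @param seed optional RNG seed.
#' @return For integer \code{x}: a list with integer index vectors
#'   \code{$train}, \code{$test}, \code{$validation}. For a
#'   SpectralExperiment: the object with \code{dataPartition} set.
#' @examples
#' sz <- lengths(splitData(552, seed = 1))
#' sz  # train 441, test 83, validation 28
#' @export
splitData <- function(x, fractions = c(0.80, 0.15, 0.05), stratified = TRUE,
                      labels = NULL, seed = NULL) {
  if (is(x, "SpectralExperiment")) {
    idx <- splitData(ncol(x), fractions = fractions, stratified = stratified,
                     labels = classLabels(x), seed = seed)
    part <- rep(NA_character_, ncol(x))
    part[idx$train] <- "train"
    part[idx$test] <- "test"
    part[idx$validation] <- "validation"
    dataPartition(x) <- part
    return(x)
  }
  n <- as.integer(x)
  if (length(fractions) != 3 || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-9)
    stop("fractions must be three positive numbers summing to 1")
  if (!is.null(seed)) set.seed(seed)
  nVal <- as.integer(ceiling(fractions[3] * n))
  nTest <- as.integer(round(fractions[2] * n))
  nTrain <- n - nVal - nTest
  if (nTrain < 1) stop("split leaves no training data")

  if (!stratified || is.null(labels)) {
    perm <- sample.int(n)
    return(list(train = sort(perm[seq_len(nTrain)]),
                test = sort(perm[nTrain + seq_len(nTest)]),
                validation = sort(perm[nTrain + nTest + seq_len(nVal)])))
  }
  stopifnot(length(labels) == n)
  byClass <- split(seq_len(n), labels)
  byClass <- lapply(byClass, function(ix) ix[sample.int(length(ix))])
  take <- function(total, counts) {
    # largest-remainder allocation of `total` across classes
    quota <- total * counts / sum(counts)
    alloc <- pmin(floor(quota), counts)
    left <- total - sum(alloc)
    ord <- order(-(quota - floor(quota)), sample.int(length(counts)))
    while (left > 0) {
      placed <- FALSE
      for (i in ord) {
        if (left == 0) break
        if (counts[i] - alloc[i] > 0) {
          alloc[i] <- alloc[i] + 1L; left <- left - 1L; placed <- TRUE
        }
      }
      if (!placed) stop("cannot allocate split within class counts")
    }
    as.integer(alloc)
  }
  counts <- lengths(byClass)
  aVal <- take(nVal, counts)
  aTest <- take(nTest, counts - aVal)
  val <- test <- train <- integer(0)
  for (i in seq_along(byClass)) {
    ix <- byClass[[i]]
    nv <- aVal[i]; nt <- aTest[i]
    val <- c(val, ix[seq_len(nv)])
    test <- c(test, ix[nv + seq_len(nt)])
    if (nv + nt < length(ix)) train <- c(train, ix[(nv + nt + 1):length(ix)])
  }
  list(train = sort(train), test = sort(test), validation = sort(val))
}

#' Repeated-validation battery for a selected feature group
#'
#' Checks the stability of the selected frequencies by running
#' \code{nIter} random and independent iterations: each iteration draws
#' fresh ELM hidden weights, fits on the training partition restricted to
#' the selected features and evaluates accuracy and Rho-squared on the
#' validation partition. The data split is fixed; only the ELM weights
#' are redrawn.
#'
#' @param se a partitioned \linkS4class{SpectralExperiment}.
#' @param features integer indices of the selected feature group.
#' @param nIter number of iterations (reference battery: 60).
#' @param L ELM hidden-node count.
#' @param seed optional RNG seed.
#' @return A list with \code{meanAccuracy}, \code{meanRhoSquared} and
#'   \code{table}, a data.frame with one row per iteration.
#' @export
validateSelection <- function(se, features, nIter = 60, L = 23,
                              seed = NULL) {
  stopifnot(is(se, "SpectralExperiment"), length(features) >= 1)
  features <- as.integer(features)
  if (any(features < 1 | features > nrow(se)))
    stop("selected feature indices outside the dataset's feature range")
  if (!is.null(seed)) set.seed(seed)
  part <- dataPartition(se)
  trainIdx <- which(part == "train")
  valIdx <- which(part == "validation")
  if (length(trainIdx) == 0 || length(valIdx) == 0)
    stop("dataset must carry train and validation partitions")
  X <- featureMatrix(se)[, features, drop = FALSE]
  y <- classLabels(se)
  acc <- rho <- numeric(nIter)
  for (i in seq_len(nIter)) {
    m <- elmFit(elmInit(L = L, d = length(features)),
                X[trainIdx, , drop = FALSE], y[trainIdx])
    pred <- predict(m, X[valIdx, , drop = FALSE])
    acc[i] <- classificationAccuracy(pred, y[valIdx])
    rho[i] <- rhoSquared(pred, y[valIdx])
  }
  list(meanAccuracy = mean(acc), meanRhoSquared = mean(rho),
       table = data.frame(iteration = seq_len(nIter), accuracy = acc,
                          rhoSquared = rho))
}

#' Per-class spectral patterns at the selected frequencies
#'
#' Builds the class fingerprint table: for every class and selected
#' frequency, the mean and standard deviation of the energy density over
#' that class's replicate measurements. The relative SD is the SD divided
#' by the overall range of the feature matrix, and a class pattern is
#' flagged valid when its mean relative SD is at or below
#' \code{threshold} (default 5%).
#'
#' @param se a labeled \linkS4class{SpectralExperiment} with >= 2
#'   replicates per class.
#' @param features integer indices of the selected frequencies.
#' @param threshold mean relative SD above which a class pattern is
#'   flagged invalid.
#' @return A data.frame with one row per (class, frequency): columns
#'   \code{label}, \code{feature}, \code{freqHz} (NA when unknown),
#'   \code{meanDb}, \code{sdDb}, \code{relSd}; the per-class summary
#'   (label, meanRelSd, valid) is attached as attribute
#'   \code{"classSummary"}.
#' @export
classPatterns <- function(se, features, threshold = 0.05) {
  stopifnot(is(se, "SpectralExperiment"), length(features) >= 1)
  features <- as.integer(features)
  X <- featureMatrix(se)
  y <- classLabels(se)
  reps <- table(y)
  if (any(reps < 2))
    stop("every class needs >= 2 replicate measurements to form a pattern")
  rng <- diff(range(X))
  if (rng == 0) rng <- 1
  rd <- SummarizedExperiment::rowData(se)
  fHz <- if ("freqHz" %in% colnames(rd)) rd$freqHz[features]
         else rep(NA_real_, length(features))
  out <- do.call(rbind, lapply(sort(unique(y)), function(cl) {
    Xc <- X[y == cl, features, drop = FALSE]
    data.frame(label = cl, feature = features, freqHz = fHz,
               meanDb = colMeans(Xc), sdDb = apply(Xc, 2, sd))
  }))
  out$relSd <- out$sdDb / rng
  summ <- aggregate(relSd ~ label, out, mean)
  names(summ)[2] <- "meanRelSd"
  summ$valid <- summ$meanRelSd <= threshold
  rownames(out) <- NULL
  attr(out, "classSummary") <- summ
  out
}

#' Write / read a labeled feature dataset as CSV
#'
#' The on-disk format is one row per measurement: first column
#' \code{label} (integer), then columns \code{f_1 ... f_E} (and an
#' optional \code{partition} column). Frequency metadata, when present,
#' is stored in a \code{# freqHz:} comment line.
#'
#' @param se a \linkS4class{SpectralExperiment}.
#' @param path CSV path.
#' @return \code{path} invisibly; \code{readFeatureCSV} returns a
#'   \linkS4class{SpectralExperiment}.
#' @export
writeFeatureCSV <- function(se, path) {
  stopifnot(is(se, "SpectralExperiment"))
  X <- featureMatrix(se)
  colnames(X) <- paste0("f_", seq_len(ncol(X)))
  df <- data.frame(label = classLabels(se), X, check.names = FALSE)
  part <- dataPartition(se)
  if (!all(is.na(part))) df$partition <- part
  rd <- SummarizedExperiment::rowData(se)
  con <- file(path, "w")
  on.exit(close(con))
  if ("freqHz" %in% colnames(rd))
    writeLines(paste0("# freqHz: ", paste(rd$freqHz, collapse = ",")), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatureCSV
#' @export
readFeatureCSV <- function(path) {
  first <- readLines(path, n = 1L)
  freqHz <- NULL
  skip <- 0L
  if (startsWith(first, "# freqHz:")) {
    freqHz <- as.numeric(strsplit(sub("^# freqHz: *", "", first),
                                  ",")[[1]])
    skip <- 1L
  }
  df <- read.csv(path, skip = skip, check.names = FALSE,
                 comment.char = "")
  if (!"label" %in% names(df)) stop("CSV must have a 'label' column")
  part <- if ("partition" %in% names(df)) df$partition else NULL
  feat <- as.matrix(df[grepl("^f_", names(df))])
  SpectralExperiment(feat, labels = df$label, freqHz = freqHz,
                     partition = part)
}
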