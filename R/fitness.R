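#' Evaluate the wrapper fitness of a grouping solution
#'
#' For every group in the solution's grouping part, an ELM is
#' initialized with fresh random hidden weights, fitted on the training
#' partition restricted to that group's feature columns, and its
#' classification rate computed on the held-out test partition (or on the
#' training partition when \code{control$rateOn == "train"}). The best
#' rate becomes the individual's fitness and the winning group its best
#' group (ties toward the smaller id); the other groups' rates are
#' discarded.
#'
#' @param sol a \linkS4class{GroupingSolution}.
#' @param se a partitioned \linkS4class{SpectralExperiment} (train and
#'   test sets marked).
#' @param L hidden-node count of the fitness ELM.
#' @param control a \code{\link{ggaControl}} (only \code{rateOn} is
#'   used here).
#' @param weightSeed optional seed drawn for the hidden weights of this
#'   evaluation only (the surrounding RNG stream is preserved); by
#'   default weights come from the current stream, so the GGA redraws
#'   them at every evaluation.
#' @return The solution with \code{fitness} and \code{bestGroup} set.
#' @export
evaluateFitness <- function(sol, se, L = 23, control = ggaControl(),
                            weightSeed = NULL) {
  stopifnot(is(sol, "GroupingSolution"), is(se, "SpectralExperiment"))
  part <- dataPartition(se)
  trainIdx <- which(part == "train")
  rateIdx <- if (control$rateOn == "train") trainIdx
             else which(part == "test")
  if (length(trainIdx) == 0 || length(rateIdx) == 0)
    stop("dataset must carry train and test partitions")
  X <- featureMatrix(se)
  y <- classLabels(se)
  if (!is.null(weightSeed)) {
    hasSeed <- exists(".Random.seed", envir = globalenv())
    if (hasSeed) old <- get(".Random.seed", envir = globalenv())
    set.seed(weightSeed)
    on.exit(if (hasSeed) assign(".Random.seed", old, envir = globalenv()))
  }
  best <- -Inf
  bestId <- NA_integer_
  for (id in sol@grouping) {          # ascending: first strict max wins ties
    cols <- which(sol@assignment == id)
    if (length(cols) == 0) stop("group ", id, " has no features")
    m <- elmInit(L = L, d = length(cols))
    m <- elmFit(m, X[trainIdx, cols, drop = FALSE], y[trainIdx])
    rate <- classificationAccuracy(
      predict(m, X[rateIdx, cols, drop = FALSE]), y[rateIdx])
    if (rate > best) { best <- rate; bestId <- id }
  }
  sol@fitness <- best
  sol@bestGroup <- bestId
  sol
}

# binary tournament pick of one parent index
pickParent <- function(fit) {
  ij <- sample.int(length(fit), 2L)
  if (fit[ij[1]] >= fit[ij[2]]) ij[1] else ij[2]
}

#' Run the grouping genetic algorithm feature selection
#'
#' Wrapper feature selection: an initial population of random grouping
#' solutions is evaluated with \code{\link{evaluateFitness}}; each
#' generation creates \code{0.5 nInd} offspring by grouping crossover of
#' tournament-picked parents, mutates them with probability \code{pMut},
#' evaluates them, merges parents and offspring and applies a tournament
#' survival round. The loop stops at population convergence
#' (\code{\link{hasConverged}}) or after \code{gMax} generations. The
#' best-ever individual is tracked separately, since survival has no
#' elitism and the best individual can be lost to tournament chance.
#'
#' @param se a partitioned \linkS4class{SpectralExperiment}; every class
#'   must be present in the training partition.
#' @param control a \code{\link{ggaControl}}.
#' @param L hidden-node count of the fitness ELM.
#' @param seed optional seed for the whole run; identical (seed, data,
#'   control) triples reproduce identical results.
#' @return A \linkS4class{GGAResult}.
#' @examples
#' sp <- syntheticSpec(nClasses = 3, nReps = 8, nFeatures = 40,
#'                     informativeIndices = c(4, 9, 21), seed = 2)
#' se <- simulateFeatureDataset(sp)
#' se <- splitData(se, seed = 2)
#' se <- normalizeSpectra(se)
#' ctl <- ggaControl(nInd = 6, gMax = 3, kGroups = c(2, 3),
#'                   groupSize = c(3, 8), tournamentRounds = 4)
#' res <- runGGA(se, ctl, L = 4, seed = 2)
#' res
#' @export
runGGA <- function(se, control = ggaControl(), L = 23, seed = NULL) {
  stopifnot(is(se, "SpectralExperiment"))
  if (!is.null(seed)) set.seed(seed)
  part <- dataPartition(se)
  y <- classLabels(se)
  if (!all(unique(y) %in% y[which(part == "train")]))
    stop("every class must be present in the training partition")
  E <- nrow(se)
  wSeed <- if (control$fixedWeights) drawInt(1L, .Machine$integer.max - 1L)
           else NULL

  idCounter <- 0L
  pop <- vector("list", control$nInd)
  for (i in seq_len(control$nInd)) {
    pop[[i]] <- randomSolution(E, control, idBase = idCounter)
    idCounter <- max(pop[[i]]@grouping)
  }
  elmFits <- 0L
  evalSol <- function(s) {
    elmFits <<- elmFits + length(s@grouping)
    evaluateFitness(s, se, L = L, control = control, weightSeed = wSeed)
  }
  pop <- lapply(pop, evalSol)

  bestEver <- pop[[which.max(vapply(pop, fitness, numeric(1)))]]
  nOff <- max(1L, round(control$nInd / 2))
  hist <- data.frame(generation = integer(0), bestEver = numeric(0),
                     bestInPop = numeric(0), meanFitness = numeric(0))
  stopReason <- "g_max"
  g <- 0L
  while (g < control$gMax) {
    g <- g + 1L
    fit <- vapply(pop, fitness, numeric(1))
    offspring <- vector("list", nOff)
    for (k in seq_len(nOff)) {
      a <- pop[[pickParent(fit)]]
      b <- pop[[pickParent(fit)]]
      child <- crossoverSolutions(a, b)
      child <- mutateSolution(child, control, idBase = idCounter)
      if (length(child@grouping)) idCounter <- max(idCounter,
                                                   max(child@grouping))
      offspring[[k]] <- child
    }
    offspring <- lapply(offspring, evalSol)
    pop <- tournamentSurvival(c(pop, offspring), control)
    fit <- vapply(pop, fitness, numeric(1))
    if (max(fit) > fitness(bestEver)) bestEver <- pop[[which.max(fit)]]
    hist <- rbind(hist, data.frame(generation = g,
                                   bestEver = fitness(bestEver),
                                   bestInPop = max(fit),
                                   meanFitness = mean(fit)))
    if (hasConverged(pop, control$epsilon)) { stopReason <- "converged"; break }
  }
  selected <- sort(which(bestEver@assignment == bestEver@bestGroup))
  new("GGAResult", bestSolution = bestEver,
      selectedFeatures = as.integer(selected), history = hist,
      generationsRun = g, stopReason = stopReason,
      elmFits = elmFits)
}
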