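#' Control parameters for the grouping genetic algorithm
#'
#' Defaults follow the reference configuration: population of 50,
#' mutation probability 0.1, at most 100 generations, convergence
#' tolerance 0.001 on |best - average| fitness. Initial solutions carry
#' 2-8 groups of 20-60 features each, centering candidate groups near the
#' 40-50 feature target.
#'
#' @param nInd population size (>= 2).
#' @param pMut mutation probability in [0, 1].
#' @param gMax maximum number of generations.
#' @param epsilon convergence tolerance (> 0).
#' @param kGroups c(min, max) number of groups in a random solution.
#' @param groupSize c(min, max) features per initial group.
#' @param tournamentRounds fights per individual in the survival round.
#' @param rateOn partition on which the fitness classification rate is
#'   computed: \code{"test"} (held-out, default) or \code{"train"}.
#' @param fixedWeights if TRUE, ELM hidden weights are drawn once per
#'   run instead of per evaluation (debugging aid).
#' @return A validated list of class \code{"ggaControl"}.
#' @export
ggaControl <- function(nInd = 50, pMut = 0.1, gMax = 100, epsilon = 0.001,
                       kGroups = c(2, 8), groupSize = c(20, 60),
                       tournamentRounds = 10, rateOn = c("test", "train"),
                       fixedWeights = FALSE) {
  rateOn <- match.arg(rateOn)
  if (nInd < 2) stop("nInd must be >= 2")
  if (pMut < 0 || pMut > 1) stop("pMut must be in [0, 1]")
  if (epsilon <= 0) stop("epsilon must be > 0")
  if (gMax < 1) stop("gMax must be >= 1")
  stopifnot(length(kGroups) == 2, kGroups[1] >= 1, kGroups[2] >= kGroups[1],
            length(groupSize) == 2, groupSize[1] >= 1,
            groupSize[2] >= groupSize[1])
  structure(list(nInd = as.integer(nInd), pMut = pMut,
                 gMax = as.integer(gMax), epsilon = epsilon,
                 kGroups = as.integer(kGroups),
                 groupSize = as.integer(groupSize),
                 tournamentRounds = as.integer(tournamentRounds),
                 rateOn = rateOn, fixedWeights = fixedWeights),
            class = "ggaControl")
}

#' Create a random grouping solution
#'
#' Draws a group count uniformly in \code{kGroups}, then builds groups of
#' sizes uniform in \code{groupSize} over disjoint uniformly sampled
#' feature subsets; remaining features stay unassigned (0). Group
#' creation stops early if fewer unassigned features remain than the next
#' drawn size, so every created group respects the configured size range.
#' Fresh ids are drawn above \code{idBase} so new groups never collide
#' with ids already in use elsewhere.
#'
#' @param E number of features (chromosome length).
#' @param control a \code{\link{ggaControl}}.
#' @param idBase integer; new group ids start at \code{idBase + 1}.
#' @return A \linkS4class{GroupingSolution}. Consumes the global RNG
#'   stream; seed externally for reproducibility.
#' @export
randomSolution <- function(E, control = ggaControl(), idBase = 0L) {
  if (control$groupSize[2] > E)
    stop("requested group sizes exceed the number of features E")
  k <- drawInt(control$kGroups[1], control$kGroups[2])
  perm <- sample.int(E)
  assignment <- integer(E)
  used <- 0L
  made <- 0L
  for (g in seq_len(k)) {
    size <- drawInt(control$groupSize[1], control$groupSize[2])
    if (used + size > E) break
    assignment[perm[(used + 1L):(used + size)]] <- idBase + g
    used <- used + size
    made <- made + 1L
  }
  if (made == 0L)
    stop("could not place any group; E too small for groupSize")
  GroupingSolution(assignment,
                   grouping = idBase + seq_len(made))
}

#' Grouping crossover
#'
#' The offspring starts as a copy of parent A. A random contiguous
#' fragment of B's grouping part is selected; each fragment id not
#' already present in A is added, and every feature B assigns to that id
#' is reassigned to it in the offspring (overwriting A's assignment).
#' Groups of A emptied by the overwrite are pruned and the grouping part
#' is rewritten in ascending order.
#'
#' @param A,B \linkS4class{GroupingSolution}s over the same number of
#'   features.
#' @return The offspring \linkS4class{GroupingSolution} (fitness unset).
#' @export
crossoverSolutions <- function(A, B) {
  stopifnot(is(A, "GroupingSolution"), is(B, "GroupingSolution"))
  if (length(A@assignment) != length(B@assignment))
    stop("parents encode different numbers of features")
  gB <- B@grouping
  assignment <- A@assignment
  if (length(gB) > 0) {
    i <- drawInt(1L, length(gB))
    j <- drawInt(1L, length(gB))
    frag <- gB[min(i, j):max(i, j)]
    for (id in setdiff(frag, A@grouping))
      assignment[B@assignment == id] <- id
  }
  GroupingSolution(assignment)
}

#' Grouping mutation
#'
#' With probability \code{pMut} the individual is recombined with a fresh
#' random solution (mutation understood as crossover with a random
#' individual); otherwise it is returned unchanged. Fitness is reset when
#' the individual changes.
#'
#' @param ind a \linkS4class{GroupingSolution}.
#' @param control a \code{\link{ggaControl}}.
#' @param idBase ids for the random partner's groups start above this;
#'   defaults to the largest id in \code{ind}.
#' @return A \linkS4class{GroupingSolution}.
#' @export
mutateSolution <- function(ind, control = ggaControl(), idBase = NULL) {
  if (runif(1) >= control$pMut) return(ind)
  if (is.null(idBase))
    idBase <- if (length(ind@grouping)) max(ind@grouping) else 0L
  partner <- randomSolution(length(ind@assignment), control,
                            idBase = as.integer(idBase))
  crossoverSolutions(ind, partner)
}

#' Tournament survival round
#'
#' Every individual in the merged parents + offspring population fights
#' \code{tournamentRounds} randomly chosen foes; a fight is won by
#' strictly higher fitness (ties by coin flip). The \code{nInd}
#' individuals with most won tournaments survive, ties broken by fitness
#' and then at random.
#'
#' @param merged list of evaluated \linkS4class{GroupingSolution}s.
#' @param control a \code{\link{ggaControl}}.
#' @return A list of \code{nInd} survivors.
#' @export
tournamentSurvival <- function(merged, control = ggaControl()) {
  n <- length(merged)
  if (n < control$nInd) stop("merged population smaller than nInd")
  fit <- vapply(merged, fitness, numeric(1))
  if (anyNA(fit)) stop("all individuals must be evaluated before survival")
  if (n == control$nInd) return(merged)
  wins <- integer(n)
  for (i in seq_len(n)) {
    foes <- sample.int(n - 1L, control$tournamentRounds, replace = TRUE)
    foes <- ifelse(foes >= i, foes + 1L, foes)  # exclude self
    for (f in foes) {
      if (fit[i] > fit[f] || (fit[i] == fit[f] && runif(1) < 0.5))
        wins[i] <- wins[i] + 1L
    }
  }
  ord <- order(-wins, -fit, runif(n))
  merged[ord[seq_len(control$nInd)]]
}

#' Population convergence test
#'
#' The population has converged when the best fitness lies within
#' \code{epsilon} of the population mean:
#' \eqn{f_{avg} - \epsilon \le f_{best} \le f_{avg} + \epsilon}
#' (boundaries inclusive).
#'
#' @param population list of evaluated \linkS4class{GroupingSolution}s.
#' @param epsilon convergence tolerance.
#' @return TRUE or FALSE.
#' @export
hasConverged <- function(population, epsilon = 0.001) {
  if (length(population) == 0) stop("population is empty")
  fit <- vapply(population, fitness, numeric(1))
  if (anyNA(fit)) stop("all individuals must be evaluated")
  abs(max(fit) - mean(fit)) <= epsilon
}

#' Serialize / restore a grouping solution as JSON
#'
#' @param sol a \linkS4class{GroupingSolution}.
#' @param path output JSON path.
#' @return \code{path} invisibly; \code{readSolution} returns the
#'   solution.
#' @export
writeSolution <- function(sol, path) {
  stopifnot(is(sol, "GroupingSolution"))
  jsonlite::write_json(
    list(assignment = sol@assignment, grouping = sol@grouping,
         fitness = sol@fitness, bestGroup = sol@bestGroup),
    path, digits = NA, auto_unbox = TRUE, na = "null")
  invisible(path)
}

#' @rdname writeSolution
#' @export
readSolution <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  GroupingSolution(o$assignment, grouping = o$grouping,
                   fitness = if (is.null(o$fitness)) NA_real_ else o$fitness,
                   bestGroup = if (is.null(o$bestGroup)) NA_integer_
                               else o$bestGroup)
}
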