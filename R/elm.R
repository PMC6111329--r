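#' Initialize an Extreme Learning Machine
#'
#' Draws the hidden-layer input weights \code{a} (L x d) and biases
#' \code{b} i.i.d. uniform on [-1, 1]. These stay fixed; only the output
#' weights are learned by \code{\link{elmFit}}.
#'
#' @param L hidden-node count (the reference configuration uses 23
#'   neurons for the 23-class problem).
#' @param d input dimension (number of selected features).
#' @param seed optional RNG seed; when NULL the current RNG stream is
#'   consumed, which is how the GGA redraws weights per evaluation.
#' @return An unfitted \linkS4class{ELMModel}.
#' @examples
#' m <- elmInit(L = 23, d = 36, seed = 7)
#' dim(m@a)
#' @export
elmInit <- function(L = 23, d, seed = NULL) {
  stopifnot(L >= 1, d >= 1)
  if (!is.null(seed)) set.seed(seed)
  new("ELMModel", L = as.integer(L),
      a = matrix(runif(L * d, -1, 1), nrow = L), b = runif(L, -1, 1),
      activation = "sigmoid", beta = matrix(numeric(0), 0, 0),
      classes = integer(0))
}

#' Hidden-layer output matrix
#'
#' Computes \eqn{H_{jl} = G(a_l, b_l, x_j)} with the logistic sigmoid
#' \eqn{G(a, b, x) = 1 / (1 + e^{-(a \cdot x + b)})}; every entry lies in
#' (0, 1).
#'
#' @param model an \linkS4class{ELMModel}.
#' @param X N x d matrix of inputs.
#' @return The N x L matrix H.
#' @export
elmHidden <- function(model, X) {
  stopifnot(is(model, "ELMModel"))
  X <- as.matrix(X)
  if (ncol(X) != ncol(model@a))
    stop("X has ", ncol(X), " columns but the model expects ", ncol(model@a))
  sigmoid(sweep(X %*% t(model@a), 2, model@b, "+"))
}

#' Fit ELM output weights
#'
#' One-hot encodes the training labels into Y (N x m, +1 for the true
#' class and 0 elsewhere) and solves \eqn{\beta = H^\dagger Y}, the
#' minimum-norm least-squares solution via the Moore-Penrose
#' pseudoinverse (SVD with relative cutoff 1e-10). The residual
#' \eqn{Y - H\beta} is orthogonal to the column space of H.
#'
#' @param model an initialized \linkS4class{ELMModel}.
#' @param X N x d training inputs.
#' @param y length-N integer training labels (>= 2 distinct classes).
#' @return The fitted \linkS4class{ELMModel}.
#' @export
elmFit <- function(model, X, y) {
  stopifnot(is(model, "ELMModel"))
  X <- as.matrix(X)
  y <- as.integer(y)
  if (nrow(X) == 0) stop("training set is empty")
  classes <- sort(unique(y))
  if (length(classes) < 2) stop("training set must contain >= 2 classes")
  H <- elmHidden(model, X)
  Y <- matrix(0, nrow(X), length(classes))
  Y[cbind(seq_len(nrow(X)), match(y, classes))] <- 1
  model@beta <- pinvSolve(H, Y)
  model@classes <- classes
  model
}

#' Predict class labels with a fitted ELM
#'
#' Scores are \eqn{H \beta}; each row is decoded to the class whose
#' one-hot column scores highest, ties broken toward the lower label.
#'
#' @param object a fitted \linkS4class{ELMModel}.
#' @param X N x d matrix of inputs.
#' @param ... ignored.
#' @return Integer labels of length N.
#' @export
setMethod("predict", "ELMModel", function(object, X, ...) {
  if (length(object@classes) == 0)
    stop("model has not been fitted; call elmFit() first")
  scores <- elmHidden(object, X) %*% object@beta
  object@classes[apply(scores, 1, which.max)]  # which.max takes first tie
})

#' Classification accuracy
#'
#' @param pred,truth equal-length label vectors (length >= 2).
#' @return Fraction of agreeing positions, in [0, 1].
#' @export
classificationAccuracy <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("pred and truth lengths differ")
  if (length(pred) < 2) stop("need at least 2 labels")
  mean(pred == truth)
}

#' Squared Pearson correlation of numeric labels
#'
#' The secondary quality metric: labels are treated as numbers and the
#' squared Pearson correlation between predicted and true labels is
#' returned (the regression-plot view of a classification). If either
#' side is constant the value is 0 by convention.
#'
#' @param pred,truth equal-length numeric/integer label vectors.
#' @return Rho-squared in [0, 1].
#' @export
rhoSquared <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("pred and truth lengths differ")
  if (length(pred) < 2) stop("need at least 2 labels")
  if (sd(pred) == 0 || sd(truth) == 0) return(0)
  cor(as.numeric(pred), as.numeric(truth))^2
}

#' Serialize / restore an ELM model as JSON
#'
#' @param model a (possibly fitted) \linkS4class{ELMModel}.
#' @param path output JSON path.
#' @return \code{path} invisibly; \code{readELM} returns the model.
#' @export
writeELM <- function(model, path) {
  stopifnot(is(model, "ELMModel"))
  obj <- list(L = model@L, d = ncol(model@a), a = as.numeric(model@a),
              b = model@b, activation = model@activation,
              beta = as.numeric(model@beta), betaDim = dim(model@beta),
              classes = model@classes)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeELM
#' @export
readELM <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("ELMModel", L = as.integer(o$L),
      a = matrix(o$a, nrow = o$L, ncol = o$d), b = as.numeric(o$b),
      activation = o$activation,
      beta = matrix(as.numeric(o$beta), nrow = o$betaDim[1],
                    ncol = o$betaDim[2]),
      classes = as.integer(o$classes))
}
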