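.activations <- list(
  sigmoid = function(x) 1 / (1 + exp(-x)),
  tanh = function(x) tanh(x),
  relu = function(x) pmax(x, 0)
)

.activationGrads <- list(
  sigmoid = function(x) { s <- 1 / (1 + exp(-x)); s * (1 - s) },
  tanh = function(x) 1 - tanh(x)^2,
  relu = function(x) as.numeric(x > 0)   # subgradient 0 at the kink
)

#' Draw random hidden-layer parameters for an extreme learning machine
#'
#' Weights and biases are i.i.d. uniform on [-1, 1].
#'
#' @param d input dimension.
#' @param L hidden node count.
#' @param seed integer seed.
#' @return List with \code{weights} (L x d) and \code{biases} (length L).
#' @export
initHidden <- function(d, L, seed = 1L) {
  stopifnotScalarCount(d, "d"); stopifnotScalarCount(L, "L")
  withSeed(seed, {
    list(weights = matrix(runif(L * d, -1, 1), L, d),
         biases = runif(L, -1, 1))
  })
}

#' Hidden-layer activation matrix
#'
#' Entry (j, i) is \code{activation(w_i . x_j + b_i)}.
#'
#' @param X sample matrix (rows are samples).
#' @param W L x d input weight matrix.
#' @param b length-L bias vector.
#' @param activation "sigmoid", "tanh" or "relu".
#' @return N x L matrix.
#' @export
hiddenMatrix <- function(X, W, b, activation = "sigmoid") {
  act <- .activations[[activation]]
  if (is.null(act)) stop(sprintf("unknown activation '%s'", activation))
  if (is.null(dim(X))) X <- matrix(X, 1L)
  if (ncol(X) != ncol(W)) stop("input dimension mismatch")
  act(tcrossprod(as.matrix(X), W) +
        matrix(b, nrow(X), length(b), byrow = TRUE))
}

#' Minimum-norm least-squares output weights
#'
#' Computes the Moore-Penrose solution \code{pinv(H) \%*\% Tm} through a
#' singular value decomposition, dropping singular values below
#' \code{rcond} times the largest. Among all least-squares solutions this
#' is the one of smallest Frobenius norm.
#'
#' @param H hidden-layer matrix (N x L).
#' @param Tm target matrix (N x C).
#' @param rcond relative rank tolerance, default 1e-10.
#' @return L x C weight matrix.
#' @export
solveOutputWeights <- function(H, Tm, rcond = 1e-10) {
  H <- as.matrix(H); Tm <- as.matrix(Tm)
  if (!length(H) || !length(Tm)) stop("empty inputs")
  if (nrow(H) != nrow(Tm)) stop("H and targets must have equal row counts")
  sv <- svd(H)
  keep <- sv$d > rcond * max(sv$d)
  if (!any(keep)) return(matrix(0, ncol(H), ncol(Tm)))
  u <- sv$u[, keep, drop = FALSE]
  v <- sv$v[, keep, drop = FALSE]
  v %*% ((crossprod(u, Tm)) / sv$d[keep])
}

#' Train an extreme learning machine
#'
#' Single non-iterative pass: draw hidden parameters (uniform [-1, 1]),
#' compute the hidden activation matrix, and solve the output weights as
#' the minimum-norm least-squares solution against one-hot targets
#' (1 for the true class, 0 otherwise; \code{encoding = "pm1"} uses
#' +1/-1).
#'
#' @param X training matrix (rows are samples).
#' @param y class labels (>= 2 distinct classes, >= 1 sample per class).
#' @param L hidden node count, default 50.
#' @param activation activation name, default "sigmoid".
#' @param seed seed for the hidden-parameter draw.
#' @param encoding "zeroone" (default) or "pm1" target coding.
#' @param hidden optional list(weights, biases) to use instead of a fresh
#'   random draw (e.g. optimizer-tuned parameters).
#' @return A trained \linkS4class{ELMModel}.
#' @export
trainELM <- function(X, y, L = 50L, activation = "sigmoid", seed = 1L,
                     encoding = c("zeroone", "pm1"), hidden = NULL) {
  encoding <- match.arg(encoding)
  X <- as.matrix(X)
  y <- as.character(y)
  if (nrow(X) != length(y)) stop("X rows and labels must align")
  classes <- sort(unique(y))
  if (length(classes) < 2L)
    stop("training data must contain at least 2 classes")
  if (is.null(hidden)) hidden <- initHidden(ncol(X), L, seed)
  H <- hiddenMatrix(X, hidden$weights, hidden$biases, activation)
  Tm <- oneHot(y, classes, encoding)
  beta <- solveOutputWeights(H, Tm)
  new("ELMModel", inputWeights = hidden$weights, biases = hidden$biases,
      activation = activation, outputWeights = beta, classes = classes,
      trained = TRUE)
}

oneHot <- function(y, classes, encoding = "zeroone") {
  Tm <- matrix(if (encoding == "pm1") -1 else 0,
               length(y), length(classes),
               dimnames = list(NULL, classes))
  Tm[cbind(seq_along(y), match(y, classes))] <- 1
  Tm
}

#' Class scores and labels from a trained ELM
#'
#' Scores are the hidden-layer outputs times the output weights; the
#' predicted label is the class of maximal score, ties broken by the
#' lowest class index.
#'
#' @param object a trained \linkS4class{ELMModel}.
#' @param X matrix of samples (or one sample vector).
#' @return List with \code{scores} (N x C matrix) and \code{labels}.
#' @export
elmPredict <- function(object, X) {
  stopifnot(is(object, "ELMModel"))
  if (!object@trained) stop("model is not trained")
  scores <- hiddenMatrix(X, object@inputWeights, object@biases,
                         object@activation) %*% object@outputWeights
  colnames(scores) <- object@classes
  list(scores = scores,
       labels = object@classes[max.col(scores, ties.method = "first")])
}

#' @describeIn elmPredict \code{predict} method returning labels
#'   (\code{type = "class"}) or the score matrix (\code{type = "score"}).
#' @param type "class" or "score".
#' @param ... ignored.
#' @export
setMethod("predict", "ELMModel", function(object, X,
                                          type = c("class", "score"), ...) {
  type <- match.arg(type)
  p <- elmPredict(object, X)
  if (type == "class") p$labels else p$scores
})

#' Serialize / restore an ELM model as JSON
#'
#' @param model a trained \linkS4class{ELMModel}.
#' @param path file path.
#' @return \code{readELM} returns the restored model.
#' @export
writeELM <- function(model, path) {
  obj <- list(inputWeights = model@inputWeights, biases = model@biases,
              activation = model@activation,
              outputWeights = model@outputWeights,
              classes = model@classes, trained = model@trained)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeELM
#' @export
readELM <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("ELMModel",
      inputWeights = matrix(as.numeric(o$inputWeights),
                            nrow = length(o$biases)),
      biases = as.numeric(o$biases), activation = o$activation,
      outputWeights = matrix(as.numeric(o$outputWeights),
                             nrow = length(o$biases)),
      classes = as.character(o$classes), trained = as.logical(o$trained))
}

setMethod("show", "ELMModel", function(object) {
  cat(sprintf("ELMModel: %d hidden nodes, d=%d, activation=%s%s\n",
              nrow(object@inputWeights), ncol(object@inputWeights),
              object@activation,
              if (object@trained)
                sprintf(", trained (%s)",
                        paste(object@classes, collapse = "/"))
              else ", untrained"))
})
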