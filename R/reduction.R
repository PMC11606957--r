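#' Fit the PCA stage of the feature reduction
#'
#' Centers the feature matrix and eigendecomposes its sample covariance
#' (1/(n-1) normalization). Axes are stored by descending eigenvalue with a
#' deterministic sign convention: the loading of largest magnitude on each
#' axis is made positive.
#'
#' @param X numeric matrix, samples in rows (>= 2 rows).
#' @param maxComponents number of principal axes to retain; at most
#'   \code{min(nrow(X) - 1, ncol(X))}. Default keeps that maximum.
#' @return A partial (unfinished) \linkS4class{ReductionModel} holding the
#'   center, axes and eigenvalues; complete it with
#'   \code{\link{fitDiscriminant}} or use \code{\link{fitReduction}}.
#' @export
fitPCA <- function(X, maxComponents = min(nrow(X) - 1L, ncol(X))) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("need at least 2 samples to fit a PCA")
  if (maxComponents < 1L || maxComponents > min(nrow(X) - 1L, ncol(X)))
    stop("maxComponents must lie in [1, min(n - 1, d)]")
  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr)
  cv <- crossprod(Xc) / (nrow(X) - 1L)
  if (max(abs(cv)) < 1e-300)
    stop("degenerate input: the feature matrix has zero variance")
  e <- eigen(cv, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  keep <- seq_len(maxComponents)
  axes <- e$vectors[, keep, drop = FALSE]
  for (j in seq_len(ncol(axes))) {     # sign convention: top loading > 0
    i <- which.max(abs(axes[, j]))
    if (axes[i, j] < 0) axes[, j] <- -axes[, j]
  }
  new("ReductionModel", center = ctr, axes = axes,
      eigenvalues = ev[keep], fitted = FALSE)
}

#' Normalized cumulative sum of variance (NCSOV)
#'
#' Element i is the cumulative sum of the first i eigenvalues divided by
#' the total; the final element is exactly 1.
#'
#' @param eigenvalues non-empty, non-negative, descending numeric vector.
#' @return Numeric vector of cumulative variance fractions.
#' @examples
#' ncsov(c(4, 3, 2, 1))  # 0.4 0.7 0.9 1.0
#' @export
ncsov <- function(eigenvalues) {
  if (!length(eigenvalues)) stop("eigenvalues must be non-empty")
  if (any(eigenvalues < 0)) stop("eigenvalues must be non-negative")
  if (is.unsorted(rev(eigenvalues)))
    stop("eigenvalues must be in descending order")
  tot <- sum(eigenvalues)
  if (tot == 0) stop("all eigenvalues are zero")
  out <- cumsum(eigenvalues) / tot
  out[length(out)] <- 1
  out
}

#' Pick the PCA dimension by the NCSOV threshold
#'
#' @param eigenvalues descending non-negative eigenvalues.
#' @param threshold cumulative variance fraction in (0, 1].
#' @return The smallest component count whose NCSOV reaches the threshold.
#' @export
selectByNCSOV <- function(eigenvalues, threshold) {
  if (threshold <= 0 || threshold > 1)
    stop("threshold must lie in (0, 1]")
  frac <- ncsov(eigenvalues)
  which(frac >= threshold - 1e-12)[1L]
}

# Fisher ratio of each column of Z: between-class variance over pooled
# within-class variance.
fisherScores <- function(Z, y) {
  y <- as.character(y)
  classes <- unique(y)
  gm <- colMeans(Z)
  sb <- numeric(ncol(Z)); sw <- numeric(ncol(Z))
  for (cl in classes) {
    Zi <- Z[y == cl, , drop = FALSE]
    mi <- colMeans(Zi)
    sb <- sb + nrow(Zi) * (mi - gm)^2
    sw <- sw + colSums(sweep(Zi, 2L, mi)^2)
  }
  ifelse(sw > 0, sb / sw, ifelse(sb > 0, Inf, 0))
}

#' Complete a reduction model with the supervised discriminant stage
#'
#' Two modes. \code{"ranking"} (default, well-defined for any class count)
#' scores each PCA axis by its Fisher ratio (between-class over
#' within-class variance) and keeps the \code{nKeep} highest-scoring axes,
#' preserving their PCA order. \code{"strict"} projects onto the (at most
#' C-1) leading eigendirections of the within/between scatter ratio, i.e.
#' classical LDA; it fails with guidance when the within-class scatter is
#' singular (the small-sample-size condition).
#'
#' @param model a partial \linkS4class{ReductionModel} from
#'   \code{\link{fitPCA}}.
#' @param Z the PCA-projected training matrix (use
#'   \code{\link{pcaTransform}}).
#' @param y class labels, >= 2 classes.
#' @param nKeep output dimension (ranking mode); ignored in strict mode
#'   beyond capping at C-1.
#' @param mode \code{"ranking"} or \code{"strict"}.
#' @return The completed, fitted \linkS4class{ReductionModel}.
#' @export
fitDiscriminant <- function(model, Z, y, nKeep = ncol(Z),
                            mode = c("ranking", "strict")) {
  mode <- match.arg(mode)
  stopifnot(is(model, "ReductionModel"))
  y <- as.character(y)
  if (length(unique(y)) < 2L) stop("need at least 2 classes")
  if (nrow(Z) != length(y)) stop("Z rows and labels must align")
  if (ncol(Z) != ncol(model@axes)) stop("Z must be the PCA projection")
  if (mode == "ranking") {
    if (nKeep < 1L || nKeep > ncol(Z))
      stop("nKeep must lie in [1, ncol(Z)]")
    sc <- fisherScores(Z, y)
    sel <- sort(order(sc, decreasing = TRUE)[seq_len(nKeep)])
    model@discriminantScores <- sc
    model@selected <- as.integer(sel)
  } else {
    classes <- unique(y)
    C <- length(classes)
    gm <- colMeans(Z)
    p <- ncol(Z)
    Sw <- matrix(0, p, p); Sb <- matrix(0, p, p)
    for (cl in classes) {
      Zi <- Z[y == cl, , drop = FALSE]
      mi <- colMeans(Zi)
      Zc <- sweep(Zi, 2L, mi)
      Sw <- Sw + crossprod(Zc)
      Sb <- Sb + nrow(Zi) * tcrossprod(mi - gm)
    }
    if (rcond(Sw) < 1e-12)
      stop("within-class scatter is singular (small-sample-size ",
           "condition); use mode = 'ranking' or provide more samples")
    e <- eigen(solve(Sw, Sb))
    ld <- min(C - 1L, p)
    W <- Re(e$vectors[, seq_len(ld), drop = FALSE])
    W <- apply(W, 2L, function(v) v / sqrt(sum(v^2)))
    model@ldaProjection <- matrix(W, nrow = p)
  }
  model@mode <- mode
  model@fitted <- TRUE
  validObject(model)
  model
}

#' Project features onto the PCA axes of a reduction model
#'
#' @param model a \linkS4class{ReductionModel} (partial is fine).
#' @param X feature matrix (or single feature vector).
#' @return Centered PCA-projected matrix with \code{MA} columns.
#' @export
pcaTransform <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, 1L)
  X <- as.matrix(X)
  if (ncol(X) != length(model@center))
    stop("feature dimension does not match the model")
  sweep(X, 2L, model@center) %*% model@axes
}

#' Fit the full PCA + discriminant reduction
#'
#' Convenience wrapper: \code{\link{fitPCA}} (dimension fixed by
#' \code{pcaComponents}, or chosen by the NCSOV threshold when NULL),
#' then \code{\link{fitDiscriminant}}.
#'
#' @param X training feature matrix.
#' @param y class labels.
#' @param pcaComponents PCA dimension MA; NULL selects it as the smallest
#'   count whose normalized cumulative variance reaches
#'   \code{ncsovThreshold}.
#' @param ncsovThreshold cumulative variance threshold, default 0.98.
#' @param nKeep final reduced dimension LD (ranking mode); defaults to the
#'   PCA dimension.
#' @param mode discriminant mode, see \code{\link{fitDiscriminant}}.
#' @return A fitted \linkS4class{ReductionModel}.
#' @export
fitReduction <- function(X, y, pcaComponents = NULL, ncsovThreshold = 0.98,
                         nKeep = NULL, mode = c("ranking", "strict")) {
  mode <- match.arg(mode)
  pm <- fitPCA(X)
  ma <- if (is.null(pcaComponents))
    selectByNCSOV(pm@eigenvalues, ncsovThreshold)
  else min(as.integer(pcaComponents), ncol(pm@axes))
  pm@axes <- pm@axes[, seq_len(ma), drop = FALSE]
  pm@eigenvalues <- pm@eigenvalues[seq_len(ma)]
  pm@ncsovThreshold <- if (is.null(pcaComponents)) ncsovThreshold
                       else NA_real_
  Z <- pcaTransform(pm, X)
  if (is.null(nKeep)) nKeep <- ma else nKeep <- min(as.integer(nKeep), ma)
  fitDiscriminant(pm, Z, y, nKeep = nKeep, mode = mode)
}

#' Map raw features to the reduced space
#'
#' Centers, projects onto the PCA axes, then applies the discriminant
#' stage (axis selection in ranking mode, LDA projection in strict mode).
#'
#' @param model a fitted \linkS4class{ReductionModel}.
#' @param X feature matrix or single feature vector.
#' @return Reduced matrix with LD columns.
#' @export
reduceFeatures <- function(model, X) {
  stopifnot(is(model, "ReductionModel"))
  if (!model@fitted) stop("reduction model is not fitted")
  Z <- pcaTransform(model, X)
  if (model@mode == "ranking") Z[, model@selected, drop = FALSE]
  else Z %*% model@ldaProjection
}

#' Dimension bookkeeping of a reduction model
#'
#' @param model a \linkS4class{ReductionModel}.
#' @return Named integer vector with the input dimension D, the PCA
#'   dimension MA and the final reduced dimension LD.
#' @export
reducedDims <- function(model) {
  ld <- if (!model@fitted) NA_integer_
        else if (model@mode == "ranking") length(model@selected)
        else ncol(model@ldaProjection)
  c(D = nrow(model@axes), MA = ncol(model@axes), LD = ld)
}

# Linear map of the full fitted reduction (LD x D), used by the saliency
# backward pass: reduceFeatures(model, x) == t(M %*% (x - center)).
reductionMatrix <- function(model) {
  stopifnot(model@fitted)
  if (model@mode == "ranking")
    t(model@axes[, model@selected, drop = FALSE])
  else t(model@axes %*% model@ldaProjection)
}

#' Serialize / restore a reduction model as JSON
#'
#' @param model a \linkS4class{ReductionModel}.
#' @param path file path to write to (or read from).
#' @return \code{readReduction} returns the restored model.
#' @export
writeReduction <- function(model, path) {
  obj <- list(center = model@center, axes = model@axes,
              eigenvalues = model@eigenvalues,
              ncsovThreshold = model@ncsovThreshold, mode = model@mode,
              discriminantScores = model@discriminantScores,
              selected = model@selected,
              ldaProjection = model@ldaProjection, fitted = model@fitted)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeReduction
#' @export
readReduction <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  thr <- suppressWarnings(as.numeric(o$ncsovThreshold))
  new("ReductionModel", center = as.numeric(o$center),
      axes = matrix(as.numeric(o$axes), ncol = length(o$eigenvalues)),
      eigenvalues = as.numeric(o$eigenvalues),
      ncsovThreshold = if (length(thr)) thr else NA_real_, mode = o$mode,
      discriminantScores = as.numeric(o$discriminantScores),
      selected = as.integer(o$selected),
      ldaProjection = if (length(o$ldaProjection))
        matrix(as.numeric(o$ldaProjection),
               nrow = length(o$eigenvalues)) else matrix(0, 0, 0),
      fitted = as.logical(o$fitted))
}

setMethod("show", "ReductionModel", function(object) {
  d <- reducedDims(object)
  cat(sprintf("ReductionModel (%s%s): D=%d -> MA=%d -> LD=%s\n",
              object@mode, if (object@fitted) ", fitted" else ", partial",
              d["D"], d["MA"],
              if (is.na(d["LD"])) "?" else d["LD"]))
})
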