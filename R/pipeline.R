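# End-to-end MOD-POA + ELM classifier, evaluation protocols and metrics.

#' Pack / unpack ELM hidden parameters for the optimizer
#'
#' Bijective row-major packing of the L x d input weight matrix followed
#' by the L biases; the search dimension is L * (d + 1).
#'
#' @param W L x d weight matrix.
#' @param b length-L bias vector.
#' @return \code{encodePosition}: numeric vector of length L * (d + 1).
#' @export
encodePosition <- function(W, b) {
  if (nrow(W) != length(b)) stop("one bias per hidden node required")
  c(as.vector(t(W)), b)
}

#' @rdname encodePosition
#' @param position flat parameter vector.
#' @param L hidden node count.
#' @param d input dimension.
#' @return \code{decodePosition}: list(weights, biases).
#' @export
decodePosition <- function(position, L, d) {
  if (length(position) != L * (d + 1L))
    stop("position length must equal L * (d + 1)")
  list(weights = matrix(position[seq_len(L * d)], L, d, byrow = TRUE),
       biases = position[L * d + seq_len(L)])
}

#' Validation-error objective for hidden-parameter tuning
#'
#' Decodes a candidate position into hidden weights and biases, solves the
#' ELM output weights on the training split (minimum-norm least squares)
#' and returns the misclassification rate on the validation split.
#'
#' @param position flat hidden-parameter vector.
#' @param Xtrain,ytrain training split.
#' @param Xval,yval validation split.
#' @param L hidden node count.
#' @param activation activation name.
#' @return Error rate in [0, 1].
#' @export
elmFitness <- function(position, Xtrain, ytrain, Xval, yval, L,
                       activation = "sigmoid") {
  hidden <- decodePosition(position, L, ncol(Xtrain))
  model <- trainELM(Xtrain, ytrain, L = L, activation = activation,
                    hidden = hidden)
  mean(elmPredict(model, Xval)$labels != as.character(yval))
}

#' Stratified k-fold assignments
#'
#' Each class is shuffled then dealt round-robin into the k folds, so
#' per-fold class counts differ from exact proportionality by at most one
#' sample.
#'
#' @param y class labels.
#' @param k fold count; every class must have at least k members.
#' @param seed integer seed.
#' @return Integer vector of fold ids (1..k), aligned with \code{y}.
#' @export
stratifiedFolds <- function(y, k, seed = 1L) {
  y <- as.character(y)
  stopifnotScalarCount(k, "k", min = 2L)
  counts <- table(y)
  if (any(counts < k))
    stop(sprintf("class '%s' has fewer than k = %d members",
                 names(counts)[which.min(counts)], k))
  fold <- integer(length(y))
  withSeed(seed, {
    for (cl in names(counts)) {
      ids <- sample(which(y == cl))
      fold[ids] <- rep_len(seq_len(k), length(ids))
    }
  })
  fold
}

#' Stratified holdout split
#'
#' @param y class labels.
#' @param trainFraction fraction per class assigned to training, in (0,1);
#'   default 0.6 (the 60:40 protocol).
#' @param seed integer seed.
#' @return List with integer id vectors \code{train} and \code{test}.
#' @export
holdoutSplit <- function(y, trainFraction = 0.6, seed = 1L) {
  y <- as.character(y)
  if (trainFraction <= 0 || trainFraction >= 1)
    stop("trainFraction must lie in (0, 1)")
  if (any(table(y) < 2L)) stop("every class needs at least 2 members")
  train <- integer(0)
  withSeed(seed, {
    for (cl in unique(y)) {
      ids <- sample(which(y == cl))
      nTr <- max(1L, min(length(ids) - 1L,
                         floor(trainFraction * length(ids) + 0.5)))
      train <- c(train, ids[seq_len(nTr)])
    }
  })
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(y), train))
}

#' Confusion counts with a fixed positive class
#'
#' @param truth,predicted label vectors.
#' @param positive positive class name (default "glaucoma").
#' @return Named vector TP, FP, TN, FN.
#' @export
confusionCounts <- function(truth, predicted, positive = "glaucoma") {
  truth <- as.character(truth); predicted <- as.character(predicted)
  c(TP = sum(truth == positive & predicted == positive),
    FP = sum(truth != positive & predicted == positive),
    TN = sum(truth != positive & predicted != positive),
    FN = sum(truth == positive & predicted != positive))
}

#' Accuracy, sensitivity and specificity from confusion counts
#'
#' Values are reported in percent. A zero denominator (no positives or no
#' negatives in the test set) yields NaN with a warning.
#'
#' @param counts named vector with TP, FP, TN, FN (non-negative,
#'   positive total).
#' @return Named vector \code{accuracy}, \code{sensitivity},
#'   \code{specificity} in percent.
#' @examples
#' computeMetrics(c(TP = 30, FP = 5, TN = 55, FN = 10))
#' @export
computeMetrics <- function(counts) {
  counts <- counts[c("TP", "FP", "TN", "FN")]
  if (any(is.na(counts)) || any(counts < 0))
    stop("counts must be non-negative TP, FP, TN, FN")
  tot <- sum(counts)
  if (tot == 0) stop("empty confusion matrix")
  sens <- if (counts["TP"] + counts["FN"] > 0)
    counts[["TP"]] / (counts[["TP"]] + counts[["FN"]]) else {
      warning("no positive-class samples: sensitivity undefined"); NaN
    }
  spec <- if (counts["TN"] + counts["FP"] > 0)
    counts[["TN"]] / (counts[["TN"]] + counts[["FP"]]) else {
      warning("no negative-class samples: specificity undefined"); NaN
    }
  c(accuracy = 100 * (counts[["TP"]] + counts[["TN"]]) / tot,
    sensitivity = 100 * sens, specificity = 100 * spec)
}

#' Default classifier configuration
#'
#' @param L hidden node count (default 50).
#' @param activation ELM activation (default "sigmoid").
#' @param U population size (default 20).
#' @param P optimizer iterations (default 100).
#' @param variant "MOD-POA", "POA" or "random" (plain random-init ELM, no
#'   tuning).
#' @param mode discriminant mode: "strict" (default; classical PCA-LDA
#'   cascade, the right choice for binary labels) or "ranking" (per-axis
#'   Fisher-ratio selection keeping \code{nKeep} axes).
#' @param innerFraction inner train fraction for the tuning objective's
#'   stratified train/validation split (default 0.8).
#' @param pcaComponents,ncsovThreshold,nKeep reduction settings, see
#'   \code{\link{fitReduction}}.
#' @return Plain list of settings.
#' @export
classifierConfig <- function(L = 50L, activation = "sigmoid", U = 20L,
                             P = 100L, variant = "MOD-POA",
                             innerFraction = 0.8, pcaComponents = 32L,
                             ncsovThreshold = 0.98, nKeep = 28L,
                             mode = "strict") {
  list(L = as.integer(L), activation = activation, U = as.integer(U),
       P = as.integer(P), variant = variant,
       innerFraction = innerFraction, pcaComponents = pcaComponents,
       ncsovThreshold = ncsovThreshold, nKeep = nKeep, mode = mode)
}

#' Train an ELM whose hidden parameters are tuned by the pelican optimizer
#'
#' Splits the training data with an inner stratified 80:20
#' train/validation split, minimizes the validation misclassification rate
#' (\code{\link{elmFitness}}) over the hidden weights and biases in
#' [-1, 1] with the chosen optimizer variant, then refits the output
#' weights on the full training data at the best position. The seed-derived
#' random ELM initialization is injected as the first population member, so
#' on the inner criterion the tuned model never does worse than the plain
#' random-init ELM.
#'
#' @param X reduced training matrix.
#' @param y class labels.
#' @param config list from \code{\link{classifierConfig}}.
#' @param seed master seed.
#' @return List with \code{elm} (trained \linkS4class{ELMModel}) and
#'   \code{optimization} (\linkS4class{PelicanResult} or NULL for
#'   \code{variant = "random"}).
#' @export
trainModPoaELM <- function(X, y, config = classifierConfig(), seed = 1L) {
  X <- as.matrix(X); y <- as.character(y)
  if (length(unique(y)) < 2L) stop("need at least 2 classes")
  L <- config$L; d <- ncol(X)
  # standardize features so that uniform [-1, 1] hidden weights operate on
  # comparable scales; the scaling is folded back into the trained weights
  # below, so the returned model acts on raw (unscaled) features
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  scl[scl == 0] <- 1
  Xs <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")
  fit <- if (config$variant == "random") {
    list(elm = trainELM(Xs, y, L = L, activation = config$activation,
                        seed = seed),
         optimization = NULL)
  } else {
    inner <- holdoutSplit(y, trainFraction = config$innerFraction,
                          seed = seed)
    Xtr <- Xs[inner$train, , drop = FALSE]; ytr <- y[inner$train]
    Xval <- Xs[inner$test, , drop = FALSE]; yval <- y[inner$test]
    if (length(unique(ytr)) < 2L) stop("single-class inner training split")
    objective <- function(pos)
      elmFitness(pos, Xtr, ytr, Xval, yval, L, config$activation)
    V <- L * (d + 1L)
    init <- initHidden(d, L, seed = seed)
    res <- pelicanMinimize(objective, lower = rep(-1, V), upper = rep(1, V),
                           U = config$U, P = config$P,
                           variant = config$variant, seed = seed,
                           inject = list(encodePosition(init$weights,
                                                        init$biases)))
    hidden <- decodePosition(bestPosition(res), L, d)
    list(elm = trainELM(Xs, y, L = L, activation = config$activation,
                        hidden = hidden),
         optimization = res)
  }
  # fold the standardization into the hidden layer:
  # W (x - ctr) / scl + b  ==  (W / scl) x + (b - W (ctr / scl))
  elm <- fit$elm
  W <- sweep(elm@inputWeights, 2L, scl, "/")
  elm@inputWeights <- W
  elm@biases <- elm@biases - as.vector(W %*% ctr)
  fit$elm <- elm
  fit
}

#' Train the full curvelet + reduction + optimized-ELM pipeline
#'
#' Extracts curvelet features from the training images, fits the
#' PCA+discriminant reduction on them, and trains the (optionally
#' optimizer-tuned) ELM on the reduced features.
#'
#' @param images list of \linkS4class{FundusImage} or matrices.
#' @param labels class labels.
#' @param config list from \code{\link{classifierConfig}}.
#' @param curvelet a \linkS4class{CurveletConfig} (default derived from the
#'   image size).
#' @param scales,stats feature settings, see \code{\link{extractFeatures}}.
#' @param seed master seed.
#' @return A \linkS4class{GlaucomaPipeline}.
#' @export
trainPipeline <- function(images, labels, config = classifierConfig(),
                          curvelet = NULL, scales = NULL,
                          stats = c("mean", "sd", "energy"), seed = 1L) {
  if (is.null(curvelet))
    curvelet <- curveletConfig(nrow(asPixels(images[[1]])))
  X <- batchExtract(images, curvelet, scales, stats)
  fitPipelineOnFeatures(X, labels, config, curvelet,
                        resolveScales(curvelet, scales), stats, seed)
}

# Shared trainer over a precomputed raw feature matrix.
fitPipelineOnFeatures <- function(X, labels, config, curvelet, scales,
                                  stats, seed) {
  red <- fitReduction(X, labels, pcaComponents = config$pcaComponents,
                      ncsovThreshold = config$ncsovThreshold,
                      nKeep = config$nKeep, mode = config$mode)
  Z <- reduceFeatures(red, X)
  fit <- trainModPoaELM(Z, labels, config, seed = seed)
  new("GlaucomaPipeline", curveletConfig = curvelet,
      scales = as.integer(scales), stats = stats, reduction = red,
      elm = fit$elm, optimization = fit$optimization)
}

#' @describeIn trainPipeline Predict labels (or class scores) for new
#'   images.
#' @param object a trained \linkS4class{GlaucomaPipeline}.
#' @param type "class" or "score".
#' @param ... ignored.
#' @export
setMethod("predict", "GlaucomaPipeline",
          function(object, images, type = c("class", "score"), ...) {
  type <- match.arg(type)
  X <- batchExtract(images, object@curveletConfig, object@scales,
                    object@stats)
  Z <- reduceFeatures(object@reduction, X)
  predict(object@elm, Z, type = type)
})

#' Repeated stratified k-fold cross-validation on a feature matrix
#'
#' For each run a fresh fold seed is drawn; within each fold the reduction
#' is fitted on the training folds only (no test-fold leakage), the
#' classifier is trained (with hidden-parameter tuning unless
#' \code{variant = "random"}) and the held-out fold is scored. The report
#' mirrors the run-by-fold layout of the study protocol.
#'
#' @param X raw feature matrix (rows are samples).
#' @param y class labels.
#' @param config list from \code{\link{classifierConfig}}.
#' @param runs repeated CV runs (default 10).
#' @param k folds per run (default 5).
#' @param seed master seed; run r uses a fold seed derived from \code{seed} and r.
#' @param positive positive class for sensitivity/specificity.
#' @return An \linkS4class{EvaluationReport}.
#' @export
crossValidate <- function(X, y, config = classifierConfig(), runs = 10L,
                          k = 5L, seed = 1L, positive = "glaucoma") {
  X <- as.matrix(X); y <- as.character(y)
  rows <- vector("list", runs * k)
  idx <- 0L
  for (r in seq_len(runs)) {
    fold <- stratifiedFolds(y, k, seed = seedOffset(seed, r))
    for (f in seq_len(k)) {
      tr <- which(fold != f); te <- which(fold == f)
      red <- fitReduction(X[tr, , drop = FALSE], y[tr],
                          pcaComponents = config$pcaComponents,
                          ncsovThreshold = config$ncsovThreshold,
                          nKeep = config$nKeep, mode = config$mode)
      Ztr <- reduceFeatures(red, X[tr, , drop = FALSE])
      fit <- trainModPoaELM(Ztr, y[tr], config,
                            seed = seedOffset(seed, 1000L * r + f))
      Zte <- reduceFeatures(red, X[te, , drop = FALSE])
      pred <- elmPredict(fit$elm, Zte)$labels
      cc <- confusionCounts(y[te], pred, positive)
      m <- suppressWarnings(computeMetrics(cc))
      idx <- idx + 1L
      rows[[idx]] <- data.frame(run = r, fold = f, t(cc), t(m))
    }
  }
  new("EvaluationReport", table = do.call(rbind, rows),
      positive = positive, runs = as.integer(runs), k = as.integer(k))
}

#' Summarize an evaluation report
#'
#' @param report an \linkS4class{EvaluationReport}.
#' @return List with \code{perRun} (mean metrics per run) and \code{grand}
#'   (mean and sd of the per-fold metrics).
#' @export
reportSummary <- function(report) {
  tab <- report@table
  mets <- c("accuracy", "sensitivity", "specificity")
  perRun <- aggregate(tab[mets], by = list(run = tab$run), FUN = mean)
  grand <- rbind(mean = colMeans(tab[mets], na.rm = TRUE),
                 sd = apply(tab[mets], 2L, stats::sd, na.rm = TRUE))
  list(perRun = perRun, grand = grand)
}

#' @describeIn reportSummary Grand mean accuracy in percent.
#' @export
meanAccuracy <- function(report) mean(report@table$accuracy, na.rm = TRUE)

setMethod("show", "EvaluationReport", function(object) {
  s <- reportSummary(object)
  cat(sprintf("EvaluationReport: %d x %d-fold CV, positive class '%s'\n",
              object@runs, object@k, object@positive))
  cat(sprintf("  accuracy    %6.2f%% +/- %.2f\n",
              s$grand["mean", "accuracy"], s$grand["sd", "accuracy"]))
  cat(sprintf("  sensitivity %6.2f%% +/- %.2f\n",
              s$grand["mean", "sensitivity"], s$grand["sd", "sensitivity"]))
  cat(sprintf("  specificity %6.2f%% +/- %.2f\n",
              s$grand["mean", "specificity"], s$grand["sd", "specificity"]))
})

setMethod("show", "GlaucomaPipeline", function(object) {
  d <- reducedDims(object@reduction)
  cat(sprintf(
    "GlaucomaPipeline: curvelet %dpx/%d scales -> D=%d -> MA=%d -> LD=%d -> ELM(L=%d, %s)%s\n",
    object@curveletConfig@imageSize, object@curveletConfig@nScales,
    d["D"], d["MA"], d["LD"], nrow(object@elm@inputWeights),
    object@elm@activation,
    if (is.null(object@optimization)) " [random init]"
    else sprintf(" [%s]", object@optimization@variant)))
})
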