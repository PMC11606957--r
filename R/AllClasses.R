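#' @import methods
#' @importFrom stats fft rnorm runif sd var predict
NULL

#' Synthetic fundus generator settings
#'
#' Parameter container for the synthetic fundus generator. The generator
#' draws a bright elliptical optic disc, a brighter concentric optic cup
#' whose radius is the label-dependent cup-to-disc ratio (CDR) times the
#' disc radius, dark curvilinear vessel strokes, a smooth illumination
#' gradient and additive Gaussian noise.
#'
#' @slot imageSize integer, pixels per side (square image); even, >= 32.
#' @slot discRadiusRange numeric length-2, disc semi-major axis range (px).
#' @slot cdrHealthy cup-to-disc ratio for the healthy class, in (0,1).
#' @slot cdrGlaucoma cup-to-disc ratio for the glaucoma class, in (0,1);
#'   must exceed \code{cdrHealthy}.
#' @slot vesselCount integer, number of vessel strokes.
#' @slot noiseSigma standard deviation of additive Gaussian noise on the
#'   [0,1] gray scale.
#' @slot seed default integer seed used when an operation is not given one.
#' @export
setClass("SyntheticSpec",
  representation(
    imageSize = "integer",
    discRadiusRange = "numeric",
    cdrHealthy = "numeric",
    cdrGlaucoma = "numeric",
    vesselCount = "integer",
    noiseSigma = "numeric",
    seed = "integer"
  ),
  prototype(
    imageSize = 128L,
    discRadiusRange = c(24, 28),
    cdrHealthy = 0.3,
    cdrGlaucoma = 0.7,
    vesselCount = 4L,
    noiseSigma = 0.02,
    seed = 1L
  )
)

setValidity("SyntheticSpec", function(object) {
  msg <- character()
  if (length(object@imageSize) != 1L || object@imageSize < 32L ||
      object@imageSize %% 2L != 0L)
    msg <- c(msg, "imageSize must be a single even integer >= 32")
  if (length(object@discRadiusRange) != 2L ||
      any(object@discRadiusRange <= 0) ||
      diff(object@discRadiusRange) < 0)
    msg <- c(msg, "discRadiusRange must be two positive non-decreasing values")
  if (!(object@cdrHealthy > 0 && object@cdrHealthy < object@cdrGlaucoma &&
        object@cdrGlaucoma < 1))
    msg <- c(msg, "need 0 < cdrHealthy < cdrGlaucoma < 1")
  if (object@vesselCount < 0L) msg <- c(msg, "vesselCount must be >= 0")
  if (object@noiseSigma < 0 || object@noiseSigma > 1)
    msg <- c(msg, "noiseSigma must lie in [0,1]")
  if (length(msg)) msg else TRUE
})

#' A fundus-like grayscale image with optional label and generator masks
#'
#' @slot pixels numeric matrix with values in [0,1].
#' @slot label class label, one of \code{"healthy"}, \code{"glaucoma"}, or
#'   \code{""} when unlabeled.
#' @slot discMask logical matrix marking the optic disc region (generator
#'   images only; empty matrix otherwise).
#' @slot cupMask logical matrix marking the optic cup region.
#' @export
setClass("FundusImage",
  representation(
    pixels = "matrix",
    label = "character",
    discMask = "matrix",
    cupMask = "matrix"
  ),
  prototype(label = "", discMask = matrix(logical(0), 0, 0),
            cupMask = matrix(logical(0), 0, 0))
)

setValidity("FundusImage", function(object) {
  p <- object@pixels
  if (nrow(p) != ncol(p)) return("pixels must be square")
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    return("pixel values must be finite and within [0,1]")
  if (!object@label %in% c("", "healthy", "glaucoma"))
    return("label must be '', 'healthy' or 'glaucoma'")
  TRUE
})

#' Curvelet transform configuration
#'
#' @slot imageSize side length of the (square) input image in pixels.
#' @slot nScales number of scales; the coarsest and finest scales are
#'   isotropic, intermediate scales are split into angular wedges.
#' @slot nAnglesCoarse number of angular wedges at the second-coarsest
#'   scale; one of 8, 16, 32. Wedge counts double every second scale step
#'   (parabolic scaling).
#' @export
setClass("CurveletConfig",
  representation(
    imageSize = "integer",
    nScales = "integer",
    nAnglesCoarse = "integer"
  )
)

setValidity("CurveletConfig", function(object) {
  msg <- character()
  if (object@nScales < 2L) msg <- c(msg, "nScales must be >= 2")
  if (!(object@nAnglesCoarse %in% c(8L, 16L, 32L)))
    msg <- c(msg, "nAnglesCoarse must be one of 8, 16, 32")
  if (object@imageSize < 16L || object@imageSize %% 2L != 0L)
    msg <- c(msg, "imageSize must be even and >= 16")
  if (length(msg)) msg else TRUE
})

#' Curvelet coefficients of one image
#'
#' Nested scale/wedge collection of complex coefficient arrays produced by
#' the wrapping-based fast discrete curvelet transform. Scale 1 (coarsest)
#' and the finest scale hold a single isotropic array; intermediate scales
#' hold one wrapped array per angular wedge.
#'
#' @slot wedges list of length \code{nScales}; element s is a list of
#'   complex matrices (one per wedge at that scale).
#' @slot config the \linkS4class{CurveletConfig} used.
#' @export
setClass("CurveletCoefficients",
  representation(wedges = "list", config = "CurveletConfig")
)

#' PCA + discriminant feature reduction model
#'
#' Principal axes with eigenvalues, the normalized cumulative sum of
#' variance (NCSOV) threshold used to pick the PCA dimension, and a
#' supervised discriminant stage: either Fisher-ratio ranking of the PCA
#' axes (default, keeps \code{nKeep} axes) or a strict LDA projection onto
#' at most C-1 eigendirections of the scatter-ratio matrix.
#'
#' @slot center feature-wise training mean (length D).
#' @slot axes D x MA matrix of orthonormal principal axes (columns).
#' @slot eigenvalues descending PCA eigenvalues (length MA).
#' @slot ncsovThreshold cumulative-variance threshold in (0,1] that chose MA
#'   (NA when MA was fixed directly).
#' @slot mode \code{"ranking"} or \code{"strict"}.
#' @slot discriminantScores Fisher ratio per PCA axis (ranking mode).
#' @slot selected integer indices of the retained PCA axes (ranking mode).
#' @slot ldaProjection MA x LD projection matrix (strict mode).
#' @slot fitted logical.
#' @export
setClass("ReductionModel",
  representation(
    center = "numeric",
    axes = "matrix",
    eigenvalues = "numeric",
    ncsovThreshold = "numeric",
    mode = "character",
    discriminantScores = "numeric",
    selected = "integer",
    ldaProjection = "matrix",
    fitted = "logical"
  ),
  prototype(ncsovThreshold = NA_real_, mode = "ranking",
            discriminantScores = numeric(0), selected = integer(0),
            ldaProjection = matrix(0, 0, 0), fitted = FALSE)
)

setValidity("ReductionModel", function(object) {
  if (!object@fitted) return(TRUE)
  ev <- object@eigenvalues
  msg <- character()
  if (any(ev < -1e-10)) msg <- c(msg, "eigenvalues must be non-negative")
  if (is.unsorted(rev(ev), strictly = FALSE))
    msg <- c(msg, "eigenvalues must be sorted in descending order")
  if (ncol(object@axes) != length(ev))
    msg <- c(msg, "one eigenvalue per principal axis required")
  g <- crossprod(object@axes)
  if (max(abs(g - diag(ncol(g)))) > 1e-8)
    msg <- c(msg, "principal axes must be orthonormal")
  if (!object@mode %in% c("ranking", "strict"))
    msg <- c(msg, "mode must be 'ranking' or 'strict'")
  if (length(msg)) msg else TRUE
})

#' Extreme learning machine model
#'
#' Single-hidden-layer feed-forward network with randomly drawn hidden
#' parameters and analytically solved output weights: the output weights
#' are the minimum-norm least-squares (Moore-Penrose) solution of
#' H beta = T, where H is the hidden-layer activation matrix.
#'
#' @slot inputWeights L x d matrix of hidden-layer input weights.
#' @slot biases length-L hidden biases.
#' @slot activation activation name: "sigmoid", "tanh" or "relu".
#' @slot outputWeights L x C output weight matrix (empty until trained).
#' @slot classes class registry (column order of outputWeights).
#' @slot trained logical.
#' @export
setClass("ELMModel",
  representation(
    inputWeights = "matrix",
    biases = "numeric",
    activation = "character",
    outputWeights = "matrix",
    classes = "character",
    trained = "logical"
  ),
  prototype(outputWeights = matrix(0, 0, 0), classes = character(0),
            trained = FALSE)
)

setValidity("ELMModel", function(object) {
  msg <- character()
  if (nrow(object@inputWeights) != length(object@biases))
    msg <- c(msg, "one bias per hidden node required")
  if (!object@activation %in% c("sigmoid", "tanh", "relu"))
    msg <- c(msg, "unknown activation")
  if (object@trained) {
    if (nrow(object@outputWeights) != nrow(object@inputWeights))
      msg <- c(msg, "outputWeights rows must equal hidden node count")
    if (ncol(object@outputWeights) != length(object@classes))
      msg <- c(msg, "one output column per class required")
  }
  if (any(!is.finite(object@inputWeights)) || any(!is.finite(object@biases)))
    msg <- c(msg, "non-finite hidden parameters")
  if (length(msg)) msg else TRUE
})

#' Result of a pelican optimization run
#'
#' @slot bestPosition best solution found.
#' @slot bestFitness objective value at \code{bestPosition}.
#' @slot trajectory best-so-far fitness after each iteration (non-increasing
#'   by greedy acceptance).
#' @slot iterations number of iterations run.
#' @slot seed RNG seed used.
#' @slot variant \code{"POA"} or \code{"MOD-POA"}.
#' @export
setClass("PelicanResult",
  representation(
    bestPosition = "numeric",
    bestFitness = "numeric",
    trajectory = "numeric",
    iterations = "integer",
    seed = "integer",
    variant = "character"
  )
)

setValidity("PelicanResult", function(object) {
  tr <- object@trajectory
  if (length(tr) && any(diff(tr) > 0))
    return("best-so-far trajectory must be non-increasing")
  if (length(tr) && abs(object@bestFitness - min(tr)) > 0)
    return("bestFitness must equal the trajectory minimum")
  if (!object@variant %in% c("POA", "MOD-POA"))
    return("variant must be 'POA' or 'MOD-POA'")
  TRUE
})

#' End-to-end trained glaucoma screening pipeline
#'
#' Chains the curvelet feature extractor, the PCA+discriminant reduction
#' and the (optionally metaheuristically tuned) extreme learning machine.
#'
#' @slot curveletConfig the \linkS4class{CurveletConfig} used for features.
#' @slot scales integer scales whose wedges supply features.
#' @slot stats per-wedge statistic names.
#' @slot reduction fitted \linkS4class{ReductionModel}.
#' @slot elm trained \linkS4class{ELMModel}.
#' @slot optimization \linkS4class{PelicanResult} from hidden-parameter
#'   tuning, or NULL for a plain random-init ELM.
#' @export
setClass("GlaucomaPipeline",
  representation(
    curveletConfig = "CurveletConfig",
    scales = "integer",
    stats = "character",
    reduction = "ReductionModel",
    elm = "ELMModel",
    optimization = "ANY"
  )
)

#' Cross-validation evaluation report
#'
#' Per-(run, fold) confusion matrices with the glaucoma (positive) class
#' convention TP = glaucoma called glaucoma, plus derived accuracy,
#' sensitivity and specificity in percent.
#'
#' @slot table data.frame with columns run, fold, TP, FP, TN, FN,
#'   accuracy, sensitivity, specificity.
#' @slot positive name of the positive class.
#' @slot runs number of repeated CV runs.
#' @slot k folds per run.
#' @export
setClass("EvaluationReport",
  representation(
    table = "data.frame",
    positive = "character",
    runs = "integer",
    k = "integer"
  )
)

setValidity("EvaluationReport", function(object) {
  tab <- object@table
  need <- c("run", "fold", "TP", "FP", "TN", "FN",
            "accuracy", "sensitivity", "specificity")
  if (!all(need %in% names(tab)))
    return(paste("report table must contain:", paste(need, collapse = ", ")))
  if (nrow(tab) != object@runs * object@k)
    return("expected one row per (run, fold)")
  TRUE
})

#' A per-pixel saliency map
#'
#' @slot values real matrix, same size as the explained image.
#' @slot method "vanilla", "integrated" or "smoothgrad".
#' @slot targetClass class whose score was attributed.
#' @slot normalization record of any normalization applied ("none" or "max").
#' @export
setClass("SaliencyMap",
  representation(
    values = "matrix",
    method = "character",
    targetClass = "character",
    normalization = "character"
  ),
  prototype(normalization = "none")
)

setValidity("SaliencyMap", function(object) {
  if (any(!is.finite(object@values))) return("saliency values must be finite")
  if (!object@method %in% c("vanilla", "integrated", "smoothgrad"))
    return("unknown saliency method")
  TRUE
})
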