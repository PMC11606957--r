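# Gradient-based saliency for the trained pipeline. Every stage is
# differentiated exactly: the ELM analytically through its activation, the
# reduction through its linear map, and the curvelet feature stage through
# the tight-frame adjoint (the inverse transform applied to the
# coefficient-space cotangent).

#' Exact gradient of a class score with respect to the input pixels
#'
#' Chain rule through the trained pipeline: the class-score gradient with
#' respect to the hidden layer is the output-weight column; the activation
#' is differentiated analytically; the reduction is linear, so its
#' transpose maps the reduced-space gradient back to feature space; and
#' the per-wedge magnitude statistics are pulled back to pixel space
#' through the curvelet adjoint. Non-smooth points (zero coefficient
#' magnitude, the ReLU kink) use subgradient 0.
#'
#' @param model a trained \linkS4class{GlaucomaPipeline}.
#' @param image a \linkS4class{FundusImage} or square numeric matrix
#'   matching the pipeline's image size.
#' @param targetClass class whose score is differentiated; defaults to the
#'   model's predicted class for the image.
#' @return List with \code{gradient} (matrix, same size as the image),
#'   \code{score} (the class score) and \code{targetClass}.
#' @export
classScoreGradient <- function(model, image, targetClass = NULL) {
  stopifnot(is(model, "GlaucomaPipeline"))
  if (!model@elm@trained) stop("pipeline ELM is not trained")
  x <- asPixels(image)
  if (nrow(x) != model@curveletConfig@imageSize)
    stop("image size does not match the pipeline")
  co <- fdctForward(x, model@curveletConfig)
  f <- extractFeatures(co, model@scales, model@stats)
  z <- reduceFeatures(model@reduction, matrix(f, 1L))

  elm <- model@elm
  if (is.null(targetClass))
    targetClass <- elmPredict(elm, z)$labels[1L]
  ci <- match(targetClass, elm@classes)
  if (is.na(ci)) stop(sprintf("unknown class '%s'", targetClass))

  pre <- as.vector(elm@inputWeights %*% t(z)) + elm@biases
  act <- .activations[[elm@activation]]
  dact <- .activationGrads[[elm@activation]]
  score <- sum(act(pre) * elm@outputWeights[, ci])
  dPre <- elm@outputWeights[, ci] * dact(pre)          # d score / d pre
  dZ <- as.vector(crossprod(elm@inputWeights, dPre))   # d score / d z
  dF <- as.vector(crossprod(reductionMatrix(model@reduction), dZ))
  grad <- fdctInverse(featureCotangent(co, dF, model@scales, model@stats),
                      warnImaginary = FALSE)
  list(gradient = grad, score = score, targetClass = targetClass)
}

#' Vanilla gradient saliency
#'
#' Absolute value of the exact class-score gradient, optionally
#' max-normalized to [0, 1].
#'
#' @inheritParams classScoreGradient
#' @param normalize divide by the maximum absolute value (default FALSE).
#' @return A \linkS4class{SaliencyMap}.
#' @export
vanillaGradient <- function(model, image, targetClass = NULL,
                            normalize = FALSE) {
  g <- classScoreGradient(model, image, targetClass)
  v <- abs(g$gradient)
  if (normalize && max(v) > 0) v <- v / max(v)
  new("SaliencyMap", values = v, method = "vanilla",
      targetClass = g$targetClass,
      normalization = if (normalize) "max" else "none")
}

#' Integrated gradients saliency
#'
#' Attribution along the straight path from a baseline image to the input:
#' \code{(x - baseline)} times the path-mean gradient, integrated with the
#' midpoint Riemann rule. For enough steps the attributions satisfy the
#' completeness axiom: they sum to \code{score(x) - score(baseline)}.
#'
#' @inheritParams classScoreGradient
#' @param baseline baseline image (default: all-zero image).
#' @param steps number of midpoint integration steps (>= 1), default 50.
#' @return A \linkS4class{SaliencyMap} with signed attributions.
#' @export
integratedGradients <- function(model, image, targetClass = NULL,
                                baseline = NULL, steps = 50L) {
  if (steps < 1L) stop("steps must be >= 1")
  x <- asPixels(image)
  if (is.null(baseline)) baseline <- matrix(0, nrow(x), ncol(x))
  baseline <- asPixels(baseline)
  if (!all(dim(baseline) == dim(x)))
    stop("baseline shape must match the image")
  if (is.null(targetClass))
    targetClass <- predict(model@elm,
      reduceFeatures(model@reduction,
        matrix(extractFeatures(fdctForward(x, model@curveletConfig),
                               model@scales, model@stats), 1L)))[1L]
  acc <- matrix(0, nrow(x), ncol(x))
  for (s in seq_len(steps)) {
    alpha <- (s - 0.5) / steps
    g <- classScoreGradient(model, baseline + alpha * (x - baseline),
                            targetClass)
    acc <- acc + g$gradient
  }
  new("SaliencyMap", values = (x - baseline) * acc / steps,
      method = "integrated", targetClass = targetClass)
}

#' SmoothGrad saliency
#'
#' Mean vanilla-gradient map over Gaussian-perturbed copies of the input.
#'
#' @inheritParams classScoreGradient
#' @param sigma noise standard deviation (>= 0).
#' @param nSamples number of perturbed copies (>= 1).
#' @param seed integer seed for the noise draws.
#' @return A \linkS4class{SaliencyMap}.
#' @export
smoothGrad <- function(model, image, targetClass = NULL, sigma = 0.1,
                       nSamples = 25L, seed = 1L) {
  if (sigma < 0) stop("sigma must be >= 0")
  stopifnotScalarCount(nSamples, "nSamples")
  x <- asPixels(image)
  if (is.null(targetClass))
    targetClass <- classScoreGradient(model, x)$targetClass
  acc <- matrix(0, nrow(x), ncol(x))
  withSeed(seed, {
    for (s in seq_len(nSamples)) {
      noisy <- x + if (sigma > 0)
        matrix(rnorm(length(x), sd = sigma), nrow(x)) else 0
      acc <- acc + abs(classScoreGradient(model, noisy,
                                          targetClass)$gradient)
    }
  })
  new("SaliencyMap", values = acc / nSamples, method = "smoothgrad",
      targetClass = targetClass)
}

#' Render a saliency heatmap over the image
#'
#' Min-max normalizes the map to [0, 1], applies a cool-to-warm color
#' scale and alpha-blends it over the grayscale image; optionally writes
#' a PNG.
#'
#' @param map a \linkS4class{SaliencyMap}.
#' @param image the image it explains (same size).
#' @param alpha blend weight of the heatmap, in [0, 1].
#' @param file optional PNG output path.
#' @return Invisibly, the blended H x W x 3 RGB array.
#' @export
renderHeatmap <- function(map, image, alpha = 0.5, file = NULL) {
  stopifnot(is(map, "SaliencyMap"))
  x <- asPixels(image)
  v <- map@values
  if (!all(dim(v) == dim(x))) stop("map and image shapes must match")
  rng <- range(v)
  v01 <- if (diff(rng) > 0) (v - rng[1]) / diff(rng) else v * 0
  ramp <- grDevices::colorRamp(c("#313695", "#ffffbf", "#a50026"))
  cols <- ramp(as.vector(v01)) / 255
  out <- array(0, c(nrow(x), ncol(x), 3L))
  for (ch in 1:3)
    out[, , ch] <- (1 - alpha) * x + alpha * matrix(cols[, ch], nrow(x))
  if (!is.null(file)) png::writePNG(out, file)
  invisible(out)
}

setMethod("show", "SaliencyMap", function(object) {
  cat(sprintf("SaliencyMap (%s, class %s): %dx%d, range [%.3g, %.3g]\n",
              object@method, object@targetClass, nrow(object@values),
              ncol(object@values), min(object@values), max(object@values)))
})

#' @describeIn renderHeatmap Accessor for the raw saliency values.
#' @export
saliencyValues <- function(map) {
  stopifnot(is(map, "SaliencyMap"))
  map@values
}
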