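# Per-wedge statistics over coefficient magnitudes. Order of the feature
# vector is scale-major, wedge-minor, statistic-innermost.

.featureStats <- c("mean", "sd", "energy")

statOfWedge <- function(cw, stat) {
  a <- Mod(cw)
  switch(stat,
         mean = mean(a),
         sd = stats::sd(a),
         energy = sum(a^2),
         stop(sprintf("unknown statistic '%s'", stat)))
}

# Resolve and check the feature scale selection for a configuration.
resolveScales <- function(config, scales, strict = TRUE) {
  J <- config@nScales
  if (is.null(scales)) scales <- setdiff(seq_len(J), c(1L, J))
  scales <- as.integer(scales)
  if (any(scales < 1L | scales > J)) stop("requested scale does not exist")
  if (strict && any(scales %in% c(1L, J)))
    stop("the coarsest and finest scales are excluded from features ",
         "(set strict = FALSE to override)")
  if (!length(scales)) stop("no scales selected")
  sort(unique(scales))
}

#' Names of the curvelet feature columns
#'
#' @param config a \linkS4class{CurveletConfig}.
#' @param scales scales contributing features (default: all intermediate
#'   scales, i.e. excluding the coarsest and finest).
#' @param stats per-wedge statistics, a subset of
#'   \code{c("mean", "sd", "energy")}.
#' @param strict disallow the coarsest/finest scale (default TRUE).
#' @return Character vector like \code{"s2.w01.mean"}.
#' @export
featureNames <- function(config, scales = NULL, stats = .featureStats,
                         strict = TRUE) {
  scales <- resolveScales(config, scales, strict)
  stats <- match.arg(stats, .featureStats, several.ok = TRUE)
  unlist(lapply(scales, function(s)
    unlist(lapply(seq_len(wedgeCount(config, s)), function(w)
      sprintf("s%d.w%02d.%s", s, w, stats)))))
}

#' Extract a statistical feature vector from curvelet coefficients
#'
#' For each wedge at the selected scales the configured statistics of the
#' coefficient magnitudes are computed (default: mean magnitude, standard
#' deviation of magnitude, energy) and concatenated scale-major,
#' wedge-minor, statistic-innermost. The coarsest and finest scales are
#' excluded by default: they carry illumination offsets and noise rather
#' than the curve-like boundary structure of interest.
#'
#' @param coeffs a \linkS4class{CurveletCoefficients}.
#' @inheritParams featureNames
#' @return Named numeric feature vector.
#' @export
extractFeatures <- function(coeffs, scales = NULL, stats = .featureStats,
                            strict = TRUE) {
  stopifnot(is(coeffs, "CurveletCoefficients"))
  config <- coeffs@config
  scales <- resolveScales(config, scales, strict)
  stats <- match.arg(stats, .featureStats, several.ok = TRUE)
  v <- unlist(lapply(scales, function(s)
    unlist(lapply(coeffs@wedges[[s]], function(cw)
      vapply(stats, function(st) statOfWedge(cw, st), 0)))))
  names(v) <- featureNames(config, scales, stats, strict)
  if (any(!is.finite(v))) stop("non-finite feature value")
  v
}

#' Extract curvelet features for a list of images
#'
#' @param images list of \linkS4class{FundusImage} objects or square
#'   numeric matrices, all the same size.
#' @param config a \linkS4class{CurveletConfig}.
#' @inheritParams featureNames
#' @return Numeric matrix, one row per image, with the column registry of
#'   \code{\link{featureNames}} (also for an empty input list).
#' @export
batchExtract <- function(images, config = NULL, scales = NULL,
                         stats = .featureStats, strict = TRUE) {
  if (length(images)) {
    sizes <- vapply(images, function(im) nrow(asPixels(im)), 0L)
    if (length(unique(sizes)) != 1L)
      stop("all images must have the same size")
    if (is.null(config)) config <- curveletConfig(sizes[1])
    if (sizes[1] != config@imageSize)
      stop("image size does not match the curvelet configuration")
  } else if (is.null(config)) {
    stop("a configuration is required for an empty image list")
  }
  cols <- featureNames(config, scales, stats, strict)
  X <- matrix(NA_real_, length(images), length(cols),
              dimnames = list(NULL, cols))
  for (i in seq_along(images))
    X[i, ] <- extractFeatures(fdctForward(asPixels(images[[i]]), config),
                              scales, stats, strict)
  X
}

# Backward pass of extractFeatures: given d(loss)/d(feature) weights,
# return the coefficient-space cotangent (complex arrays, zero off the
# selected scales). Convention: for G real and c = x + iy a coefficient,
# the cotangent entry is dG/dx + i dG/dy; the pixel gradient is then
# fdctInverse of the cotangent (the transform is a tight frame, so the
# adjoint equals the inverse). Non-smooth points of |.| at zero magnitude
# take subgradient 0.
featureCotangent <- function(coeffs, weights, scales = NULL,
                             stats = .featureStats, strict = TRUE) {
  config <- coeffs@config
  scales <- resolveScales(config, scales, strict)
  stats <- match.arg(stats, .featureStats, several.ok = TRUE)
  cot <- lapply(coeffs@wedges, function(scale)
    lapply(scale, function(w) matrix(0i, nrow(w), ncol(w))))
  idx <- 0L
  for (s in scales) {
    for (w in seq_along(coeffs@wedges[[s]])) {
      cw <- coeffs@wedges[[s]][[w]]
      a <- Mod(cw)
      unit <- cw
      nz <- a > 0
      unit[nz] <- cw[nz] / a[nz]
      unit[!nz] <- 0i
      nK <- length(a)
      g <- matrix(0i, nrow(cw), ncol(cw))
      for (st in stats) {
        idx <- idx + 1L
        wt <- weights[idx]
        if (wt == 0) next
        g <- g + switch(st,
          mean = wt / nK * unit,
          sd = {
            m <- mean(a); sdev <- stats::sd(a)
            if (sdev > 0) wt * ((a - m) / ((nK - 1) * sdev)) * unit
            else 0i * unit
          },
          energy = wt * 2 * cw)
      }
      cot[[s]][[w]] <- g
    }
  }
  if (idx != length(weights)) stop("weight vector length mismatch")
  new("CurveletCoefficients", wedges = cot, config = config)
}
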