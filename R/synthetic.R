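#' Construct synthetic fundus generator settings
#'
#' The generator emulates the manually cropped 128x128 optic-nerve-head
#' regions of interest used in fundus-based glaucoma screening: a bright
#' elliptical optic disc (intensity about 0.75) on a darker background
#' (about 0.35), a brighter concentric cup (about 0.95) whose radius is the
#' cup-to-disc ratio (CDR) times the disc radius, dark curvilinear vessels,
#' a smooth illumination gradient and additive Gaussian noise. The class
#' signal is purely the CDR: healthy images default to CDR 0.3, glaucoma
#' images to 0.7.
#'
#' @param imageSize pixels per side (even, >= 32). Default 128.
#' @param discRadiusRange range of the disc semi-major axis in pixels.
#' @param cdrHealthy,cdrGlaucoma class-wise cup-to-disc ratios, with
#'   \code{0 < cdrHealthy < cdrGlaucoma < 1}.
#' @param vesselCount number of vessel strokes per image.
#' @param noiseSigma std. dev. of additive Gaussian noise (gray levels).
#' @param seed default seed recorded in the spec.
#' @return A \linkS4class{SyntheticSpec}.
#' @examples
#' spec <- syntheticSpec()
#' img <- generateFundus(spec, "glaucoma", seed = 1)
#' range(pixels(img))
#' @export
syntheticSpec <- function(imageSize = 128L, discRadiusRange = c(24, 28),
                          cdrHealthy = 0.3, cdrGlaucoma = 0.7,
                          vesselCount = 4L, noiseSigma = 0.02, seed = 1L) {
  new("SyntheticSpec", imageSize = as.integer(imageSize),
      discRadiusRange = as.numeric(discRadiusRange),
      cdrHealthy = cdrHealthy, cdrGlaucoma = cdrGlaucoma,
      vesselCount = as.integer(vesselCount), noiseSigma = noiseSigma,
      seed = as.integer(seed))
}

# Fill pixels under an elliptical mask; returns the logical mask.
ellipseMask <- function(n, cx, cy, a, b, phi) {
  xs <- matrix(rep(seq_len(n), each = n), n, n)   # column index
  ys <- matrix(rep(seq_len(n), times = n), n, n)  # row index
  dx <- xs - cx; dy <- ys - cy
  u <- cos(phi) * dx + sin(phi) * dy
  v <- -sin(phi) * dx + cos(phi) * dy
  (u / a)^2 + (v / b)^2 <= 1
}

# Blend a quadratic Bezier stroke of the given width into img. The stroke
# is rendered from the distance to the sampled curve with a 1-px soft
# edge: hard pixel stamping would add aliasing energy across all curvelet
# scales and swamp the anatomical boundaries the features target.
drawStroke <- function(img, p0, p1, p2, width, value) {
  n <- nrow(img)
  ts <- seq(0, 1, length.out = 3L * n)
  bx <- (1 - ts)^2 * p0[1] + 2 * (1 - ts) * ts * p1[1] + ts^2 * p2[1]
  by <- (1 - ts)^2 * p0[2] + 2 * (1 - ts) * ts * p1[2] + ts^2 * p2[2]
  D2 <- matrix(Inf, n, n)
  hw <- as.integer(ceiling(width / 2 + 2))
  for (q in seq_along(ts)) {
    r0 <- max(1L, round(by[q]) - hw); r1 <- min(n, round(by[q]) + hw)
    c0 <- max(1L, round(bx[q]) - hw); c1 <- min(n, round(bx[q]) + hw)
    if (r0 > r1 || c0 > c1) next
    rr <- r0:r1; cc <- c0:c1
    D2[rr, cc] <- pmin(D2[rr, cc], outer((rr - by[q])^2, (cc - bx[q])^2, "+"))
  }
  wgt <- pmin(pmax(width / 2 + 0.5 - sqrt(D2), 0), 1)
  img + (value - img) * wgt
}

#' Generate one synthetic fundus image
#'
#' Deterministic for a fixed seed. All geometric draws are independent of
#' the label, so a healthy and a glaucoma image generated with the same
#' seed share disc geometry, vessels, illumination and noise and differ
#' only in the cup radius.
#'
#' @param spec a \linkS4class{SyntheticSpec}.
#' @param label \code{"healthy"} or \code{"glaucoma"}.
#' @param seed integer seed.
#' @return A \linkS4class{FundusImage} carrying the generator's disc and
#'   cup masks (useful as ground truth for saliency checks).
#' @export
generateFundus <- function(spec, label, seed = spec@seed) {
  validObject(spec)
  if (length(label) != 1L || !label %in% c("healthy", "glaucoma"))
    stop("label must be 'healthy' or 'glaucoma'")
  n <- spec@imageSize
  withSeed(seed, {
    # smooth illumination gradient over a flat background
    theta <- runif(1, 0, 2 * pi)
    amp <- runif(1, 0.03, 0.08)
    xs <- matrix(rep(seq_len(n), each = n), n, n) / n - 0.5
    ys <- matrix(rep(seq_len(n), times = n), n, n) / n - 0.5
    img <- 0.35 + amp * (cos(theta) * xs + sin(theta) * ys)

    # disc geometry: centered with jitter, mild eccentricity and rotation
    cx <- n / 2 + runif(1, -n / 16, n / 16)
    cy <- n / 2 + runif(1, -n / 16, n / 16)
    a <- runif(1, spec@discRadiusRange[1], spec@discRadiusRange[2])
    b <- a * runif(1, 0.85, 1)
    phi <- runif(1, 0, pi)
    cdr <- if (label == "glaucoma") spec@cdrGlaucoma else spec@cdrHealthy
    disc <- ellipseMask(n, cx, cy, a, b, phi)
    # cup offset drawn before use so the draw order is label-independent
    off <- runif(2, -0.08, 0.08) * a * (1 - cdr)
    cup <- ellipseMask(n, cx + off[1], cy + off[2], cdr * a, cdr * b, phi)
    cup <- cup & disc
    img[disc] <- 0.75
    img[cup] <- 0.95

    # vessels: quadratic Bezier strokes leaving the disc along the
    # superior/inferior arcades (alternating up/down, small angular
    # jitter), as retinal vessels do in an ONH-centered crop
    if (spec@vesselCount > 0L) {
      for (v in seq_len(spec@vesselCount)) {
        base <- if (v %% 2L == 0L) pi / 2 else -pi / 2
        ang <- base + runif(1, -0.15, 0.15)
        p0 <- c(cx, cy) + runif(2, -a / 8, a / 8)
        p2 <- p0 + 0.75 * n * c(cos(ang), sin(ang))
        p1 <- (p0 + p2) / 2 + runif(2, -n / 32, n / 32)
        w <- runif(1, 1.5, 2.5)
        img <- drawStroke(img, p0, p1, p2, w, 0.2)
      }
    }

    img <- img + rnorm(n * n, sd = spec@noiseSigma)
    img <- pmin(pmax(img, 0), 1)
    new("FundusImage", pixels = img, label = label,
        discMask = disc, cupMask = cup)
  })
}

#' Generate a labeled synthetic dataset
#'
#' Per-image seeds are derived deterministically from the master seed, so
#' the dataset is reproducible image-by-image.
#'
#' @param spec a \linkS4class{SyntheticSpec}.
#' @param nHealthy,nGlaucoma class counts (>= 0).
#' @param seed master seed.
#' @return List with \code{images} (list of \linkS4class{FundusImage},
#'   healthy first) and \code{labels} (character vector).
#' @export
generateDataset <- function(spec, nHealthy, nGlaucoma, seed = spec@seed) {
  if (nHealthy < 0 || nGlaucoma < 0) stop("counts must be >= 0")
  nH <- as.integer(nHealthy); nG <- as.integer(nGlaucoma)
  labels <- c(rep("healthy", nH), rep("glaucoma", nG))
  seeds <- deriveSeeds(seed, nH + nG)
  images <- vector("list", nH + nG)
  for (i in seq_along(images))
    images[[i]] <- generateFundus(spec, labels[i], seed = seeds[i])
  list(images = images, labels = labels)
}

#' Generate two labeled Gaussian feature clouds
#'
#' A classifier-level fixture that bypasses the image stage: two classes
#' with unit within-class covariance whose means are \code{separation}
#' apart along a random unit direction.
#'
#' @param nPerClass samples per class.
#' @param dim feature dimension.
#' @param separation distance between class means (>= 0).
#' @param seed integer seed.
#' @return List with \code{X} (2*nPerClass x dim matrix), \code{labels}
#'   (character: "healthy" then "glaucoma") and \code{direction} (the true
#'   unit separation direction).
#' @export
generateFeatureClouds <- function(nPerClass, dim, separation, seed = 1L) {
  stopifnotScalarCount(nPerClass, "nPerClass")
  stopifnotScalarCount(dim, "dim")
  if (separation < 0) stop("separation must be >= 0")
  withSeed(seed, {
    u <- rnorm(dim)
    u <- u / sqrt(sum(u^2))
    X0 <- matrix(rnorm(nPerClass * dim), nPerClass, dim)
    X1 <- matrix(rnorm(nPerClass * dim), nPerClass, dim) +
      matrix(separation * u, nPerClass, dim, byrow = TRUE)
    X <- rbind(X0, X1)
    colnames(X) <- paste0("f", seq_len(dim))
    list(X = X,
         labels = c(rep("healthy", nPerClass), rep("glaucoma", nPerClass)),
         direction = u)
  })
}

#' @describeIn syntheticSpec Accessor for the pixel matrix of a
#'   \linkS4class{FundusImage}.
#' @param x a \linkS4class{FundusImage}.
#' @export
pixels <- function(x) asPixels(x)

#' @describeIn syntheticSpec Accessor for the generator's disc mask.
#' @export
discMask <- function(x) {
  stopifnot(is(x, "FundusImage"))
  x@discMask
}

#' @describeIn syntheticSpec Accessor for the generator's cup mask.
#' @export
cupMask <- function(x) {
  stopifnot(is(x, "FundusImage"))
  x@cupMask
}

setMethod("show", "FundusImage", function(object) {
  cat(sprintf("FundusImage %dx%d label=%s mean=%.3f\n",
              nrow(object@pixels), ncol(object@pixels),
              if (nzchar(object@label)) object@label else "<none>",
              mean(object@pixels)))
})

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf(
    "SyntheticSpec: %dpx, disc radius [%g,%g], CDR healthy %.2f / glaucoma %.2f, %d vessels, noise sd %.3f\n",
    object@imageSize, object@discRadiusRange[1], object@discRadiusRange[2],
    object@cdrHealthy, object@cdrGlaucoma, object@vesselCount,
    object@noiseSigma))
})
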