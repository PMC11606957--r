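#' Number of curvelet decomposition scales for an image size
#'
#' The decomposition depth is \code{ceiling(log2(min(rows, cols)) - 3)}:
#' a 128x128 image is decomposed into 4 scales.
#'
#' @param rows,cols image dimensions in pixels (each >= 16).
#' @return Integer scale count (>= 2).
#' @examples
#' scaleCount(128, 128)  # 4
#' scaleCount(256, 512)  # 5
#' @export
scaleCount <- function(rows, cols) {
  if (rows < 16 || cols < 16) stop("image must be at least 16x16")
  s <- as.integer(ceiling(log2(min(rows, cols)) - 3))
  if (s < 2L)
    stop("image too small for a multiscale decomposition (need >= 2 scales)")
  s
}

#' Construct a curvelet transform configuration
#'
#' @param imageSize side length of the square input, even and >= 16.
#' @param nScales number of scales; defaults to
#'   \code{scaleCount(imageSize, imageSize)}.
#' @param nAnglesCoarse angular wedges at the second-coarsest scale
#'   (8, 16 or 32); wedge counts double every second scale step towards
#'   finer scales (parabolic scaling). Default 16.
#' @return A \linkS4class{CurveletConfig}.
#' @export
curveletConfig <- function(imageSize = 128L,
                           nScales = scaleCount(imageSize, imageSize),
                           nAnglesCoarse = 16L) {
  new("CurveletConfig", imageSize = as.integer(imageSize),
      nScales = as.integer(nScales), nAnglesCoarse = as.integer(nAnglesCoarse))
}

# Number of angular wedges at scale s (1 for the isotropic end scales).
wedgeCount <- function(config, s) {
  J <- config@nScales
  if (s == 1L || s == J) return(1L)
  config@nAnglesCoarse * 2L^as.integer(ceiling((s - 2L) / 2))
}

# CurveLab's C-infinity transition profile pair on [0,1]:
# fall(0)=1 -> fall(1)=0 and rise = sqrt(1 - fall^2), with
# fall(x)^2 + fall(1-x)^2 = 1 (squared partition of unity across the joint).
meyerFall <- function(x) {
  fall <- ifelse(x <= 0, 1, 0)
  rise <- ifelse(x >= 1, 1, 0)
  mid <- x > 0 & x < 1
  if (any(mid)) {
    xm <- x[mid]
    f <- exp(1 - 1 / (1 - exp(1 - 1 / xm)))       # falls 1 -> 0
    r <- exp(1 - 1 / (1 - exp(1 - 1 / (1 - xm)))) # rises 0 -> 1
    nrm <- sqrt(f^2 + r^2)
    fall[mid] <- f / nrm
    rise[mid] <- r / nrm
  }
  list(fall = fall, rise = rise)
}

# Radial lowpass with unit plateau for t <= a and smooth decay on [a, 2a].
radialLowpass <- function(t, a) meyerFall((t - a) / a)$fall

# fftshift / inverse for even side lengths (DC moves to index n/2 + 1).
fftshift2 <- function(x) {
  n1 <- nrow(x); n2 <- ncol(x)
  x[c((n1 / 2 + 1):n1, 1:(n1 / 2)), c((n2 / 2 + 1):n2, 1:(n2 / 2))]
}

# Smallest divisor of n that is >= m (wrap rectangle side). Using a divisor
# keeps the wedge sampling lattice nested in the pixel grid, so integer
# image shifts act on wrapped coefficients as exact cyclic permutations.
wrapSize <- function(m, n) {
  d <- which(n %% seq_len(n) == 0)
  min(d[d >= m])
}

# package-local cache of transform plans, keyed by configuration
.planCache <- new.env(parent = emptyenv())

# Build (or fetch) the full wedge plan for a configuration: cropped
# frequency windows, support boxes, wrap rectangle sizes and index maps.
curveletPlan <- function(config) {
  validObject(config)
  key <- paste(config@imageSize, config@nScales, config@nAnglesCoarse,
               sep = "x")
  if (!is.null(.planCache[[key]])) return(.planCache[[key]])

  n <- config@imageSize
  J <- config@nScales
  kv <- seq_len(n) - 1 - n / 2                    # frequency per shifted index
  K1 <- matrix(kv, n, n)                          # row frequency
  K2 <- matrix(kv, n, n, byrow = TRUE)            # column frequency
  Tn <- sqrt(K1^2 + K2^2) / (n / 2)               # normalized radius
  Ang <- atan2(K2, K1)                            # polar angle

  # radial partition: lowpass cutoffs a_s = 2^(s - J), transition [a, 2a]
  lp <- vector("list", J - 1L)
  for (s in seq_len(J - 1L)) lp[[s]] <- radialLowpass(Tn, 2^(s - J))
  radial <- vector("list", J)
  radial[[1L]] <- lp[[1L]]
  if (J > 2L)
    for (s in 2:(J - 1L))
      radial[[s]] <- sqrt(pmax(lp[[s]]^2 - lp[[s - 1L]]^2, 0))
  radial[[J]] <- sqrt(pmax(1 - lp[[J - 1L]]^2, 0))

  planScale <- function(win) {
    sup <- which(win > 1e-15, arr.ind = TRUE)
    r1 <- min(sup[, 1]); r2 <- max(sup[, 1])
    c1 <- min(sup[, 2]); c2 <- max(sup[, 2])
    rows <- r1:r2; cols <- c1:c2
    m1 <- wrapSize(length(rows), n); m2 <- wrapSize(length(cols), n)
    list(rows = rows, cols = cols,
         win = win[rows, cols, drop = FALSE],
         m1 = m1, m2 = m2,
         rmap = ((kv[rows] %% m1) + m1) %% m1 + 1L,
         cmap = ((kv[cols] %% m2) + m2) %% m2 + 1L)
  }

  wedges <- vector("list", J)
  for (s in seq_len(J)) {
    nw <- wedgeCount(config, s)
    if (nw == 1L) {
      wedges[[s]] <- list(planScale(radial[[s]]))
    } else {
      u <- Ang / (2 * pi) * nw                    # angular coordinate, units
      ws <- vector("list", nw)
      for (w in seq_len(nw)) {
        d <- abs(((u - (w - 1) + nw / 2) %% nw) - nw / 2)
        angWin <- meyerFall(d)$fall               # transition over one unit
        ws[[w]] <- planScale(radial[[s]] * angWin)
      }
      wedges[[s]] <- ws
    }
  }
  plan <- list(config = config, wedges = wedges)
  .planCache[[key]] <- plan
  plan
}

#' Forward fast discrete curvelet transform with wrapping
#'
#' Implements the four wrapping steps: a 2-D FFT of the image; the product
#' with a smooth frequency window for every scale/angle wedge; re-indexing
#' (wrapping) of each windowed wedge about the origin into a rectangle; and
#' an inverse 2-D FFT per wedge. The window family is a Meyer-type radial
#' partition combined with smooth angular wedges whose squared magnitudes
#' sum to one at every frequency, so the transform is a tight frame: the
#' total squared coefficient magnitude equals the image energy, and
#' \code{\link{fdctInverse}} reconstructs the image exactly (to numerical
#' precision).
#'
#' @param image a \linkS4class{FundusImage} or a square numeric matrix.
#' @param config a \linkS4class{CurveletConfig}; must match the image size.
#' @return A \linkS4class{CurveletCoefficients}.
#' @examples
#' img <- matrix(rnorm(64^2), 64, 64)
#' cfg <- curveletConfig(64)
#' co <- fdctForward(img, cfg)
#' rec <- fdctInverse(co)
#' max(abs(rec - img))
#' @export
fdctForward <- function(image, config = curveletConfig(nrow(asPixels(image)))) {
  x <- asPixels(image)
  if (nrow(x) != ncol(x)) stop("image must be square")
  if (nrow(x) != config@imageSize)
    stop("image size does not match the curvelet configuration")
  plan <- curveletPlan(config)
  n <- config@imageSize
  Xs <- fftshift2(stats::fft(x))
  out <- lapply(plan$wedges, function(scale) {
    lapply(scale, function(wd) {
      Y <- Xs[wd$rows, wd$cols, drop = FALSE] * wd$win
      W <- matrix(0i, wd$m1, wd$m2)
      W[wd$rmap, wd$cmap] <- Y
      stats::fft(W, inverse = TRUE) / (n * sqrt(wd$m1 * wd$m2))
    })
  })
  new("CurveletCoefficients", wedges = out, config = config)
}

#' Inverse (adjoint) fast discrete curvelet transform
#'
#' Unwraps each wedge back to its frequency support, multiplies by the
#' conjugate window and sums; because the windows form a squared partition
#' of unity, this adjoint is an exact inverse of \code{\link{fdctForward}}.
#' A residual imaginary part above 1e-9 (relative) triggers a warning
#' before it is discarded.
#'
#' @param coeffs a \linkS4class{CurveletCoefficients}.
#' @param warnImaginary warn when the discarded imaginary residue is large.
#'   Leave TRUE when reconstructing images; the residue check is
#'   meaningless when the adjoint is applied to arbitrary cotangent arrays
#'   (as the saliency code does).
#' @return A real matrix of the configured image size.
#' @export
fdctInverse <- function(coeffs, warnImaginary = TRUE) {
  stopifnot(is(coeffs, "CurveletCoefficients"))
  config <- coeffs@config
  plan <- curveletPlan(config)
  n <- config@imageSize
  if (length(coeffs@wedges) != length(plan$wedges))
    stop("coefficient structure does not match the configuration")
  Xs <- matrix(0i, n, n)
  for (s in seq_along(plan$wedges)) {
    ps <- plan$wedges[[s]]; cs <- coeffs@wedges[[s]]
    if (length(cs) != length(ps))
      stop("coefficient structure does not match the configuration")
    for (w in seq_along(ps)) {
      wd <- ps[[w]]
      cw <- cs[[w]]
      if (nrow(cw) != wd$m1 || ncol(cw) != wd$m2)
        stop("wedge array size does not match the configuration")
      Fw <- stats::fft(cw) * n / sqrt(wd$m1 * wd$m2)
      Xs[wd$rows, wd$cols] <- Xs[wd$rows, wd$cols] +
        Conj(wd$win) * Fw[wd$rmap, wd$cmap]
    }
  }
  z <- stats::fft(fftshift2(Xs), inverse = TRUE) / (n * n)
  rel <- max(abs(Im(z))) / max(max(abs(Re(z))), .Machine$double.eps)
  if (warnImaginary && rel > 1e-9)
    warning(sprintf("discarding imaginary residue (relative %.2e)", rel))
  Re(z)
}

#' Total coefficient energy
#'
#' Sum of squared coefficient magnitudes over all scales and wedges; equals
#' the image energy (tight frame).
#'
#' @param coeffs a \linkS4class{CurveletCoefficients}.
#' @return Numeric scalar.
#' @export
coefficientEnergy <- function(coeffs) {
  stopifnot(is(coeffs, "CurveletCoefficients"))
  sum(vapply(coeffs@wedges, function(scale)
    sum(vapply(scale, function(w) sum(Mod(w)^2), 0)), 0))
}

setMethod("show", "CurveletCoefficients", function(object) {
  counts <- vapply(object@wedges, length, 0L)
  cat(sprintf("CurveletCoefficients: %d scales (wedges: %s), image %dpx\n",
              object@config@nScales, paste(counts, collapse = "/"),
              object@config@imageSize))
})

setMethod("show", "CurveletConfig", function(object) {
  cat(sprintf("CurveletConfig: %dpx, %d scales, %d coarse angles\n",
              object@imageSize, object@nScales, object@nAnglesCoarse))
})
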