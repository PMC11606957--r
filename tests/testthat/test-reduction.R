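test_that("fitPCA recovers the expected spectra", {
  # collinear points: all variance on the first axis
  t <- seq(-2, 2, length.out = 11)
  X <- cbind(3 * t, -4 * t)
  m <- fitPCA(X)
  expect_lt(m@eigenvalues[2], 1e-12)
  expect_equal(m@eigenvalues[1] / sum(m@eigenvalues), 1, tolerance = 1e-12)

  # isotropic cloud: eigenvalues within 10% of one another
  set.seed(8)
  Xi <- matrix(rnorm(5000 * 4), 5000, 4)
  mi <- fitPCA(Xi)
  expect_lt(max(mi@eigenvalues) / min(mi@eigenvalues), 1.1)

  expect_error(fitPCA(matrix(1, 1, 3)), "2 samples")
  expect_error(fitPCA(matrix(1, 5, 3)), "zero variance")
})

test_that("fitPCA agrees with an independent SVD oracle", {
  set.seed(11)
  X <- matrix(rnorm(40 * 6), 40, 6)
  m <- fitPCA(X)
  sv <- svd(scale(X, scale = FALSE))
  expect_equal(m@eigenvalues, sv$d^2 / (nrow(X) - 1), tolerance = 1e-10)
  for (j in 1:6)
    expect_lt(min(max(abs(m@axes[, j] - sv$v[, j])),
                  max(abs(m@axes[, j] + sv$v[, j]))), 1e-8)
  # orthonormality and deterministic sign convention
  expect_equal(crossprod(m@axes), diag(6), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_true(all(apply(m@axes, 2, function(v) v[which.max(abs(v))]) > 0))
})

test_that("ncsov matches its definition and boundary behavior", {
  expect_equal(ncsov(c(4, 3, 2, 1)), c(0.4, 0.7, 0.9, 1.0))
  expect_identical(ncsov(5), 1)
  set.seed(2)
  ev <- sort(runif(17), decreasing = TRUE)
  expect_equal(ncsov(ev), cumsum(ev) / sum(ev), tolerance = 1e-12)
  out <- ncsov(ev)
  expect_true(all(diff(out) >= 0))
  expect_identical(out[length(out)], 1)
  expect_error(ncsov(c(0, 0)), "zero")
  expect_error(ncsov(c(1, 2)), "descending")
  expect_error(ncsov(numeric(0)), "non-empty")
})

test_that("selectByNCSOV picks the first index reaching the threshold", {
  expect_identical(selectByNCSOV(c(4, 3, 2, 1), 0.65), 2L)
  expect_identical(selectByNCSOV(c(4, 3, 2, 1), 1.0), 4L)
  expect_identical(selectByNCSOV(c(10, 0, 0), 0.5), 1L)
  expect_error(selectByNCSOV(c(1), 0), "threshold")
})

test_that("the discriminant stage ranks and projects as advertised", {
  # two well-separated classes along x: that axis wins the Fisher score
  z <- generateFeatureClouds(100, 10, 6, seed = 1)
  pm <- fitPCA(z$X, 10)
  Z <- pcaTransform(pm, z$X)
  m <- fitDiscriminant(pm, Z, z$labels, nKeep = 3, mode = "ranking")
  align <- abs(as.vector(crossprod(m@axes, z$direction)))
  expect_identical(which.max(m@discriminantScores), which.max(align))
  expect_length(m@selected, 3L)

  # brute-force Fisher ratio oracle
  y <- z$labels
  for (j in c(1L, which.max(align))) {
    v <- Z[, j]
    mh <- mean(v[y == "healthy"]); mg <- mean(v[y == "glaucoma"])
    gm <- mean(v)
    sb <- sum(y == "healthy") * (mh - gm)^2 + sum(y == "glaucoma") * (mg - gm)^2
    sw <- sum((v[y == "healthy"] - mh)^2) + sum((v[y == "glaucoma"] - mg)^2)
    expect_equal(m@discriminantScores[j], sb / sw, tolerance = 1e-10)
  }

  # strict binary LDA yields exactly one output dimension
  ms <- fitDiscriminant(pm, Z, z$labels, mode = "strict")
  expect_identical(ncol(ms@ldaProjection), 1L)
  expect_identical(ncol(reduceFeatures(ms, z$X)), 1L)

  # singular within-class scatter triggers the small-sample-size guidance
  Xs <- matrix(rnorm(4 * 6), 4, 6)
  ps <- fitPCA(Xs, 3)
  Zs <- pcaTransform(ps, Xs)
  Zs[, 3] <- Zs[, 1]  # force rank deficiency
  psz <- ps; psz@axes <- ps@axes
  expect_error(fitDiscriminant(ps, Zs, c("a", "a", "b", "b"),
                               mode = "strict"), "ranking")
})

test_that("reduceFeatures is centered, affine and variance-preserving", {
  z <- generateFeatureClouds(40, 8, 4, seed = 3)
  m <- fitReduction(z$X, z$labels, pcaComponents = 5, nKeep = 5,
                    mode = "ranking")
  # the training mean maps to the origin before the discriminant stage
  expect_lt(max(abs(pcaTransform(m, colMeans(z$X)))), 1e-10)

  # affine in the input
  x1 <- z$X[1, ]; x2 <- z$X[2, ]; lam <- 0.3
  lhs <- reduceFeatures(m, lam * x1 + (1 - lam) * x2)
  rhs <- lam * reduceFeatures(m, x1) + (1 - lam) * reduceFeatures(m, x2)
  expect_equal(lhs, rhs, tolerance = 1e-10)

  # total transformed variance equals the sum of the selected eigenvalues
  Zr <- reduceFeatures(m, z$X)
  expect_equal(sum(apply(Zr, 2, var)), sum(m@eigenvalues[m@selected]),
               tolerance = 1e-8)

  # reconstruction error from MA components = discarded eigenvalue mass
  full <- fitPCA(z$X)
  ma <- 5L
  proj <- pcaTransform(full, z$X)[, seq_len(ma), drop = FALSE]
  back <- proj %*% t(full@axes[, seq_len(ma), drop = FALSE])
  resid <- scale(z$X, scale = FALSE) - back
  expect_equal(sum(resid^2) / (nrow(z$X) - 1),
               sum(full@eigenvalues[-seq_len(ma)]), tolerance = 1e-8)

  um <- fitPCA(z$X, 4)
  expect_error(reduceFeatures(um, z$X), "not fitted")
  expect_error(reduceFeatures(m, z$X[, 1:5]), "dimension")
})

test_that("reduction models survive a JSON round trip", {
  z <- generateFeatureClouds(25, 6, 5, seed = 9)
  m <- fitReduction(z$X, z$labels, pcaComponents = 4, nKeep = 2,
                    mode = "ranking")
  f <- tempfile(fileext = ".json")
  writeReduction(m, f)
  m2 <- readReduction(f)
  expect_equal(reduceFeatures(m2, z$X), reduceFeatures(m, z$X),
               tolerance = 1e-12)
  d <- reducedDims(m)
  expect_identical(d[["MA"]], 4L)
  expect_identical(d[["LD"]], 2L)
})
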