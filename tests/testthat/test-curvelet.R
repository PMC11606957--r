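test_that("scale count follows the ceiling-log rule", {
  expect_identical(scaleCount(128, 128), 4L)
  expect_identical(scaleCount(64, 64), 3L)
  expect_identical(scaleCount(256, 512), 5L)
  # brute-force check across the full supported size range
  for (n in seq(17L, 1024L, by = 31L))
    expect_identical(scaleCount(n, n), as.integer(ceiling(log2(n) - 3)))
  expect_error(scaleCount(8, 128), "at least")
  expect_error(scaleCount(16, 16), "too small")
})

test_that("forward transform is linear and annihilates the zero image", {
  cfg <- curveletConfig(64)
  co0 <- fdctForward(matrix(0, 64, 64), cfg)
  expect_true(all(vapply(unlist(co0@wedges, recursive = FALSE),
                         function(w) all(w == 0i), TRUE)))
  x <- randImage(64, seed = 3)
  ca <- fdctForward(3.5 * x, cfg)
  cb <- fdctForward(x, cfg)
  for (s in seq_along(ca@wedges))
    for (w in seq_along(ca@wedges[[s]]))
      expect_lt(max(Mod(ca@wedges[[s]][[w]] - 3.5 * cb@wedges[[s]][[w]])),
                1e-10)
})

test_that("the transform is a tight frame (Parseval) with perfect reconstruction", {
  cfg <- curveletConfig(128)
  for (s in 1:5) {
    x <- randImage(128, seed = s)
    co <- fdctForward(x, cfg)
    expect_lt(abs(coefficientEnergy(co) / sum(x^2) - 1), 1e-6)
    rec <- fdctInverse(co)
    expect_lt(sqrt(sum((rec - x)^2) / sum(x^2)), 1e-6)
  }
})

test_that("an impulse survives the round trip with its peak in place", {
  x <- matrix(0, 64, 64); x[33, 33] <- 1
  rec <- fdctInverse(fdctForward(x, curveletConfig(64)))
  expect_identical(which.max(abs(rec)), which.max(x))
  expect_lt(max(abs(rec - x)), 1e-10)
  rec0 <- fdctInverse(fdctForward(matrix(0, 64, 64), curveletConfig(64)))
  expect_true(all(rec0 == 0))
})

test_that("coarse-scale coefficients shift with the image (covariance)", {
  cfg <- curveletConfig(128)
  x <- randImage(128, seed = 9)
  c1 <- fdctForward(x, cfg)@wedges[[1]][[1]]
  m1 <- nrow(c1)
  step <- 128L / m1                       # coarse wedge grid spacing
  xs <- x[c((128 - step + 1):128, 1:(128 - step)), ]  # translate rows
  c2 <- fdctForward(xs, cfg)@wedges[[1]][[1]]
  # translation by one grid step is a cyclic permutation of the rows
  perm <- c1[c(m1, 1:(m1 - 1)), ]
  expect_lt(max(Mod(c2 - perm)) / max(Mod(c1)), 1e-3)
})

test_that("transform rejects mismatched inputs", {
  cfg <- curveletConfig(128)
  expect_error(fdctForward(matrix(0, 64, 64), cfg), "match")
  expect_error(fdctForward(matrix(0, 64, 32)), "square")
  expect_error(curveletConfig(128, nAnglesCoarse = 12))
  expect_error(curveletConfig(128, nScales = 1))
})

test_that("feature vectors have the documented layout and scaling", {
  cfg <- curveletConfig(128)
  co <- fdctForward(randImage(128, seed = 4), cfg)
  fv <- extractFeatures(co)
  # scales 2 and 3 carry 16 and 32 wedges; 3 statistics each
  expect_length(fv, (16 + 32) * 3)
  expect_identical(names(fv)[1:3], c("s2.w01.mean", "s2.w01.sd",
                                     "s2.w01.energy"))
  co0 <- fdctForward(matrix(0, 128, 128), cfg)
  expect_true(all(extractFeatures(co0) == 0))

  # homogeneity: mean/sd scale linearly, energy quadratically
  co2 <- fdctForward(2 * randImage(128, seed = 4), cfg)
  fv2 <- extractFeatures(co2)
  st <- sub("^.*\\.", "", names(fv))
  expect_equal(fv2[st != "energy"], 2 * fv[st != "energy"],
               tolerance = 1e-10)
  expect_equal(fv2[st == "energy"], 4 * fv[st == "energy"],
               tolerance = 1e-10)

  expect_error(extractFeatures(co, scales = c(1, 2)), "excluded")
  expect_silent(extractFeatures(co, scales = c(1, 2), strict = FALSE))
})

test_that("batchExtract preserves order, handles empty input, checks sizes", {
  cfg <- curveletConfig(64)
  img <- randImage(64, seed = 6)
  X <- batchExtract(list(img, img, img), cfg)
  expect_identical(nrow(X), 3L)
  expect_identical(X[1, ], X[2, ])
  expect_identical(X[1, ], X[3, ])

  E <- batchExtract(list(), cfg)
  expect_identical(nrow(E), 0L)
  expect_identical(colnames(E), featureNames(cfg))

  expect_error(batchExtract(list(randImage(64), randImage(32, 1))), "size")

  ds <- generateDataset(syntheticSpec(), 8, 7, seed = 2)
  M <- batchExtract(ds$images, curveletConfig(128))
  expect_identical(dim(M), c(15L, 144L))
})
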