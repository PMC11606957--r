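# small trained pipeline on 64-px images shared by the saliency tests
localPipeline <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ds <- generateDataset(syntheticSpec(imageSize = 64,
                                          discRadiusRange = c(12, 14)),
                            12, 12, seed = 6)
      # ranking mode keeps d > 1: with a 1-D discriminant input the sigmoid
      # hidden columns are nearly collinear and the minimum-norm weights
      # explode, drowning finite-difference checks in rounding noise
      cfg <- classifierConfig(L = 12, U = 4, P = 6, pcaComponents = 8,
                              nKeep = 8, mode = "ranking")
      cache <<- list(pl = trainPipeline(ds$images, ds$labels, cfg, seed = 2),
                     img = ds$images[[1]])
    }
    cache
  }
})

# independent forward pass for finite differences
scoreOf <- function(pl, x, cls) {
  X <- batchExtract(list(x), pl@curveletConfig, pl@scales, pl@stats)
  Z <- reduceFeatures(pl@reduction, X)
  elmPredict(pl@elm, Z)$scores[1, cls]
}

test_that("class-score gradients agree with central finite differences", {
  fx <- localPipeline()
  pl <- fx$pl; x <- pixels(fx$img)
  g <- classScoreGradient(pl, x, "glaucoma")
  expect_identical(dim(g$gradient), dim(x))
  expect_equal(g$score, unname(scoreOf(pl, x, "glaucoma")), tolerance = 1e-8)
  set.seed(2)
  idx <- cbind(sample(64, 20), sample(64, 20))
  for (i in 1:20) {
    e <- matrix(0, 64, 64); e[idx[i, 1], idx[i, 2]] <- 1e-4
    fd <- (scoreOf(pl, x + e, "glaucoma") -
             scoreOf(pl, x - e, "glaucoma")) / 2e-4
    expect_lt(abs(fd - g$gradient[idx[i, 1], idx[i, 2]]) /
                max(abs(fd), 1e-8), 1e-3)
  }
})

test_that("gradients are linear in the output weights and vanish for a flat head", {
  fx <- localPipeline()
  pl <- fx$pl; x <- pixels(fx$img)
  g1 <- classScoreGradient(pl, x, "glaucoma")$gradient
  pl2 <- pl; pl2@elm@outputWeights <- 2 * pl@elm@outputWeights
  expect_equal(classScoreGradient(pl2, x, "glaucoma")$gradient, 2 * g1,
               tolerance = 1e-10)
  pl0 <- pl; pl0@elm@outputWeights <- 0 * pl@elm@outputWeights
  expect_true(all(classScoreGradient(pl0, x, "glaucoma")$gradient == 0))
})

test_that("vanilla gradient maps are non-negative |gradients|", {
  fx <- localPipeline()
  v <- vanillaGradient(fx$pl, fx$img, "glaucoma")
  expect_true(all(saliencyValues(v) >= 0))
  g <- classScoreGradient(fx$pl, fx$img, "glaucoma")$gradient
  expect_equal(saliencyValues(v), abs(g), tolerance = 1e-12)
  vn <- vanillaGradient(fx$pl, fx$img, "glaucoma", normalize = TRUE)
  expect_equal(max(saliencyValues(vn)), 1)
})

test_that("integrated gradients satisfy completeness and degeneracy", {
  fx <- localPipeline()
  pl <- fx$pl; x <- pixels(fx$img)
  ig <- integratedGradients(pl, x, "glaucoma", steps = 200)
  delta <- scoreOf(pl, x, "glaucoma") -
    scoreOf(pl, matrix(0, 64, 64), "glaucoma")
  expect_lt(abs(sum(saliencyValues(ig)) - delta) / abs(delta), 0.01)

  ig0 <- integratedGradients(pl, x, "glaucoma", baseline = x, steps = 5)
  expect_true(all(saliencyValues(ig0) == 0))
  expect_error(integratedGradients(pl, x, steps = 0), "steps")
  expect_error(integratedGradients(pl, x, baseline = matrix(0, 8, 8)),
               "shape")
})

test_that("smoothgrad reduces to vanilla at zero noise and averages down variance", {
  fx <- localPipeline()
  pl <- fx$pl; x <- pixels(fx$img)
  v <- saliencyValues(vanillaGradient(pl, x, "glaucoma"))
  s0 <- saliencyValues(smoothGrad(pl, x, "glaucoma", sigma = 0,
                                  nSamples = 3))
  expect_equal(s0, v, tolerance = 1e-12)

  # n = 1 equals the vanilla gradient of the single perturbed copy
  s1 <- smoothGrad(pl, x, "glaucoma", sigma = 0.05, nSamples = 1, seed = 9)
  pert <- curvelm:::withSeed(9L, x + matrix(rnorm(64 * 64, sd = 0.05), 64))
  expect_equal(saliencyValues(s1),
               abs(classScoreGradient(pl, pert, "glaucoma")$gradient),
               tolerance = 1e-12)

  # map variance across repeated draws shrinks with the sample count
  maps5 <- sapply(1:6, function(s)
    saliencyValues(smoothGrad(pl, x, "glaucoma", sigma = 0.1,
                              nSamples = 5, seed = s)))
  maps50 <- sapply(1:6, function(s)
    saliencyValues(smoothGrad(pl, x, "glaucoma", sigma = 0.1,
                              nSamples = 50, seed = s)))
  expect_lt(mean(apply(maps50, 1, var)), mean(apply(maps5, 1, var)))
})

test_that("saliency concentrates on the optic nerve head of glaucoma images", {
  fx <- localPipeline()
  spec <- syntheticSpec(imageSize = 64, discRadiusRange = c(12, 14))
  inside <- numeric(20); outside <- numeric(20)
  for (s in 1:20) {
    img <- generateFundus(spec, "glaucoma", seed = 500 + s)
    v <- saliencyValues(vanillaGradient(fx$pl, img, "glaucoma"))
    inside[s] <- mean(v[discMask(img)])
    outside[s] <- mean(v[!discMask(img)])
  }
  expect_gt(mean(inside), mean(outside))
  expect_gt(mean(inside > outside), 0.8)
})

test_that("heatmap rendering is shape-safe and deterministic", {
  fx <- localPipeline()
  v <- vanillaGradient(fx$pl, fx$img, "glaucoma")
  out <- renderHeatmap(v, fx$img)
  expect_identical(dim(out), c(64L, 64L, 3L))
  expect_true(all(out >= 0 & out <= 1))
  expect_identical(renderHeatmap(v, fx$img), out)

  flat <- new("SaliencyMap", values = matrix(1, 64, 64),
              method = "vanilla", targetClass = "glaucoma")
  outf <- renderHeatmap(flat, matrix(0.5, 64, 64))
  expect_lt(max(abs(outf[, , 1] - outf[1, 1, 1])), 1e-12)

  f <- tempfile(fileext = ".png")
  renderHeatmap(v, fx$img, file = f)
  expect_true(file.exists(f))
  bad <- new("SaliencyMap", values = matrix(0, 8, 8), method = "vanilla",
             targetClass = "x")
  expect_error(renderHeatmap(bad, fx$img), "shape")
})
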