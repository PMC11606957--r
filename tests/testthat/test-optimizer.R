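sphere5 <- benchmarkObjective("sphere", 5)

test_that("population initialization honors bounds, seeds and degeneracy", {
  p <- initPopulation(sphere5$fn, 20, sphere5$lower, sphere5$upper,
                      seed = 1)
  expect_identical(dim(p$positions), c(20L, 5L))
  expect_true(all(p$positions >= -10 & p$positions < 10))
  expect_equal(p$fitness, apply(p$positions, 1, sphere5$fn),
               tolerance = 1e-12)
  p2 <- initPopulation(sphere5$fn, 20, sphere5$lower, sphere5$upper,
                       seed = 1)
  expect_identical(p2$positions, p$positions)

  pd <- initPopulation(function(x) sum(x), 5, rep(2, 3), rep(2, 3))
  expect_true(all(pd$positions == 2))
  expect_error(initPopulation(sphere5$fn, 4, c(1, 1), c(0, 2)), "nverted")
})

test_that("prey placement follows the best/worst midpoint rule", {
  pop <- list(positions = rbind(c(1, 2), c(3, 4)), fitness = c(0, 1),
              lower = c(-10, -10), upper = c(10, 10))
  expect_identical(preyLocation(pop, "MOD-POA"), c(2, 3))
  same <- list(positions = rbind(c(5, 5), c(5, 5)), fitness = c(1, 1),
               lower = c(-10, -10), upper = c(10, 10))
  expect_identical(preyLocation(same, "MOD-POA"), c(5, 5))
  set.seed(1)
  expect_identical(preyLocation(same, "POA"), c(5, 5))
})

test_that("both phases are greedy: fitness never worsens", {
  set.seed(2)
  pop <- initPopulation(sphere5$fn, 10, sphere5$lower, sphere5$upper,
                        seed = 2)
  f0 <- pop$fitness
  pop1 <- explorationStep(pop, preyLocation(pop, "MOD-POA"), sphere5$fn)
  expect_true(all(pop1$fitness <= f0))
  pop2 <- exploitationStep(pop1, 3, 10, sphere5$fn)
  expect_true(all(pop2$fitness <= pop1$fitness))

  # a member at the optimum of a convex bowl never moves
  atopt <- list(positions = rbind(c(0, 0), c(4, 4)), fitness = c(0, 32),
                lower = c(-10, -10), upper = c(10, 10))
  bowl <- function(x) sum(x^2)
  res <- explorationStep(atopt, c(2, 2), bowl)
  expect_identical(res$positions[1, ], c(0, 0))

  # exploration-only iterations shrink the mean fitness on the sphere
  set.seed(3)
  popA <- initPopulation(sphere5$fn, 10, rep(-10, 2), rep(10, 2), seed = 3)
  m0 <- mean(popA$fitness)
  for (i in 1:5)
    popA <- explorationStep(popA, preyLocation(popA, "MOD-POA"), sphere5$fn)
  expect_lt(mean(popA$fitness), m0)
})

test_that("exploitation decay freezes the population at the final iteration", {
  set.seed(4)
  pop <- initPopulation(sphere5$fn, 6, sphere5$lower, sphere5$upper,
                        seed = 4)
  frozen <- exploitationStep(pop, t = 10, P = 10, sphere5$fn)
  expect_identical(frozen$positions, pop$positions)

  zero <- list(positions = matrix(0, 3, 2), fitness = rep(0, 3),
               lower = c(-1, -1), upper = c(1, 1))
  still <- exploitationStep(zero, 1, 10, function(x) sum(x^2))
  expect_identical(still$positions, zero$positions)
  expect_error(exploitationStep(pop, 11, 10, sphere5$fn), "lie in")
})

test_that("the full optimizer converges, is monotone and reproducible", {
  res <- pelicanMinimize(sphere5$fn, sphere5$lower, sphere5$upper,
                         U = 20, P = 100, seed = 1)
  expect_lt(bestFitness(res), 1e-2)
  expect_true(all(diff(fitnessTrajectory(res)) <= 0))
  expect_equal(bestFitness(res), sphere5$fn(bestPosition(res)),
               tolerance = 1e-12)

  res2 <- pelicanMinimize(sphere5$fn, sphere5$lower, sphere5$upper,
                          U = 20, P = 100, seed = 1)
  expect_identical(fitnessTrajectory(res2), fitnessTrajectory(res))
  expect_identical(bestPosition(res2), bestPosition(res))

  flat <- pelicanMinimize(function(x) 7, c(-1, -1), c(1, 1), U = 4, P = 10,
                          seed = 2)
  expect_true(all(fitnessTrajectory(flat) == 7))

  ras <- benchmarkObjective("rastrigin", 2)
  for (s in 1:20) {
    r <- pelicanMinimize(ras$fn, ras$lower, ras$upper, U = 8, P = 25,
                         seed = s)
    expect_true(all(diff(fitnessTrajectory(r)) <= 0))
  }

  expect_error(pelicanMinimize(function(x) NA_real_, c(-1, -1), c(1, 1),
                               U = 3, P = 5), "non-finite")
})

test_that("MOD-POA beats random search at an equal evaluation budget", {
  mod <- numeric(20); rnd <- numeric(20)
  for (s in 1:20) {
    mod[s] <- bestFitness(pelicanMinimize(sphere5$fn, sphere5$lower,
                                          sphere5$upper, U = 10, P = 25,
                                          seed = s))
    set.seed(s)
    # same budget for pure random search: U * P draws
    draws <- matrix(runif(10 * 25 * 5, -10, 10), ncol = 5)
    rnd[s] <- min(apply(draws, 1, sphere5$fn))
  }
  expect_lte(median(mod), median(rnd))
})

test_that("POA variant runs and both variants respect bounds", {
  for (v in c("POA", "MOD-POA")) {
    r <- pelicanMinimize(sphere5$fn, rep(-2, 3), rep(2, 3), U = 6, P = 15,
                         variant = v, seed = 5)
    expect_true(all(abs(bestPosition(r)) <= 2))
    expect_identical(r@variant, v)
  }
})
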