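# Pelican optimization algorithm (POA) and its modified variant (MOD-POA).
# Minimization over a box. Two phases per iteration: exploration (move
# toward/away from a prey point) and exploitation (shrinking local sweep),
# both with greedy acceptance, so the best-so-far trajectory never
# increases.

evalObjective <- function(objective, x) {
  v <- objective(x)
  if (length(v) != 1L || !is.finite(v))
    stop(sprintf(
      "objective returned a non-finite value at position (%s)",
      paste(signif(x, 6), collapse = ", ")))
  as.numeric(v)
}

#' Initialize a pelican population
#'
#' Positions are drawn uniformly within the box, coordinate-wise:
#' \code{lower + rand * (upper - lower)}; fitness is evaluated for every
#' member.
#'
#' @param objective function mapping a length-V numeric vector to a finite
#'   scalar (minimized).
#' @param U population size (>= 2).
#' @param lower,upper bound vectors (length V, lower <= upper).
#' @param seed integer seed.
#' @param inject optional list of positions forced into the first
#'   population slots (clipped to bounds) before evaluation.
#' @return List with \code{positions} (U x V), \code{fitness} (length U)
#'   and the bounds.
#' @export
initPopulation <- function(objective, U, lower, upper, seed = 1L,
                           inject = NULL) {
  stopifnotScalarCount(U, "U", min = 2L)
  V <- length(lower)
  if (length(upper) != V || V < 1L) stop("bound vectors must match")
  if (any(lower > upper)) stop("inverted bounds")
  pos <- withSeed(seed, {
    matrix(runif(U * V), U, V) *
      matrix(upper - lower, U, V, byrow = TRUE) +
      matrix(lower, U, V, byrow = TRUE)
  })
  if (!is.null(inject)) {
    for (i in seq_along(inject)) {
      if (i > U) break
      pos[i, ] <- pmin(pmax(inject[[i]], lower), upper)
    }
  }
  fit <- apply(pos, 1L, function(x) evalObjective(objective, x))
  list(positions = pos, fitness = fit, lower = lower, upper = upper)
}

#' Prey location for the current iteration
#'
#' MOD-POA places the prey at the midpoint of the best and worst
#' population members; plain POA samples a uniformly random member.
#'
#' @param pop population list from \code{\link{initPopulation}}.
#' @param variant "MOD-POA" or "POA".
#' @return Position vector.
#' @export
preyLocation <- function(pop, variant = c("MOD-POA", "POA")) {
  variant <- match.arg(variant)
  if (variant == "MOD-POA") {
    b <- which.min(pop$fitness); w <- which.max(pop$fitness)
    (pop$positions[b, ] + pop$positions[w, ]) / 2
  } else {
    pop$positions[sample.int(nrow(pop$positions), 1L), ]
  }
}

#' Exploration phase (move toward the prey)
#'
#' Per member: when the prey is fitter than the member, the candidate is
#' \code{x + rand * (prey - I * x)} with intensity I drawn from {1, 2} per
#' member; otherwise \code{x + rand * (x - prey)}. Random factors are
#' drawn per coordinate, candidates are clipped to the bounds and accepted
#' only on strict fitness improvement.
#'
#' @param pop population list.
#' @param prey prey position for this iteration.
#' @param objective the objective function.
#' @return Updated population list.
#' @export
explorationStep <- function(pop, prey, objective) {
  fPrey <- evalObjective(objective, prey)
  V <- ncol(pop$positions)
  for (i in seq_len(nrow(pop$positions))) {
    x <- pop$positions[i, ]
    ra <- runif(V)
    cand <- if (fPrey < pop$fitness[i]) {
      I <- sample(1:2, 1L)
      x + ra * (prey - I * x)
    } else {
      x + ra * (x - prey)
    }
    cand <- pmin(pmax(cand, pop$lower), pop$upper)
    f <- evalObjective(objective, cand)
    if (f < pop$fitness[i]) {
      pop$positions[i, ] <- cand
      pop$fitness[i] <- f
    }
  }
  pop
}

#' Exploitation phase (winging on the water surface)
#'
#' Per member: \code{x + R * ((P - t) / P) * (2 * rand - 1) * x} with
#' neighborhood constant R (default 0.2) and per-coordinate random
#' factors; the sweep radius decays linearly to zero over the iterations.
#' Clipped to bounds, accepted only on strict improvement.
#'
#' @param pop population list.
#' @param t current iteration (1..P).
#' @param P maximum iteration count.
#' @param objective the objective function.
#' @param R neighborhood constant, default 0.2.
#' @return Updated population list.
#' @export
exploitationStep <- function(pop, t, P, objective, R = 0.2) {
  if (t < 1 || t > P) stop("iteration t must lie in [1, P]")
  V <- ncol(pop$positions)
  decay <- (P - t) / P
  for (i in seq_len(nrow(pop$positions))) {
    x <- pop$positions[i, ]
    cand <- x + R * decay * (2 * runif(V) - 1) * x
    cand <- pmin(pmax(cand, pop$lower), pop$upper)
    f <- evalObjective(objective, cand)
    if (f < pop$fitness[i]) {
      pop$positions[i, ] <- cand
      pop$fitness[i] <- f
    }
  }
  pop
}

#' Minimize an objective with the (modified) pelican optimizer
#'
#' Runs \code{P} iterations of prey placement, exploration and
#' exploitation over a population of \code{U} members. Greedy acceptance
#' makes the best-so-far trajectory non-increasing; the run is fully
#' reproducible from the seed.
#'
#' @param objective function of a length-V vector, minimized; must return
#'   finite values inside the box.
#' @param lower,upper box bounds (length V).
#' @param U population size, default 20.
#' @param P iteration count, default 100.
#' @param variant "MOD-POA" (default) or "POA".
#' @param seed integer seed.
#' @param R exploitation neighborhood constant, default 0.2.
#' @param inject optional positions seeded into the initial population
#'   (see \code{\link{initPopulation}}).
#' @return A \linkS4class{PelicanResult}.
#' @examples
#' sphere <- function(x) sum(x^2)
#' res <- pelicanMinimize(sphere, rep(-10, 2), rep(10, 2),
#'                        U = 10, P = 40, seed = 1)
#' bestFitness(res)
#' @export
pelicanMinimize <- function(objective, lower, upper, U = 20L, P = 100L,
                            variant = c("MOD-POA", "POA"), seed = 1L,
                            R = 0.2, inject = NULL) {
  variant <- match.arg(variant)
  stopifnotScalarCount(P, "P")
  pop <- initPopulation(objective, U, lower, upper, seed = seed,
                        inject = inject)
  withSeed(seedOffset(seed, 1L), {
    traj <- numeric(P)
    best <- min(pop$fitness)
    bestPos <- pop$positions[which.min(pop$fitness), ]
    for (t in seq_len(P)) {
      prey <- preyLocation(pop, variant)
      pop <- explorationStep(pop, prey, objective)
      pop <- exploitationStep(pop, t, P, objective, R = R)
      if (min(pop$fitness) < best) {
        best <- min(pop$fitness)
        bestPos <- pop$positions[which.min(pop$fitness), ]
      }
      traj[t] <- best
    }
    new("PelicanResult", bestPosition = bestPos, bestFitness = best,
        trajectory = traj, iterations = as.integer(P),
        seed = as.integer(seed), variant = variant)
  })
}

#' @describeIn pelicanMinimize Best objective value found.
#' @param result a \linkS4class{PelicanResult}.
#' @export
bestFitness <- function(result) result@bestFitness

#' @describeIn pelicanMinimize Best position found.
#' @export
bestPosition <- function(result) result@bestPosition

#' @describeIn pelicanMinimize Best-so-far fitness after each iteration.
#' @export
fitnessTrajectory <- function(result) result@trajectory

#' Standard continuous benchmark objectives
#'
#' Sphere, Rastrigin and Rosenbrock test functions with their customary
#' box bounds, for optimizer regression tests and the \code{benchmark}
#' CLI verb.
#'
#' @param name "sphere", "rastrigin" or "rosenbrock".
#' @param V dimension.
#' @return List with \code{fn}, \code{lower}, \code{upper}.
#' @export
benchmarkObjective <- function(name = c("sphere", "rastrigin", "rosenbrock"),
                               V = 5L) {
  name <- match.arg(name)
  switch(name,
    sphere = list(fn = function(x) sum(x^2),
                  lower = rep(-10, V), upper = rep(10, V)),
    rastrigin = list(fn = function(x)
                       10 * length(x) + sum(x^2 - 10 * cos(2 * pi * x)),
                     lower = rep(-5.12, V), upper = rep(5.12, V)),
    rosenbrock = list(fn = function(x)
                        sum(100 * (x[-1] - x[-length(x)]^2)^2 +
                              (1 - x[-length(x)])^2),
                      lower = rep(-5, V), upper = rep(10, V)))
}

setMethod("show", "PelicanResult", function(object) {
  cat(sprintf(
    "PelicanResult (%s): best %.6g after %d iterations (seed %d)\n",
    object@variant, object@bestFitness, object@iterations, object@seed))
})
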