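## Improved Whale Optimization: a bounded-box population metaheuristic with
## chaotic tent-map initialization, a nonlinear convergence factor, a
## cosine inertia weight, a Cauchy-mutation vector, spiral/encircling
## position updates and an optimal-based feedback mechanism. Lower fitness
## is better; positions are clipped to bounds after every operator.
##
## Random draw protocol (fixed so the reduction-to-vanilla-WOA oracle can
## consume an identical stream): per whale and iteration the update draws,
## in order, p ~ U[0,1), the random-whale index, r1 ~ U[0,1)^d,
## r2 ~ U[0,1)^d, s ~ U[-1,1]. Mutation and feedback draws happen outside
## this sequence and are skipped entirely when disabled.

#' One tent-map step
#'
#' The piecewise-linear chaotic map `ch/0.7` for `ch < 0.7`, else
#' `(1 - ch)/0.3`, mapping \[0,1\] onto itself.
#'
#' @param ch value in \[0,1\] (vectorized).
#' @return mapped value(s) in \[0,1\].
#' @export
tentMapStep <- function(ch) {
  if (any(ch < 0 | ch > 1)) stop("tent map input must lie in [0,1]")
  ifelse(ch < 0.7, ch / 0.7, (1 - ch) / 0.3)
}

#' Chaotic tent-map population initialization
#'
#' Runs one tent-map trajectory per dimension (random non-fixed-point
#' start; if a fixed point is hit the trajectory is restarted with a small
#' perturbation) and maps the iterates affinely onto \[lb, ub\] per
#' dimension. Degenerate dimensions with lb == ub are allowed with a
#' warning (all whales sit at lb there).
#'
#' @param space a [SearchSpace-class].
#' @param P population size (>= 2).
#' @param seed optional integer seed.
#' @return a P x d matrix of positions within bounds.
#' @export
chaoticInitialize <- function(space, P, seed = NULL) {
  stopifnot(is(space, "SearchSpace"), P >= 2)
  d <- spaceDim(space)
  lb <- space@lower; ub <- space@upper
  if (any(ub == lb))
    warning("degenerate dimension(s) with lb == ub; whales fixed at lb there")
  withSeed(seed, {
    pos <- matrix(0, P, d)
    fixedPts <- c(0, 1 / 1.3)              # tent-map fixed points
    for (j in seq_len(d)) {
      ch <- runif(1)
      for (i in seq_len(P)) {
        if (min(abs(ch - fixedPts)) < 1e-12 || ch == 1)
          ch <- runif(1)
        pos[i, j] <- lb[j] + (ub[j] - lb[j]) * ch
        ch <- tentMapStep(ch)
      }
    }
    pos
  })
}

#' Nonlinear convergence factor
#'
#' `a(t) = 2 - 2 * (exp((t/tmax)^m) - 1) / (e - 1)`: decays from 2 at
#' t = 0 to 0 at t = tmax, with curve smoothness `m` controlling how the
#' exploration-to-exploitation handover is paced.
#'
#' @param t iteration in 0..tmax (vectorized).
#' @param tmax maximum iterations (> 0).
#' @param m curve smoothness (> 0).
#' @return the decay scalar in \[0, 2\].
#' @export
convergenceFactor <- function(t, tmax, m = 2) {
  if (tmax <= 0) stop("tmax must be positive")
  stopifnot(all(t >= 0), all(t <= tmax), m > 0)
  2 - 2 * (exp((t / tmax)^m) - 1) / (exp(1) - 1)
}

#' Cosine inertia weight
#'
#' `|cos(l * t * pi / tmax)|`, cycling in \[0, 1\] with cycle size `l`.
#'
#' @param t iteration in 0..tmax (vectorized).
#' @param tmax maximum iterations.
#' @param lCycle cycle size of the weight function.
#' @return weight(s) in \[0, 1\].
#' @export
inertiaWeight <- function(t, tmax, lCycle = 1) {
  stopifnot(all(t >= 0), all(t <= tmax))
  abs(cos(lCycle * t * pi / tmax))
}

.inertiaAt <- function(t, cfg) {
  switch(cfg@inertia,
         cosine = inertiaWeight(t, cfg@tMax, cfg@lCycle),
         constant = 1,
         lineardecay = 0.9 - 0.5 * t / cfg@tMax)
}

.convergenceAt <- function(t, cfg) {
  if (cfg@convergence == "nonlinear") convergenceFactor(t, cfg@tMax, cfg@m)
  else 2 * (1 - t / cfg@tMax)
}

#' Cauchy mutation vector
#'
#' Builds a mutant from the best-so-far position: each coordinate is,
#' with probability `crossoverRate` (or always at one forced per-individual
#' index, the DE-style binomial-crossover guarantee), replaced by the best
#' coordinate plus a heavy-tailed Cauchy perturbation scaled by
#' `cauchyScale * (ub - lb)`; other coordinates keep the current whale's
#' value. The result is clipped to bounds.
#'
#' @param best best-so-far position.
#' @param current current whale position.
#' @param space a [SearchSpace-class].
#' @param cfg an [IWOConfig-class].
#' @return the mutant vector, within bounds.
#' @export
cauchyMutate <- function(best, current, space, cfg) {
  d <- length(best)
  stopifnot(length(current) == d)
  jForced <- sample.int(d, 1)
  u <- runif(d)
  cd <- rcauchy(d)
  mask <- (u < cfg@crossoverRate) | (seq_len(d) == jForced)
  mut <- ifelse(mask,
                best + cfg@cauchyScale * (space@upper - space@lower) * cd,
                current)
  clipRange(mut, space@lower, space@upper)
}

#' One whale position update
#'
#' Draws `p ~ U[0,1)`, a random whale index, per-dimension coefficient
#' vectors `A = 2 a r1 - a` and `C = 2 r2`, and a spiral parameter
#' `s ~ U[-1,1]`. With `p < 0.5` the whale encircles: per dimension the
#' target is the random whale where `|A| >= 1` (exploration) and the
#' inertia-weighted mutant where `|A| < 1` (exploitation), moving by
#' `wt * target - A * |C * target - W|`. With `p >= 0.5` it spirals:
#' `wt * WV + |WV - W| * exp(b s) * cos(2 pi s)`. The result is clipped to
#' bounds. With mutation disabled, the mutant equals the best position and
#' `wt = 1` reduces the update to the standard whale algorithm.
#'
#' @param position current whale position.
#' @param mutant mutant vector WV (best position when mutation is off).
#' @param population P x d matrix of current positions (random-whale pool).
#' @param t current iteration.
#' @param space a [SearchSpace-class].
#' @param cfg an [IWOConfig-class].
#' @param draws optional list(p, randIdx, r1, r2, s) to inject the random
#'   draws (used by the reduction tests); when NULL they are drawn from
#'   the current RNG stream in the documented order.
#' @return the updated position, within bounds.
#' @export
updatePosition <- function(position, mutant, population, t, space, cfg,
                           draws = NULL) {
  d <- length(position)
  if (is.null(draws)) {
    p <- runif(1)
    randIdx <- sample.int(nrow(population), 1)
    r1 <- runif(d); r2 <- runif(d)
    s <- runif(1, -1, 1)
  } else {
    p <- draws$p; randIdx <- draws$randIdx
    r1 <- draws$r1; r2 <- draws$r2; s <- draws$s
  }
  a <- .convergenceAt(t, cfg)
  wt <- .inertiaAt(t, cfg)
  A <- 2 * a * r1 - a
  C <- 2 * r2
  if (p < 0.5) {
    target <- ifelse(abs(A) >= 1, population[randIdx, ], mutant)
    newPos <- wt * target - A * abs(C * target - position)
  } else {
    newPos <- wt * mutant + abs(mutant - position) * exp(cfg@b * s) *
      cos(2 * pi * s)
  }
  clipRange(newPos, space@lower, space@upper)
}

#' Optimal-based feedback update
#'
#' Draws `lambda, pl ~ U[0,1)` and `C ~ U[-1,1]`; when `pl` exceeds the
#' feedback threshold the whale is replaced by
#' `lambda * W_rand + (1 - lambda) * WV + C * (W_rand - WV)` (clipped),
#' otherwise the random whale's position is returned unchanged.
#'
#' @param randWhale a randomly selected whale position.
#' @param mutant the mutant vector WV.
#' @param space a [SearchSpace-class].
#' @param cfg an [IWOConfig-class].
#' @param draws optional list(lambda, pl, C) injected draws.
#' @return the new position, within bounds.
#' @export
feedbackUpdate <- function(randWhale, mutant, space, cfg, draws = NULL) {
  if (is.null(draws)) {
    lambda <- runif(1); pl <- runif(1); C <- runif(1, -1, 1)
  } else {
    lambda <- draws$lambda; pl <- draws$pl; C <- draws$C
  }
  if (pl <= cfg@feedbackThreshold) return(randWhale)
  clipRange(lambda * randWhale + (1 - lambda) * mutant +
              C * (randWhale - mutant), space@lower, space@upper)
}

#' Run the Improved Whale Optimization algorithm
#'
#' Chaotic initialization, then `tMax` sweeps of mutation + position
#' updates with the feedback mechanism applied to the worst
#' `feedbackFraction` of the population, tracking the best-so-far
#' position. Exactly `P * (tMax + 1)` objective evaluations are performed
#' (initial population plus one re-evaluation per whale per iteration).
#' An objective returning NaN gives that whale +Inf fitness with a
#' warning. The best-so-far history is non-increasing by construction.
#'
#' @param objective function(position) -> finite scalar, lower is better.
#' @param space a [SearchSpace-class].
#' @param cfg an [IWOConfig-class]; `cfg@seed` drives all randomness.
#' @return list(bestPosition, bestFitness, history (length tMax + 1),
#'   evaluations, population, fitness).
#' @export
iwoOptimize <- function(objective, space, cfg = iwoConfig()) {
  stopifnot(is(space, "SearchSpace"), is(cfg, "IWOConfig"))
  validObject(cfg)
  P <- cfg@populationSize; d <- spaceDim(space)
  evalOne <- function(x) {
    f <- objective(x)
    if (is.na(f) || is.nan(f)) {
      warning("objective returned NaN; whale fitness set to +Inf")
      f <- Inf
    }
    f
  }
  withSeed(cfg@seed, {
    pos <- chaoticInitialize(space, P)
    fit <- apply(pos, 1, evalOne)
    nEval <- P
    bestIdx <- which.min(fit)
    bestPos <- pos[bestIdx, ]
    bestFit <- fit[bestIdx]
    history <- numeric(cfg@tMax + 1)
    history[1] <- bestFit
    nFb <- floor(cfg@feedbackFraction * P)
    for (t in seq_len(cfg@tMax)) {
      mutants <- matrix(0, P, d)
      for (i in seq_len(P)) {
        mutants[i, ] <- if (cfg@mutation)
          cauchyMutate(bestPos, pos[i, ], space, cfg) else bestPos
      }
      newPos <- pos
      for (i in seq_len(P))
        newPos[i, ] <- updatePosition(pos[i, ], mutants[i, ], pos, t, space, cfg)
      if (nFb > 0) {
        worst <- order(fit, decreasing = TRUE)[seq_len(nFb)]
        for (i in worst) {
          rIdx <- sample.int(P, 1)
          newPos[i, ] <- feedbackUpdate(newPos[rIdx, ], mutants[i, ], space, cfg)
        }
      }
      pos <- newPos
      fit <- apply(pos, 1, evalOne)
      nEval <- nEval + P
      if (min(fit) < bestFit) {
        bestFit <- min(fit)
        bestPos <- pos[which.min(fit), ]
      }
      history[t + 1] <- bestFit
    }
    list(bestPosition = bestPos, bestFitness = bestFit, history = history,
         evaluations = nEval, population = pos, fitness = fit)
  })
}

#' Wrap a subprocess command as an objective function
#'
#' Builds an objective callable from a shell command: for each evaluation
#' the position is written as a JSON array to a temporary file, the
#' command is invoked with that path as its final argument, and the
#' fitness is read back from the JSON file the command writes next to it
#' (`<input>.out.json`, a single number).
#'
#' @param command the program to run.
#' @param args extra arguments placed before the position-file path.
#' @return a function(position) -> numeric fitness usable with
#'   [iwoOptimize()].
#' @export
commandObjective <- function(command, args = character()) {
  force(command); force(args)
  function(position) {
    inPath <- tempfile(fileext = ".json")
    outPath <- paste0(inPath, ".out.json")
    jsonlite::write_json(as.numeric(position), inPath, digits = NA)
    status <- system2(command, c(args, inPath), stdout = FALSE, stderr = FALSE)
    on.exit(unlink(c(inPath, outPath)))
    if (status != 0 || !file.exists(outPath)) return(NaN)
    as.numeric(jsonlite::read_json(outPath, simplifyVector = TRUE))[1]
  }
}
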