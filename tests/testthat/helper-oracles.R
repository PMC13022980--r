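## Independent oracles, implemented separately from the package paths they
## check: a direct Cox-de Boor recursion, a vanilla whale-optimization
## reference, brute-force AUROC / kappa, and a sliding-window RMS contrast
## measure.

## Cox-de Boor recursion, one basis function at a time (deliberately the
## naive recursive form, nothing shared with splines::splineDesign).
cdbBasis <- function(x, knots, i, k) {
  if (k == 0) {
    ## right-closed at the final interval so the clamped end evaluates to 1
    if ((x >= knots[i] && x < knots[i + 1]) ||
        (x == knots[length(knots)] && knots[i + 1] == x &&
         knots[i] < knots[i + 1]))
      return(1)
    return(0)
  }
  d1 <- knots[i + k] - knots[i]
  d2 <- knots[i + k + 1] - knots[i + 1]
  t1 <- if (d1 > 0) (x - knots[i]) / d1 * cdbBasis(x, knots, i, k - 1) else 0
  t2 <- if (d2 > 0) (knots[i + k + 1] - x) / d2 *
    cdbBasis(x, knots, i + 1, k - 1) else 0
  t1 + t2
}

cdbBasisRow <- function(x, knots, degree = 3) {
  nb <- length(knots) - degree - 1
  vapply(seq_len(nb), function(i) cdbBasis(x, knots, i, degree), numeric(1))
}

## Vanilla whale optimization, independently coded with the same random
## draw protocol as the package optimizer (p, random index, r1, r2, s per
## whale) so streams can be shared. Linear decay a = 2(1 - t/tmax).
vanillaWoaSweep <- function(pos, best, t, tmax, lb, ub, b = 1) {
  P <- nrow(pos); d <- ncol(pos)
  newPos <- pos
  a <- 2 * (1 - t / tmax)
  for (i in seq_len(P)) {
    p <- runif(1)
    rIdx <- sample.int(P, 1)
    r1 <- runif(d); r2 <- runif(d)
    s <- runif(1, -1, 1)
    A <- 2 * a * r1 - a
    C <- 2 * r2
    if (p < 0.5) {
      target <- ifelse(abs(A) >= 1, pos[rIdx, ], best)
      np <- target - A * abs(C * target - pos[i, ])
    } else {
      np <- best + abs(best - pos[i, ]) * exp(b * s) * cos(2 * pi * s)
    }
    newPos[i, ] <- pmin(pmax(np, lb), ub)
  }
  newPos
}

vanillaWoaRun <- function(objective, lb, ub, P, tmax, seed, b = 1) {
  set.seed(seed)
  d <- length(lb)
  ## same chaotic initialization as the package (shared stream prefix)
  space <- searchSpace(lb, ub)
  pos <- chaoticInitialize(space, P)
  fit <- apply(pos, 1, objective)
  best <- pos[which.min(fit), ]
  bestFit <- min(fit)
  history <- bestFit
  for (t in seq_len(tmax)) {
    pos <- vanillaWoaSweep(pos, best, t, tmax, lb, ub, b)
    fit <- apply(pos, 1, objective)
    if (min(fit) < bestFit) {
      bestFit <- min(fit)
      best <- pos[which.min(fit), ]
    }
    history <- c(history, bestFit)
  }
  list(position = best, fitness = bestFit, history = history, pop = pos)
}

## O(n^2) pairwise AUROC with ties counted 1/2.
bruteAuroc <- function(scores, positive) {
  sp <- scores[positive]; sn <- scores[!positive]
  tot <- 0
  for (a in sp) for (b in sn)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(sp) * length(sn))
}

## Multiclass Cohen's kappa from first principles (explicit loops).
bruteKappa <- function(cm) {
  n <- sum(cm)
  po <- 0
  for (i in seq_len(nrow(cm))) po <- po + cm[i, i]
  po <- po / n
  pe <- 0
  for (i in seq_len(nrow(cm)))
    pe <- pe + sum(cm[i, ]) * sum(cm[, i])
  pe <- pe / n^2
  (po - pe) / (1 - pe)
}

## Mean within-tile standard deviation: a sliding-window RMS local
## contrast measure.
rmsLocalContrast <- function(gray, tile = 16) {
  d <- dim(gray)
  vals <- c()
  for (i in seq(1, d[1] - tile + 1, by = tile))
    for (j in seq(1, d[2] - tile + 1, by = tile))
      vals <- c(vals, sd(gray[i:(i + tile - 1), j:(j + tile - 1)]))
  mean(vals)
}

## Shared small fixtures (built once per test run).
testImage <- function(grade = 2, size = 64, seed = 42)
  generateFundusImage(grade, size, seed = seed)

luminanceOf <- function(img) {
  p <- pixels(img)
  0.299 * p[, , 1] + 0.587 * p[, , 2] + 0.114 * p[, , 3]
}
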