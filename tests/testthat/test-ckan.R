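test_that("B-spline basis is a partition of unity with clamped endpoints", {
  bank <- splineBank(1)
  xs <- seq(-2, 2, length.out = 101)
  B <- splineBasis(xs, bank)
  expect_lt(max(abs(rowSums(B) - 1)), 1e-10)
  expect_true(all(B >= -1e-12))
  ## clamped left endpoint: first basis function is 1, the rest 0
  b0 <- splineBasis(-2, bank)
  expect_equal(as.numeric(b0), c(1, rep(0, 9)), tolerance = 1e-12)
  ## outside the span: clamped to the boundary value
  expect_equal(splineBasis(-5, bank), splineBasis(-2, bank))
  expect_error(splineBank(1, nKnots = 3), "4 knots")
})

test_that("basis values match a direct Cox-de Boor recursion at random points", {
  bank <- splineBank(1)
  kn <- retiKAN:::.fullKnots(bank@knots)
  set.seed(31)
  xs <- runif(50, -2, 2)
  B <- splineBasis(xs, bank)
  for (i in seq_along(xs)) {
    expect_lt(max(abs(B[i, ] - cdbBasisRow(xs[i], kn))), 1e-10)
  }
})

test_that("identity-initialized splines reproduce their input on the span", {
  bank <- splineBank(4)
  x <- matrix(runif(400, -2, 2), 100, 4)
  expect_lt(max(abs(splineApply(x, bank) - x)), 1e-10)
})

test_that("the head follows the published five-stage tensor flow", {
  cfg <- ckanConfig()
  params <- ckanInit(cfg, seed = 1)
  z <- array(rnorm(1 * 14 * 14 * 256, 0, 0.5), c(1, 14, 14, 256))
  res <- ckanForward(z, cfg, params, returnIntermediates = TRUE)
  expect_identical(dim(res$probs), c(1L, 5L))
  expect_lt(abs(sum(res$probs) - 1), 1e-6)
  expect_identical(dim(res$stage1), c(1L, 14L, 14L, 128L))
  expect_identical(dim(res$stage2), c(1L, 14L, 14L, 128L))
  expect_identical(dim(res$stage3), c(1L, 14L, 14L, 256L))
  expect_identical(dim(res$stage4), c(1L, 256L))
  expect_error(ckanForward(array(0, c(1, 14, 14, 100)), cfg, params),
               "channel condenser")
})

test_that("identity splines make stage 2 reproduce its depthwise-conv input", {
  cfg <- ckanConfig(inChannels = 8, condensedChannels = 4, outChannels = 8,
                    hiddenUnits = 4)
  params <- ckanInit(cfg, seed = 2)
  params$dw <- params$dw * 0; params$dw[5, ] <- 1     # exact identity stencil
  params$norm <- list(mu = numeric(4), sd = rep(1, 4))
  z <- array(rnorm(2 * 6 * 6 * 8, 0, 0.2), c(2, 6, 6, 8))
  res <- ckanForward(z, cfg, params, returnIntermediates = TRUE)
  expect_lt(max(abs(res$stage2 - res$stage2input)), 1e-5)
})

test_that("the spline regularizer follows the L1 + entropy convention", {
  ## all-zero coefficients: both terms vanish (0 log 0 := 0)
  expect_identical(splineRegularizer(matrix(0, 3, 10)), 0)
  ## one nonzero coefficient: degenerate distribution has zero entropy
  m <- matrix(0, 1, 10); m[1, 4] <- 2.5
  expect_equal(splineRegularizer(m, mu1 = 0, mu2 = 1), 0)
  ## two equal-magnitude coefficients: entropy log 2 for that bank
  m2 <- matrix(0, 1, 10); m2[1, c(2, 7)] <- c(1.5, -1.5)
  expect_equal(splineRegularizer(m2, mu1 = 0, mu2 = 1), log(2))
  ## and the L1 term is the mean absolute coefficient
  expect_equal(splineRegularizer(m2, mu1 = 1, mu2 = 0), 3 / 10)
})

test_that("lambda = 0 makes the objective equal the prediction loss exactly", {
  cfg <- ckanConfig(inChannels = 6, condensedChannels = 3, outChannels = 6,
                    hiddenUnits = 4, lambda = 0)
  params <- ckanInit(cfg, seed = 3)
  z <- array(rnorm(4 * 5 * 5 * 6), c(4, 5, 5, 6))
  y <- c(0, 1, 2, 3)
  ob <- ckanObjective(z, y, cfg, params)
  expect_identical(ob$objective, ob$predLoss)
  ## increasing lambda never decreases the regularizer's contribution
  cfg2 <- ckanConfig(inChannels = 6, condensedChannels = 3, outChannels = 6,
                     hiddenUnits = 4, lambda = 1e-3)
  cfg3 <- ckanConfig(inChannels = 6, condensedChannels = 3, outChannels = 6,
                     hiddenUnits = 4, lambda = 1e-2)
  o2 <- ckanObjective(z, y, cfg2, params)
  o3 <- ckanObjective(z, y, cfg3, params)
  expect_gte(o3$objective - o3$predLoss, o2$objective - o2$predLoss)
})

test_that("analytic gradients match finite differences on a micro-instance", {
  cfg <- ckanConfig(inChannels = 8, condensedChannels = 5, outChannels = 8,
                    nClasses = 3, hiddenUnits = 6, lambda = 1e-3)
  params <- ckanInit(cfg, seed = 4)
  params$norm <- list(mu = numeric(5), sd = rep(1, 5))
  set.seed(5)
  params$bank@coefficients <- params$bank@coefficients +
    matrix(rnorm(50, 0, 0.2), 5)
  z <- array(rnorm(3 * 4 * 4 * 8), c(3, 4, 4, 8))
  y01 <- matrix(0, 3, 3); y01[cbind(1:3, 1:3)] <- 1
  res <- retiKAN:::.ckanGrad(z, y01, cfg, params)
  fd <- function(setter, analytic, eps = 1e-6) {
    gn <- analytic * 0
    for (i in seq_along(analytic)) {
      o1 <- retiKAN:::.ckanGrad(z, y01, cfg, setter(params, i, eps))$objective
      o2 <- retiKAN:::.ckanGrad(z, y01, cfg, setter(params, i, -eps))$objective
      gn[i] <- (o1 - o2) / (2 * eps)
    }
    max(abs(gn - analytic)) / max(abs(gn))
  }
  setCoef <- function(p, i, e) { p$bank@coefficients[i] <- p$bank@coefficients[i] + e; p }
  expect_lt(fd(setCoef, res$grads$coef), 1e-4)
  setDw <- function(p, i, e) { p$dw[i] <- p$dw[i] + e; p }
  expect_lt(fd(setDw, res$grads$dw), 1e-4)
  setW5 <- function(p, i, e) { p$W5[i] <- p$W5[i] + e; p }
  expect_lt(fd(setW5, res$grads$W5), 1e-4)
})

test_that("the cKAN head is smaller than a dense head on the same input", {
  counts <- ckanCountParamsFlops(ckanConfig(), grid = 14)
  expect_lt(counts["params"], counts["denseParams"])
})

test_that("the head learns a separable five-class problem where a linear oracle does", {
  set.seed(6)
  n <- 500; C <- 16
  lab <- sample(0:4, n, replace = TRUE)
  z <- array(rnorm(n * 4 * 4 * C, 0, 0.3), c(n, 4, 4, C))
  for (i in seq_len(n)) z[i, , , lab[i] + 1] <- z[i, , , lab[i] + 1] + 2
  cfg <- ckanConfig(inChannels = C, condensedChannels = 8, outChannels = 16,
                    hiddenUnits = 16)
  tr <- trainHead(z, lab, cfg, epochs = 30, batchSize = 32, lr = 3e-3,
                  seed = 1)
  acc <- mean(predictHead(z, cfg, tr$params, "class") == lab)
  expect_gte(acc, 0.95)
  ## logistic-regression oracle on pooled features also solves it
  G <- apply(z, c(1, 4), mean)
  or <- nnet::multinom(lab ~ G, trace = FALSE, maxit = 200)
  expect_gte(mean(predict(or) == lab), 0.95)
})

test_that("training is reproducible and guards degenerate inputs", {
  set.seed(7)
  z <- array(rnorm(30 * 3 * 3 * 6), c(30, 3, 3, 6))
  lab <- rep(0:4, 6)
  cfg <- ckanConfig(inChannels = 6, condensedChannels = 3, outChannels = 6,
                    hiddenUnits = 4)
  h1 <- trainHead(z, lab, cfg, epochs = 4, batchSize = 8, seed = 9)$history
  h2 <- trainHead(z, lab, cfg, epochs = 4, batchSize = 8, seed = 9)$history
  expect_identical(h1, h2)
  expect_error(trainHead(z[0, , , , drop = FALSE], integer(0), cfg), "empty")
  expect_error(trainHead(z, rep(1, 30), cfg), "2 classes")
})

test_that("head checkpoints round-trip parameters through JSON", {
  cfg <- ckanConfig(inChannels = 6, condensedChannels = 3, outChannels = 6,
                    hiddenUnits = 4)
  params <- ckanInit(cfg, seed = 8)
  params$norm <- list(mu = numeric(3), sd = rep(1, 3))
  path <- file.path(withr::local_tempdir(), "head.json")
  saveCkanCheckpoint(params, cfg, path)
  back <- loadCkanCheckpoint(path)
  z <- array(rnorm(2 * 4 * 4 * 6), c(2, 4, 4, 6))
  expect_equal(ckanForward(z, cfg, params), ckanForward(z, back$cfg, back$params),
               tolerance = 1e-12)
})
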