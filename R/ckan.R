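## Convolutional Kolmogorov-Arnold classification head. Five-stage tensor
## flow: 1x1 channel condenser (256 -> 128), depthwise conv + per-channel
## learnable cubic B-spline functions (the univariate function bank), 1x1
## superposition mixer (128 -> 256), global average pooling, and a hidden
## linear projection + softmax to 5 severity grades. Training minimizes
## cross-entropy plus lambda * (mu1 * L1 + mu2 * entropy) over the spline
## coefficients, with Adam, dropout and early stopping. Gradients are
## analytic (hand-derived backprop); a finite-difference check guards them
## in the test suite.

## ---- spline bank -------------------------------------------------------

.fullKnots <- function(breaks, degree = 3)
  c(rep(breaks[1], degree), breaks, rep(breaks[length(breaks)], degree))

.grevilleCoefs <- function(breaks, degree = 3) {
  kn <- .fullKnots(breaks, degree)
  nb <- length(breaks) + degree - 1
  vapply(seq_len(nb), function(i) mean(kn[(i + 1):(i + degree)]), numeric(1))
}

#' Construct a per-channel spline bank
#'
#' Each of `nChannels` channels owns one univariate function in a clamped
#' cubic B-spline basis on `nKnots` equally spaced breakpoints spanning
#' `interval`. By default coefficients are the Greville abscissae, which
#' reproduce the identity function exactly on the knot span -- the standard
#' near-linear initialization for learnable spline activations.
#'
#' @param nChannels number of channels (univariate functions).
#' @param nKnots number of breakpoints (default 8).
#' @param interval input interval (default c(-2, 2)).
#' @param coefficients optional channels x nBasis matrix; "identity"
#'   (default) uses the Greville abscissae.
#' @return a [SplineBank-class].
#' @export
splineBank <- function(nChannels, nKnots = 8, interval = c(-2, 2),
                       coefficients = "identity") {
  if (nKnots < 4) stop("need at least 4 knots for a cubic spline")
  breaks <- seq(interval[1], interval[2], length.out = nKnots)
  if (any(diff(breaks) <= 0)) stop("knots must be strictly increasing")
  nb <- nKnots + 2
  if (identical(coefficients, "identity")) {
    coefficients <- matrix(rep(.grevilleCoefs(breaks), each = nChannels),
                           nrow = nChannels)
  }
  new("SplineBank", knots = breaks, order = 3L,
      coefficients = coefficients, interval = as.numeric(interval))
}

#' Evaluate the clamped cubic B-spline basis
#'
#' Returns the basis-value matrix for a numeric vector of evaluation
#' points. Inside the knot span the basis values are nonnegative and sum to
#' one (partition of unity); points outside the span are clamped to the
#' nearest boundary, so the spline functions extrapolate by their boundary
#' value (and have zero derivative outside).
#'
#' @param x numeric vector of evaluation points.
#' @param bank a [SplineBank-class].
#' @param deriv if TRUE also return the basis derivative matrix (zero
#'   outside the span, reflecting the clamping).
#' @return a length(x) x nBasis matrix, or a list(basis, deriv) when
#'   `deriv` is TRUE.
#' @export
splineBasis <- function(x, bank, deriv = FALSE) {
  stopifnot(is(bank, "SplineBank"))
  kn <- .fullKnots(bank@knots)
  lo <- bank@interval[1]; hi <- bank@interval[2]
  inside <- x >= lo & x <= hi
  xc <- clipRange(x, lo, hi)
  B <- splines::splineDesign(kn, xc, ord = 4L)
  if (!deriv) return(B)
  D <- splines::splineDesign(kn, xc, ord = 4L, derivs = rep(1L, length(xc)))
  D[!inside, ] <- 0
  list(basis = B, deriv = D)
}

## ---- fast local evaluation ---------------------------------------------
## At any point only 4 cubic basis functions are nonzero; per knot interval
## they are fixed cubic polynomials. The per-interval polynomial
## coefficients are recovered exactly from the reference basis once per
## knot grid and cached, giving a closed-form vectorized evaluation used by
## the forward/backward passes (splineBasis stays the dense reference).

.polyCache <- new.env(parent = emptyenv())

.bankPoly <- function(bank) {
  key <- paste(c(bank@knots, bank@interval), collapse = "_")
  hit <- .polyCache[[key]]
  if (!is.null(hit)) return(hit)
  br <- bank@knots
  nInt <- length(br) - 1
  P <- array(0, c(nInt, 4, 4))            # interval x local basis x power
  for (j in seq_len(nInt)) {
    pts <- seq(br[j], br[j + 1], length.out = 4)
    B <- splineBasis(pts, bank)[, j:(j + 3), drop = FALSE]
    V <- outer(pts, 0:3, "^")
    P[j, , ] <- t(solve(V, B))
  }
  Pd <- array(0, c(nInt, 4, 3))           # derivative polynomials
  for (k in 1:3) Pd[, , k] <- P[, , k + 1] * k
  res <- list(breaks = br, P = P, Pd = Pd, nInt = nInt)
  .polyCache[[key]] <- res
  res
}

## Evaluate all channel splines at the entries of an n x C matrix.
## Returns values, optionally derivatives, and the local-basis bookkeeping
## needed for the coefficient gradient.
.splineApplyFast <- function(xmat, bank, deriv = FALSE) {
  n <- nrow(xmat); C <- ncol(xmat)
  coefs <- bank@coefficients
  pol <- .bankPoly(bank)
  lo <- bank@interval[1]; hi <- bank@interval[2]
  xv <- as.vector(xmat)
  inside <- xv >= lo & xv <= hi
  xc <- clipRange(xv, lo, hi)
  j <- findInterval(xc, pol$breaks, all.inside = TRUE)
  x2 <- xc * xc; x3 <- x2 * xc
  chanIdx <- rep(seq_len(C), each = n)
  B4 <- matrix(0, length(xv), 4)
  sVec <- numeric(length(xv))
  dVec <- if (deriv) numeric(length(xv)) else NULL
  for (k in 1:4) {
    Pk <- matrix(pol$P[, k, ], nrow = pol$nInt)
    B4[, k] <- Pk[j, 1] + Pk[j, 2] * xc + Pk[j, 3] * x2 + Pk[j, 4] * x3
    ck <- coefs[chanIdx + nrow(coefs) * (j + k - 2)]
    sVec <- sVec + B4[, k] * ck
    if (deriv) {
      Pdk <- matrix(pol$Pd[, k, ], nrow = pol$nInt)
      dVec <- dVec + ((Pdk[j, 1] + Pdk[j, 2] * xc + Pdk[j, 3] * x2) *
                        inside) * ck
    }
  }
  list(S = matrix(sVec, n, C),
       Sp = if (deriv) matrix(dVec, n, C) else NULL,
       B4 = B4, j = j, chanIdx = chanIdx, n = n, C = C)
}

## Gradient of the loss w.r.t. the coefficient matrix given upstream dS.
.splineCoefGrad <- function(fwd, dS, nBasis) {
  C <- fwd$C
  g <- numeric(C * nBasis)
  v <- as.vector(dS)
  for (k in 1:4) {
    grp <- fwd$chanIdx + C * (fwd$j + k - 2)
    acc <- rowsum(v * fwd$B4[, k], grp)
    g[as.integer(rownames(acc))] <- g[as.integer(rownames(acc))] + acc
  }
  matrix(g, C, nBasis)
}

#' Apply a spline bank channel-wise
#'
#' Evaluates channel c's spline function at every entry of column c.
#'
#' @param xmat n x channels numeric matrix.
#' @param bank a [SplineBank-class] with matching channel count.
#' @return n x channels matrix of function values.
#' @export
splineApply <- function(xmat, bank) {
  stopifnot(nrow(bank@coefficients) == ncol(xmat))
  .splineApplyFast(xmat, bank)$S
}

## ---- head parameters ---------------------------------------------------

#' Initialize cKAN head parameters
#'
#' Condenser and mixer 1x1 convolutions and the projection head are
#' He-initialized; the depthwise kernel starts as the identity stencil
#' (center 1) plus small noise; spline coefficients start at the identity
#' function (Greville abscissae). The spline-input normalization statistics
#' (`norm`) are estimated later by [trainHead()] and frozen.
#'
#' @param cfg a [CkanConfig-class].
#' @param seed integer seed.
#' @return a named parameter list.
#' @export
ckanInit <- function(cfg, seed = 1) {
  stopifnot(is(cfg, "CkanConfig"))
  withSeed(seed, {
    ci <- cfg@inChannels; cd <- cfg@condensedChannels
    co <- cfg@outChannels; hu <- cfg@hiddenUnits; nc <- cfg@nClasses
    dw <- matrix(rnorm(9 * cd, 0, 0.01), 9, cd)
    dw[5, ] <- dw[5, ] + 1                 # identity stencil
    bank <- splineBank(cd, cfg@nKnots, cfg@splineInterval)
    list(W1 = .heMat(ci, cd), b1 = numeric(cd),
         dw = dw,
         bank = bank,
         W3 = .heMat(cd, co), b3 = numeric(co),
         W4 = .heMat(co, hu), b4 = numeric(hu),
         W5 = .heMat(hu, nc), b5 = numeric(nc),
         norm = NULL)
  })
}

## Depthwise 3x3, stride 1, same padding, on (B,H,W,C): shared by forward
## and backward passes of the head.
.dw3 <- function(x, w) .dwconv2d(x, w, 3, 1, 1)

## ---- forward -----------------------------------------------------------

#' cKAN head forward pass
#'
#' Stage 1: 1x1 channel condenser; stage 2: depthwise 3x3 convolution
#' followed by the learnable per-channel spline functions (inputs
#' standardized by frozen normalization statistics so they fall inside the
#' spline interval); stage 3: 1x1 superposition mixer; stage 4: global
#' average pooling; stage 5: hidden linear layer (ReLU, dropout during
#' training) and softmax over the severity grades. Every output row sums
#' to one.
#'
#' @param z a [FeatureMap-class] or rank-4 array, batch x H x W x
#'   `cfg@inChannels`.
#' @param cfg a [CkanConfig-class].
#' @param params parameter list from [ckanInit()] (or trained).
#' @param training apply dropout stochastically.
#' @param returnIntermediates also return the per-stage tensors.
#' @return batch x nClasses probability matrix, or a list with elements
#'   `probs`, `stage1` ... `stage4` when `returnIntermediates` is TRUE.
#' @export
ckanForward <- function(z, cfg, params, training = FALSE,
                        returnIntermediates = FALSE) {
  arr <- if (is(z, "FeatureMap")) z@data else z
  d <- dim(arr)
  if (length(d) != 4 || d[4] != cfg@inChannels)
    stop(sprintf("stage 1 (channel condenser): expected %d input channels, got %d",
                 cfg@inChannels, d[4]))
  B <- d[1]; HW <- d[2] * d[3]
  Zm <- matrix(arr, ncol = d[4])
  H1 <- sweep(Zm %*% params$W1, 2, params$b1, "+")     # stage 1
  nrm <- params$norm
  if (is.null(nrm))
    nrm <- list(mu = colMeans(H1), sd = pmax(apply(H1, 2, sd), 1e-6))
  U0 <- sweep(sweep(H1, 2, nrm$mu, "-"), 2, nrm$sd, "/")
  u4 <- array(U0, c(B, d[2], d[3], cfg@condensedChannels))
  V <- .dw3(u4, params$dw)                             # stage 2a: depthwise
  Vm <- matrix(V, ncol = cfg@condensedChannels)
  S <- splineApply(Vm, params$bank)                    # stage 2b: splines
  M <- sweep(S %*% params$W3, 2, params$b3, "+")       # stage 3
  ## stage 4: global average pooling over the spatial axes
  M4 <- array(M, c(B, HW, cfg@outChannels))
  G <- colSums(aperm(M4, c(2, 1, 3)), dims = 1) / HW
  H4 <- .relu(sweep(G %*% params$W4, 2, params$b4, "+"))
  if (training && cfg@dropout > 0) {
    keep <- 1 - cfg@dropout
    mask <- matrix(runif(length(H4)), nrow(H4)) < keep
    H4 <- H4 * mask / keep
  }
  logits <- sweep(H4 %*% params$W5, 2, params$b5, "+")
  probs <- .softmaxRows(logits)
  if (!returnIntermediates) return(probs)
  list(probs = probs,
       stage1 = array(H1, c(B, d[2], d[3], cfg@condensedChannels)),
       stage2 = array(S, c(B, d[2], d[3], cfg@condensedChannels)),
       stage2input = V,
       stage3 = array(M, c(B, d[2], d[3], cfg@outChannels)),
       stage4 = G)
}

## ---- regularizer -------------------------------------------------------

#' Spline-coefficient regularizer
#'
#' `mu1 * mean(|phi|) + mu2 * mean_over_banks(S(phi))`, where each
#' channel's coefficient vector is one bank and `S` is the Shannon entropy
#' of the normalized absolute-coefficient distribution (0 log 0 := 0, and
#' an all-zero bank contributes zero entropy). Nonnegative by construction.
#'
#' @param banks a [SplineBank-class], a coefficient matrix (channels x
#'   nBasis), or a list of either.
#' @param mu1,mu2 nonnegative weights.
#' @return a nonnegative scalar.
#' @export
splineRegularizer <- function(banks, mu1 = 1, mu2 = 1) {
  stopifnot(mu1 >= 0, mu2 >= 0)
  coefs <- .coefMatrix(banks)
  a <- abs(coefs)
  l1 <- mean(a)
  rowT <- rowSums(a)
  ent <- vapply(seq_len(nrow(a)), function(i) {
    if (rowT[i] == 0) return(0)
    p <- a[i, ] / rowT[i]
    p <- p[p > 0]
    -sum(p * log(p))
  }, numeric(1))
  mu1 * l1 + mu2 * mean(ent)
}

.coefMatrix <- function(banks) {
  if (is(banks, "SplineBank")) return(banks@coefficients)
  if (is.matrix(banks)) return(banks)
  if (is.list(banks)) return(do.call(rbind, lapply(banks, .coefMatrix)))
  stop("banks must be a SplineBank, a coefficient matrix, or a list of them")
}

## Gradient of the regularizer w.r.t. the coefficient matrix.
.regGrad <- function(coefs, mu1, mu2) {
  a <- abs(coefs)
  sg <- sign(coefs)
  gL1 <- mu1 * sg / length(coefs)
  gEnt <- matrix(0, nrow(coefs), ncol(coefs))
  for (i in seq_len(nrow(coefs))) {
    Tt <- sum(a[i, ])
    if (Tt == 0) next
    al <- a[i, ]
    la <- ifelse(al > 0, log(al), 0)
    slog <- sum(al * la) / Tt
    g <- (slog - la) / Tt                  # d entropy / d |c_k|
    g[al == 0] <- 0
    gEnt[i, ] <- sg[i, ] * g
  }
  gL1 + mu2 * gEnt / nrow(coefs)
}

## ---- objective + analytic gradients ------------------------------------

#' Training objective of the cKAN head
#'
#' `O_total = O_pred + lambda * regularizer`, where `O_pred` is the mean
#' cross-entropy of the severity predictions and the regularizer is
#' [splineRegularizer()] over the spline banks. With `lambda = 0` the
#' objective equals the prediction loss exactly.
#'
#' @param z features (rank-4 array or [FeatureMap-class]).
#' @param labels integer grades 0..(nClasses-1).
#' @param cfg a [CkanConfig-class].
#' @param params parameter list.
#' @return list(objective, predLoss, regularizer).
#' @export
ckanObjective <- function(z, labels, cfg, params) {
  probs <- ckanForward(z, cfg, params)
  n <- nrow(probs)
  idx <- cbind(seq_len(n), as.integer(labels) + 1L)
  pred <- -mean(log(pmax(probs[idx], 1e-12)))
  reg <- splineRegularizer(params$bank, cfg@mu1, cfg@mu2)
  list(objective = pred + cfg@lambda * reg, predLoss = pred, regularizer = reg)
}

## Forward + backward in one pass. Returns loss components and gradients
## for every trainable parameter. `dropMask` (n x hidden) is supplied by
## the training loop when dropout is active so forward and backward agree.
.ckanGrad <- function(arr, y01, cfg, params, dropMask = NULL) {
  d <- dim(arr)
  B <- d[1]; HW <- d[2] * d[3]
  cd <- cfg@condensedChannels; co <- cfg@outChannels
  Zm <- matrix(arr, ncol = d[4])
  H1 <- sweep(Zm %*% params$W1, 2, params$b1, "+")
  nrm <- params$norm
  U0 <- sweep(sweep(H1, 2, nrm$mu, "-"), 2, nrm$sd, "/")
  u4 <- array(U0, c(B, d[2], d[3], cd))
  V <- .dw3(u4, params$dw)
  Vm <- matrix(V, ncol = cd)
  bk <- params$bank
  sf <- .splineApplyFast(Vm, bk, deriv = TRUE)
  S <- sf$S; Sp <- sf$Sp
  M <- sweep(S %*% params$W3, 2, params$b3, "+")
  M4 <- array(M, c(B, HW, co))
  G <- colSums(aperm(M4, c(2, 1, 3)), dims = 1) / HW
  A4 <- sweep(G %*% params$W4, 2, params$b4, "+")
  H4 <- .relu(A4)
  keep <- 1 - cfg@dropout
  H4d <- if (!is.null(dropMask)) H4 * dropMask / keep else H4
  logits <- sweep(H4d %*% params$W5, 2, params$b5, "+")
  probs <- .softmaxRows(logits)
  idx <- cbind(seq_len(B), max.col(y01, ties.method = "first"))
  predLoss <- -mean(log(pmax(probs[idx], 1e-12)))
  reg <- splineRegularizer(bk, cfg@mu1, cfg@mu2)

  ## backward
  dLogits <- (probs - y01) / B
  gW5 <- crossprod(H4d, dLogits); gb5 <- colSums(dLogits)
  dH4d <- dLogits %*% t(params$W5)
  dH4 <- if (!is.null(dropMask)) dH4d * dropMask / keep else dH4d
  dA4 <- dH4 * (A4 > 0)
  gW4 <- crossprod(G, dA4); gb4 <- colSums(dA4)
  dG <- dA4 %*% t(params$W4)
  ## GAP backward: spread evenly over spatial positions (rows are
  ## batch-fastest, matching the forward flattening)
  dM <- dG[rep(seq_len(B), HW), , drop = FALSE] / HW
  gW3 <- crossprod(S, dM); gb3 <- colSums(dM)
  dS <- dM %*% t(params$W3)
  ## spline backward: coefficients and inputs
  gCoef <- .splineCoefGrad(sf, dS, ncol(bk@coefficients)) +
    cfg@lambda * .regGrad(bk@coefficients, cfg@mu1, cfg@mu2)
  dV <- dS * Sp
  dV4 <- array(dV, c(B, d[2], d[3], cd))
  ## depthwise backward: weight gradient by shifted sums; input gradient is
  ## a correlation with the flipped kernel (same-padding, stride 1)
  up <- .padSpatial(u4, 1)
  gdw <- matrix(0, 9, cd)
  for (ki in 1:3) for (kj in 1:3) {
    ii <- ki + (seq_len(d[2]) - 1); jj <- kj + (seq_len(d[3]) - 1)
    gdw[ki + (kj - 1) * 3, ] <-
      colSums(matrix(up[, ii, jj, , drop = FALSE] * dV4, ncol = cd))
  }
  dU0 <- matrix(.dwconv2d(dV4, params$dw[9:1, , drop = FALSE], 3, 1, 1),
                ncol = cd)
  dH1 <- sweep(dU0, 2, nrm$sd, "/")
  gW1 <- crossprod(Zm, dH1); gb1 <- colSums(dH1)

  list(objective = predLoss + cfg@lambda * reg, predLoss = predLoss,
       regularizer = reg, probs = probs,
       grads = list(W1 = gW1, b1 = gb1, dw = gdw, coef = gCoef,
                    W3 = gW3, b3 = gb3, W4 = gW4, b4 = gb4,
                    W5 = gW5, b5 = gb5))
}

## ---- training ----------------------------------------------------------

.adamStep <- function(state, g, lr, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  state$m <- b1 * state$m + (1 - b1) * g
  state$v <- b2 * state$v + (1 - b2) * g^2
  state$t <- state$t + 1
  mh <- state$m / (1 - b1^state$t)
  vh <- state$v / (1 - b2^state$t)
  state$delta <- lr * mh / (sqrt(vh) + eps)
  state
}

#' Train the cKAN head
#'
#' Minimizes the regularized objective (cross-entropy plus
#' `lambda * regularizer`) with Adam over minibatches; dropout on the
#' hidden layer; optional early stopping on validation loss. The
#' spline-input normalization statistics are estimated once from the full
#' training set before the first update and then frozen. Reproducible
#' given `seed`.
#'
#' @param features rank-4 array or [FeatureMap-class] of training features.
#' @param labels integer grades 0..(nClasses-1).
#' @param cfg a [CkanConfig-class].
#' @param epochs maximum training epochs.
#' @param batchSize minibatch size.
#' @param lr Adam learning rate.
#' @param weightDecay decoupled weight decay on the dense parameters.
#' @param valFeatures,valLabels optional validation split for early
#'   stopping.
#' @param patience early-stopping patience in epochs.
#' @param seed integer seed.
#' @param params optional warm-start parameters.
#' @return list(params, history) where history is a data.frame with one
#'   row per epoch (trainLoss, predLoss, and validation columns when a
#'   validation split is given).
#' @export
trainHead <- function(features, labels, cfg = ckanConfig(), epochs = 30,
                      batchSize = 16, lr = 1e-3, weightDecay = 0,
                      valFeatures = NULL, valLabels = NULL, patience = 5,
                      seed = 1, params = NULL) {
  arr <- if (is(features, "FeatureMap")) features@data else features
  n <- dim(arr)[1]
  if (n == 0) stop("empty training set")
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2)
    stop("need at least 2 classes present to train")
  nc <- cfg@nClasses
  y01 <- matrix(0, n, nc); y01[cbind(seq_len(n), labels + 1L)] <- 1
  valArr <- if (is(valFeatures, "FeatureMap")) valFeatures@data else valFeatures

  withSeed(seed, {
    if (is.null(params)) params <- ckanInit(cfg, seed = childSeed(seed, 1))
    if (is.null(params$norm)) {
      H1 <- sweep(matrix(arr, ncol = dim(arr)[4]) %*% params$W1, 2,
                  params$b1, "+")
      params$norm <- list(mu = colMeans(H1), sd = pmax(apply(H1, 2, sd), 1e-6))
    }
    pn <- c("W1", "b1", "dw", "coef", "W3", "b3", "W4", "b4", "W5", "b5")
    getP <- function(nm) if (nm == "coef") params$bank@coefficients else params[[nm]]
    adam <- lapply(pn, function(nm) {
      p <- getP(nm)
      list(m = p * 0, v = p * 0, t = 0)
    })
    names(adam) <- pn
    decayed <- c("W1", "W3", "W4", "W5")
    history <- data.frame()
    bestVal <- Inf; bestParams <- params; wait <- 0
    for (ep in seq_len(epochs)) {
      ord <- sample(n)
      epLoss <- 0; epPred <- 0; nb <- 0
      for (s0 in seq(1, n, by = batchSize)) {
        sel <- ord[s0:min(n, s0 + batchSize - 1)]
        zb <- arr[sel, , , , drop = FALSE]
        yb <- y01[sel, , drop = FALSE]
        dropMask <- if (cfg@dropout > 0)
          matrix(runif(length(sel) * cfg@hiddenUnits),
                 length(sel)) < (1 - cfg@dropout) else NULL
        res <- .ckanGrad(zb, yb, cfg, params, dropMask)
        for (nm in pn) {
          g <- res$grads[[nm]]
          if (nm %in% decayed && weightDecay > 0)
            g <- g                          # decoupled decay applied below
          adam[[nm]] <- .adamStep(adam[[nm]], g, lr)
          p <- getP(nm) - adam[[nm]]$delta
          if (nm %in% decayed && weightDecay > 0) p <- p - lr * weightDecay * p
          if (nm == "coef") params$bank@coefficients <- p else params[[nm]] <- p
        }
        epLoss <- epLoss + res$objective; epPred <- epPred + res$predLoss
        nb <- nb + 1
      }
      row <- data.frame(epoch = ep, trainLoss = epLoss / nb,
                        predLoss = epPred / nb)
      if (!is.null(valArr)) {
        vp <- ckanForward(valArr, cfg, params)
        vi <- cbind(seq_len(nrow(vp)), as.integer(valLabels) + 1L)
        row$valLoss <- -mean(log(pmax(vp[vi], 1e-12)))
        row$valAcc <- mean(max.col(vp, ties.method = "first") - 1L ==
                             as.integer(valLabels))
        if (row$valLoss < bestVal - 1e-9) {
          bestVal <- row$valLoss; bestParams <- params; wait <- 0
        } else {
          wait <- wait + 1
        }
      }
      history <- rbind(history, row)
      if (!is.null(valArr) && wait >= patience) break
    }
    if (!is.null(valArr)) params <- bestParams
    list(params = params, history = history)
  })
}

#' Predict severity probabilities / grades
#'
#' @param features rank-4 array or [FeatureMap-class].
#' @param cfg a [CkanConfig-class].
#' @param params trained parameters.
#' @param type "prob" for the probability matrix, "class" for hard grades
#'   0..(nClasses-1).
#' @return matrix of probabilities or integer vector of grades.
#' @export
predictHead <- function(features, cfg, params, type = c("prob", "class")) {
  type <- match.arg(type)
  probs <- ckanForward(features, cfg, params)
  if (type == "prob") return(probs)
  max.col(probs, ties.method = "first") - 1L
}

#' Analytic parameter/FLOPs count of the cKAN head
#'
#' Layer-by-layer accounting on a g x g spatial grid; `denseParams` gives
#' the parameter count of the dense alternative (flatten + linear to the
#' class scores) for the same input, against which the cKAN head's
#' parameter efficiency is measured.
#'
#' @param cfg a [CkanConfig-class].
#' @param grid spatial grid side (14 for 224-pixel inputs).
#' @return named numeric c(params, flops, denseParams).
#' @export
ckanCountParamsFlops <- function(cfg, grid = 14) {
  ci <- cfg@inChannels; cd <- cfg@condensedChannels
  co <- cfg@outChannels; hu <- cfg@hiddenUnits; nc <- cfg@nClasses
  nb <- cfg@nKnots + 2
  HW <- grid^2
  params <- (ci * cd + cd) +              # condenser
    9 * cd +                              # depthwise 3x3
    cd * nb +                             # spline coefficients
    (cd * co + co) +                      # mixer
    (co * hu + hu) + (hu * nc + nc)       # projection head
  flops <- convFlops(grid, grid, ci, cd) +
    convFlops(grid, grid, cd, cd, 3, groups = cd) +
    2 * HW * cd * nb +                    # basis expansion + weighting
    convFlops(grid, grid, cd, co) +
    linearFlops(co, hu) + linearFlops(hu, nc)
  dense <- HW * ci * nc + nc
  c(params = params, flops = flops, denseParams = dense)
}

#' Save / load a cKAN head checkpoint
#'
#' Plain-text JSON with parameters and config embedded.
#'
#' @param params trained parameter list.
#' @param cfg a [CkanConfig-class].
#' @param path file path.
#' @return the path (save) or list(params, cfg) (load).
#' @export
saveCkanCheckpoint <- function(params, cfg, path) {
  ser <- list(
    config = list(inChannels = cfg@inChannels,
                  condensedChannels = cfg@condensedChannels,
                  outChannels = cfg@outChannels, nClasses = cfg@nClasses,
                  hiddenUnits = cfg@hiddenUnits, lambda = cfg@lambda,
                  mu1 = cfg@mu1, mu2 = cfg@mu2, dropout = cfg@dropout,
                  nKnots = cfg@nKnots, splineInterval = cfg@splineInterval),
    W1 = params$W1, b1 = params$b1, dw = params$dw,
    coefficients = params$bank@coefficients,
    W3 = params$W3, b3 = params$b3, W4 = params$W4, b4 = params$b4,
    W5 = params$W5, b5 = params$b5, norm = params$norm)
  jsonlite::write_json(ser, path, digits = NA)
  invisible(path)
}

#' @rdname saveCkanCheckpoint
#' @export
loadCkanCheckpoint <- function(path) {
  ck <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfgl <- as.list(ck$config)
  cfg <- ckanConfig(cfgl$inChannels, cfgl$condensedChannels, cfgl$outChannels,
                    cfgl$nClasses, cfgl$hiddenUnits, cfgl$lambda, cfgl$mu1,
                    cfgl$mu2, cfgl$dropout, cfgl$nKnots, cfgl$splineInterval)
  bank <- splineBank(cfg@condensedChannels, cfg@nKnots, cfg@splineInterval,
                     coefficients = as.matrix(ck$coefficients))
  params <- list(W1 = as.matrix(ck$W1), b1 = as.numeric(ck$b1),
                 dw = as.matrix(ck$dw), bank = bank,
                 W3 = as.matrix(ck$W3), b3 = as.numeric(ck$b3),
                 W4 = as.matrix(ck$W4), b4 = as.numeric(ck$b4),
                 W5 = as.matrix(ck$W5), b5 = as.numeric(ck$b5),
                 norm = if (!is.null(ck$norm))
                   list(mu = as.numeric(ck$norm$mu), sd = as.numeric(ck$norm$sd))
                 else NULL)
  list(params = params, cfg = cfg)
}
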