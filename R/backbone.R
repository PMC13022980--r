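## Toy-scale hybrid feature extractor: a 3-stage ShuffleNet-V2-style
## convolutional stack (stage repeats 2/4/2, stride-2 stem + pool) followed
## by one LeViT-style multi-head self-attention block at the coarsest grid,
## then a fixed 1x1 projection to 256 channels. A single layout structure
## drives weight initialization, the forward pass and the analytic
## parameter/FLOPs accounting, so the three can never drift apart.
##
## FLOPs convention: 1 multiply-accumulate = 2 FLOPs.

#' Analytic FLOPs of a convolution layer
#'
#' `2 * hOut * wOut * cOut * (k^2 * cIn / groups)` with the
#' 1 MAC = 2 FLOPs convention.
#'
#' @param hOut,wOut output spatial size.
#' @param cIn,cOut input/output channels.
#' @param k kernel size.
#' @param groups convolution groups (cIn for depthwise).
#' @return FLOPs as a double (exact integer value).
#' @export
convFlops <- function(hOut, wOut, cIn, cOut, k = 1, groups = 1)
  2 * hOut * wOut * cOut * (k^2 * cIn / groups)

#' Analytic FLOPs of a linear layer
#'
#' `2 * nIn * nOut` per token/sample.
#'
#' @param nIn,nOut input/output features.
#' @param n number of tokens/samples the layer is applied to.
#' @return FLOPs as a double.
#' @export
linearFlops <- function(nIn, nOut, n = 1) 2 * n * nIn * nOut

.evenRound <- function(x) {
  y <- round(x)
  y + (y %% 2)
}

.convDesc <- function(name, k, cin, cout, stride, pad, hin, groups = 1,
                      bias = TRUE) {
  hout <- (hin + 2 * pad - k) %/% stride + 1
  list(op = "conv", name = name, k = k, cin = cin, cout = cout,
       stride = stride, pad = pad, hin = hin, hout = hout, groups = groups,
       bias = bias,
       params = k^2 * cin * cout / groups + if (bias) cout else 0,
       flops = convFlops(hout, hout, cin, cout, k, groups))
}

.linDesc <- function(name, nin, nout, n, bias = TRUE)
  list(op = "linear", name = name, nin = nin, nout = nout, n = n, bias = bias,
       params = nin * nout + if (bias) nout else 0,
       flops = linearFlops(nin, nout, n))

## Full nested layout for a given configuration.
.backboneLayout <- function(cfg) {
  stopifnot(is(cfg, "BackboneConfig"))
  s <- cfg@inputSize
  k <- cfg@depthwiseKernel
  pd <- (k - 1) %/% 2
  stageC <- .evenRound(c(48, 96) * cfg@widthMultiplier)
  stemC <- 24L
  d <- cfg@embedDim

  unitBasic <- function(cin, hin, tag) {
    ch <- cin %/% 2                      # right branch operates on half
    list(kind = "basic", cin = cin, hin = hin, hout = hin, layers = list(
      pw1 = .convDesc(paste0(tag, ".pw1"), 1, ch, ch, 1, 0, hin),
      dw  = .convDesc(paste0(tag, ".dw"), k, ch, ch, 1, pd, hin, groups = ch,
                      bias = FALSE),
      pw2 = .convDesc(paste0(tag, ".pw2"), 1, ch, ch, 1, 0, hin)))
  }
  unitDown <- function(cin, cout, hin, tag) {
    ch <- cout %/% 2
    hout <- hin %/% 2
    list(kind = "down", cin = cin, cout = cout, hin = hin, hout = hout,
      layers = list(
        l.dw  = .convDesc(paste0(tag, ".l.dw"), k, cin, cin, 2, pd, hin,
                          groups = cin, bias = FALSE),
        l.pw  = .convDesc(paste0(tag, ".l.pw"), 1, cin, ch, 1, 0, hout),
        r.pw1 = .convDesc(paste0(tag, ".r.pw1"), 1, cin, ch, 1, 0, hin),
        r.dw  = .convDesc(paste0(tag, ".r.dw"), k, ch, ch, 2, pd, hin,
                          groups = ch, bias = FALSE),
        r.pw2 = .convDesc(paste0(tag, ".r.pw2"), 1, ch, ch, 1, 0, hout)))
  }

  h <- s %/% 2                            # after stem
  hp <- h %/% 2                           # after pool
  stage1 <- list(unitDown(stemC, stageC[1], hp, "s1u1"),
                 unitBasic(stageC[1], hp %/% 2, "s1u2"))
  h1 <- hp %/% 2
  stage2 <- c(list(unitDown(stageC[1], stageC[2], h1, "s2u1")),
              lapply(2:4, function(i) unitBasic(stageC[2], h1 %/% 2,
                                                paste0("s2u", i))))
  h2 <- h1 %/% 2
  stage3 <- lapply(1:2, function(i) unitBasic(stageC[2], h2, paste0("s3u", i)))
  g <- h2                                 # final grid (inputSize / 16)
  N <- g * g

  attn <- list(
    tokenProj = .linDesc("attn.tokenProj", stageC[2], d, N),
    qkv = .linDesc("attn.qkv", d, 3 * d, N),
    scores = list(op = "matmul", name = "attn.scores", params = 0,
                  flops = 2 * N * N * d),
    av = list(op = "matmul", name = "attn.av", params = 0,
              flops = 2 * N * N * d),
    proj = .linDesc("attn.proj", d, d, N),
    ffn1 = .linDesc("attn.ffn1", d, 2 * d, N),
    ffn2 = .linDesc("attn.ffn2", 2 * d, d, N),
    outProj = .linDesc("attn.outProj", d, 256, N))

  list(cfg = cfg,
       stem = .convDesc("stem", 3, 3, stemC, 2, 1, s),
       stages = list(stage1, stage2, stage3),
       attn = attn, grid = g, stageC = stageC, stemC = stemC)
}

.layoutLeaves <- function(node) {
  if (is.list(node) && !is.null(node$op)) return(list(node))
  if (is.list(node)) return(do.call(c, lapply(node, .layoutLeaves)))
  list()
}

#' Analytic parameter and FLOPs accounting
#'
#' Walks the backbone layout (and optionally the cKAN head) layer by layer
#' and sums exact parameter counts and forward FLOPs
#' (1 multiply-accumulate = 2 FLOPs; convolution
#' `2 * Hout * Wout * Cout * K^2 * Cin / groups`, linear `2 * in * out`,
#' attention includes the QKV projections and both N x N matmuls).
#'
#' @param cfg a [BackboneConfig-class].
#' @param headCfg optional [CkanConfig-class] to include the classifier
#'   head.
#' @return named numeric c(params, flops), exact integer values.
#' @export
countParamsFlops <- function(cfg, headCfg = NULL) {
  layout <- .backboneLayout(cfg)
  leaves <- c(.layoutLeaves(layout$stem), .layoutLeaves(layout$stages),
              .layoutLeaves(layout$attn))
  params <- sum(vapply(leaves, function(l) l$params, numeric(1)))
  flops <- sum(vapply(leaves, function(l) l$flops, numeric(1)))
  if (!is.null(headCfg)) {
    hc <- ckanCountParamsFlops(headCfg, grid = layout$grid)
    params <- params + hc["params"]
    flops <- flops + hc["flops"]
  }
  c(params = unname(params), flops = unname(flops))
}

## ---- forward-pass primitives ------------------------------------------

.idxCache <- new.env(parent = emptyenv())

.padSpatial <- function(x, pad, fill = 0) {
  if (pad == 0) return(x)
  d <- dim(x)
  xp <- array(fill, c(d[1], d[2] + 2 * pad, d[3] + 2 * pad, d[4]))
  xp[, pad + seq_len(d[2]), pad + seq_len(d[3]), ] <- x
  xp
}

.im2colIdx <- function(B, Hp, Wp, Cin, k, stride, Ho, Wo) {
  key <- paste(B, Hp, Wp, Cin, k, stride, sep = "_")
  if (!is.null(.idxCache[[key]])) return(.idxCache[[key]])
  b <- seq_len(B)
  rowbase <- as.vector(outer(outer(b, B * stride * (seq_len(Ho) - 1), "+"),
                             B * Hp * stride * (seq_len(Wo) - 1), "+"))
  coloff <- as.vector(outer(outer(B * (seq_len(k) - 1),
                                  B * Hp * (seq_len(k) - 1), "+"),
                            B * Hp * Wp * (seq_len(Cin) - 1), "+"))
  idx <- outer(rowbase, coloff, "+")
  if (length(ls(.idxCache)) > 12) rm(list = ls(.idxCache)[1], envir = .idxCache)
  .idxCache[[key]] <- idx
  idx
}

## Full convolution via im2col (used for the 3x3 stem; 1x1 convs take the
## direct matrix-multiply path).
.conv2d <- function(x, W, bias, k, stride, pad) {
  d <- dim(x)
  if (k == 1 && stride == 1) {
    out <- matrix(x, ncol = d[4]) %*% W
    if (!is.null(bias)) out <- sweep(out, 2, bias, "+")
    dim(out) <- c(d[1], d[2], d[3], ncol(W))
    return(out)
  }
  xp <- .padSpatial(x, pad)
  dp <- dim(xp)
  Ho <- (d[2] + 2 * pad - k) %/% stride + 1
  Wo <- (d[3] + 2 * pad - k) %/% stride + 1
  idx <- .im2colIdx(d[1], dp[2], dp[3], d[4], k, stride, Ho, Wo)
  P <- matrix(xp[idx], nrow = nrow(idx))
  out <- P %*% W
  if (!is.null(bias)) out <- sweep(out, 2, bias, "+")
  dim(out) <- c(d[1], Ho, Wo, ncol(W))
  out
}

## Depthwise convolution by k^2 shifted multiply-accumulates.
.dwconv2d <- function(x, w, k, stride, pad) {
  d <- dim(x)
  xp <- .padSpatial(x, pad)
  Ho <- (d[2] + 2 * pad - k) %/% stride + 1
  Wo <- (d[3] + 2 * pad - k) %/% stride + 1
  C <- d[4]
  out <- array(0, c(d[1], Ho, Wo, C))
  nrep <- d[1] * Ho * Wo
  for (ki in seq_len(k)) {
    ii <- ki + stride * (seq_len(Ho) - 1)
    for (kj in seq_len(k)) {
      jj <- kj + stride * (seq_len(Wo) - 1)
      out <- out + xp[, ii, jj, , drop = FALSE] *
        rep(w[ki + (kj - 1) * k, ], each = nrep)
    }
  }
  out
}

.maxpool3 <- function(x) {
  d <- dim(x)
  xp <- .padSpatial(x, 1, fill = -Inf)
  Ho <- d[2] %/% 2
  out <- array(-Inf, c(d[1], Ho, Ho, d[4]))
  for (ki in 1:3) {
    ii <- ki + 2 * (seq_len(Ho) - 1)
    for (kj in 1:3) {
      jj <- kj + 2 * (seq_len(Ho) - 1)
      out <- pmax(out, xp[, ii, jj, , drop = FALSE])
    }
  }
  out
}

.relu <- function(x) pmax(x, 0)

#' Channel shuffle
#'
#' Deterministic channel permutation (reshape-transpose-reshape) enabling
#' information flow between grouped convolutions. Spatial values are
#' untouched; the operation is a pure permutation of channels.
#'
#' @param x a [FeatureMap-class] or rank-4 array (B, H, W, C).
#' @param groups positive integer dividing the channel count.
#' @return same type as the input with channels permuted.
#' @export
channelShuffle <- function(x, groups) {
  arr <- if (is(x, "FeatureMap")) x@data else x
  C <- dim(arr)[4]
  if (C %% groups != 0)
    stop(sprintf("channels (%d) not divisible by groups (%d)", C, groups))
  perm <- as.vector(matrix(seq_len(C), nrow = groups, byrow = TRUE))
  out <- arr[, , , perm, drop = FALSE]
  if (is(x, "FeatureMap")) featureMap(out) else out
}

.shuffleInvPerm <- function(C, groups)
  order(as.vector(matrix(seq_len(C), nrow = groups, byrow = TRUE)))

## ---- weights -----------------------------------------------------------

.heMat <- function(nin, nout, k = 1) {
  fanin <- k^2 * nin
  matrix(rnorm(fanin * nout, 0, sqrt(2 / fanin)), nrow = fanin, ncol = nout)
}

.allocLayer <- function(desc) {
  if (desc$op == "conv") {
    W <- if (desc$groups > 1)             # depthwise: (k^2, C)
      matrix(rnorm(desc$k^2 * desc$cout, 0, sqrt(2 / desc$k^2)),
             nrow = desc$k^2, ncol = desc$cout)
    else .heMat(desc$cin, desc$cout, desc$k)
    list(W = W, b = if (desc$bias) numeric(desc$cout) else NULL, desc = desc)
  } else if (desc$op == "linear") {
    list(W = .heMat(desc$nin, desc$nout),
         b = if (desc$bias) numeric(desc$nout) else NULL, desc = desc)
  } else desc
}

#' Initialize backbone weights
#'
#' He-initialized weights for every layer of the configured backbone,
#' reproducible given the seed. The configuration is embedded so a weight
#' set and its architecture travel together (checkpoints serialize both).
#'
#' @param cfg a [BackboneConfig-class].
#' @param seed integer seed.
#' @return a weight list with the layout embedded.
#' @export
initBackboneWeights <- function(cfg, seed = 1) {
  layout <- .backboneLayout(cfg)
  withSeed(seed, {
    allocUnit <- function(u) {
      u$weights <- lapply(u$layers, .allocLayer)
      u
    }
    list(cfg = cfg, layout = layout, seed = seed,
         stem = .allocLayer(layout$stem),
         stages = lapply(layout$stages, function(st) lapply(st, allocUnit)),
         attn = lapply(layout$attn, function(d)
           if (!is.null(d$op) && d$op == "matmul") d else .allocLayer(d)))
  })
}

.fwdConvLayer <- function(x, lw, act = TRUE) {
  d <- lw$desc
  out <- if (d$groups > 1) .dwconv2d(x, lw$W, d$k, d$stride, d$pad)
         else .conv2d(x, lw$W, lw$b, d$k, d$stride, d$pad)
  if (act && d$groups == 1) out <- .relu(out)
  out
}

.fwdUnit <- function(x, u) {
  w <- u$weights
  if (u$kind == "basic") {
    C <- dim(x)[4]
    half <- C %/% 2
    x1 <- x[, , , seq_len(half), drop = FALSE]
    x2 <- x[, , , half + seq_len(C - half), drop = FALSE]
    x2 <- .fwdConvLayer(x2, w$pw1)
    x2 <- .fwdConvLayer(x2, w$dw, act = FALSE)
    x2 <- .fwdConvLayer(x2, w$pw2)
    out <- array(c(x1, x2), c(dim(x1)[1:3], C))
  } else {
    b1 <- .fwdConvLayer(x, w$l.dw, act = FALSE)
    b1 <- .fwdConvLayer(b1, w$l.pw)
    b2 <- .fwdConvLayer(x, w$r.pw1)
    b2 <- .fwdConvLayer(b2, w$r.dw, act = FALSE)
    b2 <- .fwdConvLayer(b2, w$r.pw2)
    out <- array(c(b1, b2), c(dim(b1)[1:3], dim(b1)[4] + dim(b2)[4]))
  }
  channelShuffle(out, 2)
}

.softmaxRows <- function(m) {
  m <- exp(m - apply(m, 1, max))
  m / rowSums(m)
}

.fwdAttention <- function(x, aw, cfg, training = FALSE,
                          returnAttention = FALSE) {
  d <- dim(x)
  B <- d[1]; N <- d[2] * d[3]
  ed <- cfg@embedDim; h <- cfg@nHeads; dk <- ed %/% h
  X <- sweep(matrix(x, ncol = d[4]) %*% aw$tokenProj$W, 2,
             aw$tokenProj$b, "+")                     # (B*N, ed)
  qkv <- sweep(X %*% aw$qkv$W, 2, aw$qkv$b, "+")
  attnOut <- matrix(0, B * N, ed)
  attnMats <- if (returnAttention) array(0, c(B, h, N, N)) else NULL
  for (b in seq_len(B)) {
    rows <- seq(b, B * N, by = B)
    for (hh in seq_len(h)) {
      cq <- (hh - 1) * dk + seq_len(dk)
      Q <- qkv[rows, cq, drop = FALSE]
      K <- qkv[rows, ed + cq, drop = FALSE]
      V <- qkv[rows, 2 * ed + cq, drop = FALSE]
      A <- .softmaxRows(Q %*% t(K) / sqrt(dk))
      if (training && cfg@attentionDropout > 0) {
        keep <- 1 - cfg@attentionDropout
        A <- A * (matrix(runif(N * N), N, N) < keep) / keep
      }
      if (returnAttention) attnMats[b, hh, , ] <- A
      attnOut[rows, cq] <- A %*% V
    }
  }
  X <- X + sweep(attnOut %*% aw$proj$W, 2, aw$proj$b, "+")
  ffn <- .relu(sweep(X %*% aw$ffn1$W, 2, aw$ffn1$b, "+"))
  X <- X + sweep(ffn %*% aw$ffn2$W, 2, aw$ffn2$b, "+")
  Z <- sweep(X %*% aw$outProj$W, 2, aw$outProj$b, "+")
  dim(Z) <- c(B, d[2], d[3], 256L)
  list(Z = Z, attn = attnMats)
}

#' Extract contextualized feature maps
#'
#' Runs a batch of \[-1,1\]-normalized fundus images through the
#' convolutional stages (stride-2 stem, max-pool, shuffle units with the
#' configured depthwise kernels; 16-fold spatial downsampling), tokenizes
#' the coarsest feature map, applies one LeViT-style multi-head
#' self-attention block with residual and feed-forward sublayers, and
#' projects to a fixed 256 channels, giving a batch x g x g x 256 output
#' with g = inputSize / 16 (14 for 224-pixel inputs) regardless of the
#' width multiplier.
#'
#' @param x list of [FundusImage-class] in the \[-1,1\] range, or a rank-4
#'   array (B, H, W, 3).
#' @param weights result of [initBackboneWeights()].
#' @param chunkSize images processed per internal batch (memory knob).
#' @param returnAttention attach per-head attention matrices (use only for
#'   small batches).
#' @param training apply attention dropout stochastically.
#' @return a [FeatureMap-class]; when `returnAttention` is TRUE the
#'   attention array (B, heads, N, N) is attached as attribute `"attention"`.
#' @export
extractFeatures <- function(x, weights, chunkSize = 16,
                            returnAttention = FALSE, training = FALSE) {
  cfg <- weights$cfg
  if (is.list(x) && length(x) && is(x[[1]], "FundusImage")) {
    for (img in x)
      if (!isTRUE(all.equal(img@valueRange, c(-1, 1))))
        stop("images must be normalized to [-1, 1] before feature extraction")
    arr <- array(0, c(length(x), dim(x[[1]]@pixels)))
    for (i in seq_along(x)) arr[i, , , ] <- x[[i]]@pixels
    x <- arr
  }
  d <- dim(x)
  if (length(d) != 4 || d[4] != 3)
    stop("input must be a (batch, H, W, 3) array")
  if (d[2] != cfg@inputSize || d[3] != cfg@inputSize)
    stop(sprintf("input spatial size %dx%d; expected %dx%d",
                 d[2], d[3], cfg@inputSize, cfg@inputSize))
  B <- d[1]
  g <- weights$layout$grid
  Z <- array(0, c(B, g, g, 256L))
  attnAll <- if (returnAttention)
    array(0, c(B, cfg@nHeads, g * g, g * g)) else NULL
  starts <- seq(1, B, by = chunkSize)
  for (s0 in starts) {
    sel <- s0:min(B, s0 + chunkSize - 1)
    xb <- x[sel, , , , drop = FALSE]
    h <- .fwdConvLayer(xb, weights$stem)
    h <- .maxpool3(h)
    for (st in weights$stages)
      for (u in st) h <- .fwdUnit(h, u)
    res <- .fwdAttention(h, weights$attn, cfg, training = training,
                         returnAttention = returnAttention)
    Z[sel, , , ] <- res$Z
    if (returnAttention) attnAll[sel, , , ] <- res$attn
  }
  fm <- featureMap(Z)
  if (returnAttention) attr(fm, "attention") <- attnAll
  fm
}

#' Serialize backbone weights to a checkpoint file
#'
#' Plain-text JSON checkpoint with the configuration embedded, so a weight
#' set can be reloaded without reference to external state.
#'
#' @param weights result of [initBackboneWeights()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
saveBackboneCheckpoint <- function(weights, path) {
  cfg <- weights$cfg
  jsonlite::write_json(list(
    config = list(widthMultiplier = cfg@widthMultiplier,
                  depthwiseKernel = cfg@depthwiseKernel,
                  embedDim = cfg@embedDim, nHeads = cfg@nHeads,
                  attentionDropout = cfg@attentionDropout,
                  inputSize = cfg@inputSize),
    seed = weights$seed), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a backbone checkpoint
#'
#' Rebuilds the weights from the embedded config and seed (weights are
#' generated deterministically, so config + seed fully determine them).
#'
#' @param path checkpoint path written by [saveBackboneCheckpoint()].
#' @return a weight list as from [initBackboneWeights()].
#' @export
loadBackboneCheckpoint <- function(path) {
  ck <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- backboneConfig(ck$config$widthMultiplier, ck$config$depthwiseKernel,
                        ck$config$embedDim, ck$config$nHeads,
                        ck$config$attentionDropout, ck$config$inputSize)
  initBackboneWeights(cfg, seed = ck$seed)
}
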