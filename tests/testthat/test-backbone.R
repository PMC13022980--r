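test_that("channel shuffle is a pure, invertible channel permutation", {
  x <- array(rnorm(2 * 4 * 4 * 12), c(2, 4, 4, 12))
  ## groups = 1 is the identity
  expect_identical(channelShuffle(x, 1), x)
  out <- channelShuffle(x, 3)
  ## multiset of values preserved
  expect_identical(sort(as.vector(out)), sort(as.vector(x)))
  ## applying the tracked inverse permutation restores the original
  inv <- retiKAN:::.shuffleInvPerm(12, 3)
  expect_identical(out[, , , inv], x)
  expect_error(channelShuffle(x, 5), "divisible")
})

test_that("feature extraction yields the contracted 14x14x256 map at 224 px", {
  cfg <- backboneConfig()
  bw <- initBackboneWeights(cfg, seed = 1)
  x <- array(runif(2 * 224 * 224 * 3, -1, 1), c(2, 224, 224, 3))
  fm <- extractFeatures(x, bw)
  expect_identical(dim(featureData(fm)), c(2L, 14L, 14L, 256L))
  expect_true(all(is.finite(featureData(fm))))
  ## wrong input size names the expected size
  bad <- array(0, c(1, 112, 112, 3))
  expect_error(extractFeatures(bad, bw), "expected 224x224")
})

test_that("attention weights are row-stochastic and forwards are deterministic", {
  cfg <- backboneConfig(inputSize = 64)
  bw <- initBackboneWeights(cfg, seed = 2)
  x <- array(runif(1 * 64 * 64 * 3, -1, 1), c(1, 64, 64, 3))
  fm <- extractFeatures(x, bw, returnAttention = TRUE)
  at <- attr(fm, "attention")        # (B, heads, N, N)
  sums <- apply(at, c(1, 2, 3), sum)
  expect_lt(max(abs(sums - 1)), 1e-6)
  ## dropout 0, fixed weights: bit-identical repeat
  fm2 <- extractFeatures(x, bw)
  expect_identical(featureData(fm), featureData(fm2))
})

test_that("analytic FLOPs follow the closed forms", {
  ## single 1x1 convolution, 14x14 spatial, 128 -> 256 channels
  expect_identical(convFlops(14, 14, 128, 256, k = 1), 12845056)
  ## doubling the output channels doubles the layer's FLOPs
  expect_identical(convFlops(14, 14, 128, 512), 2 * convFlops(14, 14, 128, 256))
  expect_identical(linearFlops(128, 256, 10), 2 * 10 * 128 * 256)
  ## an empty layer list counts zero
  expect_length(retiKAN:::.layoutLeaves(list()), 0)
})

test_that("FLOPs are monotone in width multiplier and embedding dimension", {
  flopsAt <- function(wm, ed)
    countParamsFlops(backboneConfig(wm, 3, ed, 4))["flops"]
  for (ed in c(128, 256, 384)) {
    f <- vapply(c(0.5, 0.75, 1.0), flopsAt, numeric(1), ed = ed)
    expect_true(all(diff(f) >= 0))
  }
  for (wm in c(0.5, 0.75, 1.0)) {
    f <- vapply(c(128, 256, 384), function(e) flopsAt(wm, e), numeric(1))
    expect_true(all(diff(f) >= 0))
  }
})

test_that("all categorical config combinations produce finite features", {
  grid <- expand.grid(wm = c(0.5, 0.75, 1.0), k = c(3, 5),
                      ed = c(128, 256, 384), h = c(4, 8))
  x <- array(runif(64 * 64 * 3, -1, 1), c(1, 64, 64, 3))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    cfg <- backboneConfig(g$wm, g$k, g$ed, g$h, inputSize = 64)
    bw <- initBackboneWeights(cfg, seed = 3)
    fm <- extractFeatures(x, bw)
    expect_true(all(is.finite(featureData(fm))),
                info = sprintf("wm=%g k=%d ed=%d h=%d", g$wm, g$k, g$ed, g$h))
    expect_identical(dim(featureData(fm))[2:4], c(4L, 4L, 256L))
  }
})

test_that("horizontal flip changes features but keeps the global norm comparable", {
  cfg <- backboneConfig(inputSize = 64)
  bw <- initBackboneWeights(cfg, seed = 4)
  img <- normalizeSignedRange(testImage(4, 64, seed = 10))
  x <- array(pixels(img), c(1, 64, 64, 3))
  xf <- x[, , 64:1, , drop = FALSE]
  f1 <- featureData(extractFeatures(x, bw))
  f2 <- featureData(extractFeatures(xf, bw))
  expect_false(identical(f1, f2))                  # non-degeneracy
  n1 <- sqrt(mean(f1^2)); n2 <- sqrt(mean(f2^2))
  expect_lt(abs(n1 - n2) / n1, 0.2)                # architecture sanity
})

test_that("backbone checkpoints rebuild identical weights from config + seed", {
  cfg <- backboneConfig(0.75, 5, 256, 8, 0.1, inputSize = 64)
  bw <- initBackboneWeights(cfg, seed = 9)
  path <- file.path(withr::local_tempdir(), "ckpt.json")
  saveBackboneCheckpoint(bw, path)
  bw2 <- loadBackboneCheckpoint(path)
  expect_identical(bw$stem$W, bw2$stem$W)
  expect_identical(bw$attn$qkv$W, bw2$attn$qkv$W)
  expect_equal(bw2$cfg@embedDim, 256L)
})

test_that("backbone config validity enforces the menus", {
  expect_error(backboneConfig(widthMultiplier = 0.6), "widthMultiplier")
  expect_error(backboneConfig(depthwiseKernel = 7), "3 or 5")
  expect_error(backboneConfig(embedDim = 100), "embedDim")
  expect_error(backboneConfig(attentionDropout = 0.5), "attentionDropout")
})
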