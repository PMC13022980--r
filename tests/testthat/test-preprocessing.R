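test_that("CLAHE preserves shape, range and flat images", {
  img <- testImage(2, 128, seed = 1)
  out <- claheEnhance(img)
  expect_s4_class(out, "FundusImage")
  expect_identical(dim(pixels(out)), dim(pixels(img)))
  expect_gte(min(pixels(out)), 0)
  expect_lte(max(pixels(out)), 1)
  expect_identical(grade(out), grade(img))

  ## constant mid-gray image: histogram already flat, equalization is the
  ## identity
  flat <- fundusImage(array(0.5, c(64, 64, 3)), 0, "flat")
  expect_identical(pixels(claheEnhance(flat)), pixels(flat))

  ## re-applying never leaves [0, 1]
  out2 <- claheEnhance(out)
  expect_gte(min(pixels(out2)), 0)
  expect_lte(max(pixels(out2)), 1)
})

test_that("CLAHE strictly increases RMS local contrast on a low-contrast blob", {
  s <- 128
  g <- outer(seq_len(s), seq_len(s), function(i, j)
    0.45 + 0.1 * exp(-((i - s / 2)^2 + (j - s / 2)^2) / (2 * (s / 6)^2)))
  img <- fundusImage(array(rep(g, 3), c(s, s, 3)), 0, "blob")
  out <- claheEnhance(img)
  expect_gt(rmsLocalContrast(luminanceOf(out)),
            rmsLocalContrast(luminanceOf(img)))
})

test_that("CLAHE rejects tile grids larger than the image, naming the dimension", {
  img <- testImage(0, 64, seed = 2)
  expect_error(claheEnhance(img, tileGrid = c(100, 8)), "x dimension")
  expect_error(claheEnhance(img, tileGrid = c(8, 100)), "y dimension")
})

test_that("signed-range normalization is the linear map 2x - 1 with guards", {
  px <- array(0.5, c(64, 64, 3))
  px[1, 1, ] <- 0; px[1, 2, ] <- 1; px[1, 3, ] <- 0.25
  img <- fundusImage(px, 1, "n")
  out <- normalizeSignedRange(img)
  expect_equal(valueRange(out), c(-1, 1))
  expect_equal(pixels(out)[1, 1, 1], -1)
  expect_equal(pixels(out)[1, 2, 1], 1)
  expect_equal(pixels(out)[1, 3, 1], -0.5)
  ## double-normalization guard
  expect_error(normalizeSignedRange(out), "already")
  ## inverse map is the identity to within 1e-12
  back <- unnormalizeSignedRange(out)
  expect_lt(max(abs(pixels(back) - px)), 1e-12)
})

test_that("augmentation samples rotations within the tolerance and flips by probability", {
  set.seed(11)
  angles <- replicate(10000, sampleAugmentation()$angle)
  expect_true(all(abs(angles) <= 15))
  expect_gt(max(abs(angles)), 10)       # the range is actually used
  ## disabled transform stays at its identity value
  pOff <- augmentationParams(enabled = c(rotation = FALSE))
  expect_identical(sampleAugmentation(pOff)$angle, 0)
})

test_that("augmentation preserves the grade label and is seed-deterministic", {
  img <- normalizeSignedRange(testImage(3, 64, seed = 5))
  for (i in 1:50) {
    a <- augmentImage(img, seed = i)
    expect_identical(grade(a), grade(img))
    expect_gte(min(pixels(a)), -1)
    expect_lte(max(pixels(a)), 1)
  }
  ## label preservation over many sampled transforms (distributional part)
  set.seed(21)
  for (i in 1:1000) {
    tr <- sampleAugmentation()
    expect_true(abs(tr$angle) <= 15 && tr$scale >= 0.9 && tr$scale <= 1.1)
  }
  a1 <- augmentImage(img, seed = 99)
  a2 <- augmentImage(img, seed = 99)
  expect_identical(pixels(a1), pixels(a2))
  a3 <- augmentImage(img, seed = 100)
  expect_false(identical(pixels(a1), pixels(a3)))
})

test_that("augmentation with everything disabled is bitwise identity", {
  img <- testImage(1, 64, seed = 6)
  off <- augmentationParams(enabled = stats::setNames(
    rep(FALSE, 8), c("rotation", "flipH", "flipV", "scale", "translate",
                     "brightness", "contrast", "saturation")))
  out <- augmentImage(img, off, seed = 1)
  expect_identical(pixels(out), pixels(img))
})

test_that("PNG round trip preserves pixels and sidecar metadata", {
  img <- testImage(2, 64, seed = 7)
  path <- file.path(withr::local_tempdir(), "img.png")
  writeFundusImage(img, path)
  expect_true(file.exists(paste0(path, ".json")))
  back <- readFundusImage(path)
  expect_identical(grade(back), 2L)
  expect_lt(max(abs(pixels(back) - pixels(img))), 1 / 255)
  ## signed-range image round-trips through the sidecar
  nimg <- normalizeSignedRange(img)
  writeFundusImage(nimg, path)
  back2 <- readFundusImage(path)
  expect_equal(valueRange(back2), c(-1, 1))
  expect_lt(max(abs(pixels(back2) - pixels(nimg))), 2 / 255)
})

test_that("FundusImage validity enforces the domain invariants", {
  expect_error(fundusImage(array(0.5, c(32, 32, 3)), 0), "64")
  expect_error(fundusImage(array(0.5, c(64, 80, 3)), 0), "square")
  expect_error(fundusImage(array(2, c(64, 64, 3)), 0), "range")
  expect_error(fundusImage(array(0.5, c(64, 64, 3)), 7), "grade")
})
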