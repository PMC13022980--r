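## Image quality enhancement, intensity normalization and label-preserving
## augmentation. Contrast work happens on the luminance channel only so the
## color cues that distinguish lesion classes (red microaneurysms and
## hemorrhages vs. yellow exudates) are approximately preserved.

## RGB <-> YCbCr-style luma/chroma transform (BT.601 luma weights). The
## inverse is exact for the forward used here.
.rgbToYcc <- function(px) {
  y <- 0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
  cb <- (px[, , 3] - y) * 0.564
  cr <- (px[, , 1] - y) * 0.713
  list(y = y, cb = cb, cr = cr)
}

.yccToRgb <- function(ycc) {
  r <- ycc$y + ycc$cr / 0.713
  b <- ycc$y + ycc$cb / 0.564
  g <- (ycc$y - 0.299 * r - 0.114 * b) / 0.587
  out <- array(0, c(dim(ycc$y), 3))
  out[, , 1] <- r; out[, , 2] <- g; out[, , 3] <- b
  out
}

#' Contrast-limited adaptive histogram equalization (CLAHE)
#'
#' Enhances local contrast on the luminance channel of a fundus image while
#' the clip limit prevents amplification of noise in homogeneous regions.
#' The RGB image is converted to a luma/chroma representation, the luma
#' channel is equalized tile-wise, and the image is converted back, so hue
#' is approximately preserved. Images whose luminance channel is flat
#' (zero dynamic range) are returned unchanged: equalizing an already flat
#' histogram is the identity.
#'
#' @param img a [FundusImage-class] in the \[0,1\] range.
#' @param clipLimit positive contrast clip limit (default 2).
#' @param tileGrid positive integer pair, number of tiles per axis
#'   (default c(8, 8)).
#' @return a [FundusImage-class] of identical shape, range and grade.
#' @export
claheEnhance <- function(img, clipLimit = 2, tileGrid = c(8, 8)) {
  stopifnot(is(img, "FundusImage"))
  if (!isTRUE(all.equal(img@valueRange, c(0, 1))))
    stop("claheEnhance expects an image in the [0, 1] range")
  if (clipLimit <= 0) stop("clipLimit must be positive")
  tileGrid <- as.integer(rep(tileGrid, length.out = 2))
  d <- dim(img@pixels)
  if (tileGrid[1] > d[1])
    stop(sprintf("tile grid x dimension (%d) exceeds image height (%d)",
                 tileGrid[1], d[1]))
  if (tileGrid[2] > d[2])
    stop(sprintf("tile grid y dimension (%d) exceeds image width (%d)",
                 tileGrid[2], d[2]))
  ycc <- .rgbToYcc(img@pixels)
  if (diff(range(ycc$y)) < 1e-12) return(img)
  yEq <- EBImage::clahe(ycc$y, nx = tileGrid[1], ny = tileGrid[2],
                        limit = clipLimit)
  ycc$y <- as.numeric(yEq)
  dim(ycc$y) <- d[1:2]
  out <- clipRange(.yccToRgb(ycc), 0, 1)
  fundusImage(out, img@grade, img@id, c(0, 1), img@meta)
}

#' Scale pixel values from \[0,1\] to \[-1,1\]
#'
#' Applies the linear map `x -> 2x - 1` and updates the declared value
#' range. Calling it on an image already in \[-1,1\] is an error (double
#' normalization guard).
#'
#' @param img a [FundusImage-class] in the \[0,1\] range.
#' @return the image rescaled to \[-1,1\].
#' @export
normalizeSignedRange <- function(img) {
  stopifnot(is(img, "FundusImage"))
  if (isTRUE(all.equal(img@valueRange, c(-1, 1))))
    stop("image is already normalized to [-1, 1]")
  if (!isTRUE(all.equal(img@valueRange, c(0, 1))))
    stop("normalizeSignedRange expects an image in the [0, 1] range")
  fundusImage(2 * img@pixels - 1, img@grade, img@id, c(-1, 1), img@meta)
}

#' Invert the signed-range normalization
#'
#' @param img a [FundusImage-class] in the \[-1,1\] range.
#' @return the image rescaled back to \[0,1\].
#' @export
unnormalizeSignedRange <- function(img) {
  stopifnot(is(img, "FundusImage"))
  if (!isTRUE(all.equal(img@valueRange, c(-1, 1))))
    stop("unnormalizeSignedRange expects an image in the [-1, 1] range")
  fundusImage((img@pixels + 1) / 2, img@grade, img@id, c(0, 1), img@meta)
}

#' Sample a concrete augmentation transform
#'
#' Draws one realization of the random augmentation (rotation angle, flips,
#' scale, translation, photometric jitter) from the parameter distribution.
#' Exposed so the sampling distribution can be inspected independently of
#' the image warp.
#'
#' @param params an [AugmentationParams-class] object.
#' @return a list with elements `angle` (degrees), `flipH`, `flipV`,
#'   `scale`, `translate` (length 2, fraction of size), `brightness`,
#'   `contrast`, `saturation`.
#' @export
sampleAugmentation <- function(params = augmentationParams()) {
  stopifnot(is(params, "AugmentationParams"))
  en <- params@enabled
  list(
    angle = if (en["rotation"]) runif(1, -params@maxRotation, params@maxRotation) else 0,
    flipH = if (en["flipH"]) runif(1) < params@flipHorizontal else FALSE,
    flipV = if (en["flipV"]) runif(1) < params@flipVertical else FALSE,
    scale = if (en["scale"]) runif(1, params@scaleRange[1], params@scaleRange[2]) else 1,
    translate = if (en["translate"])
      runif(2, params@translateRange[1], params@translateRange[2]) else c(0, 0),
    brightness = if (en["brightness"])
      runif(1, params@brightnessJitter[1], params@brightnessJitter[2]) else 0,
    contrast = if (en["contrast"])
      runif(1, params@contrastJitter[1], params@contrastJitter[2]) else 1,
    saturation = if (en["saturation"])
      runif(1, params@saturationJitter[1], params@saturationJitter[2]) else 1
  )
}

.isIdentityTransform <- function(tr) {
  tr$angle == 0 && !tr$flipH && !tr$flipV && tr$scale == 1 &&
    all(tr$translate == 0) && tr$brightness == 0 && tr$contrast == 1 &&
    tr$saturation == 1
}

## Apply a sampled transform to a pixel array. Geometric part is one
## affine warp about the image center; exposed borders are filled with the
## channel's darkest corner value (mimics the black fundus surround).
.applyTransform <- function(px, tr, lo, hi) {
  d <- dim(px)
  if (tr$flipH) px <- px[, d[2]:1, , drop = FALSE]
  if (tr$flipV) px <- px[d[1]:1, , , drop = FALSE]
  if (tr$angle != 0 || tr$scale != 1 || any(tr$translate != 0)) {
    th <- tr$angle * pi / 180
    M <- tr$scale * rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
    cen <- c((d[1] + 1) / 2, (d[2] + 1) / 2)
    off <- cen + tr$translate * d[1:2] - M %*% cen
    m <- rbind(t(M), as.numeric(off))
    for (ch in 1:3) {
      corners <- c(px[1, 1, ch], px[1, d[2], ch], px[d[1], 1, ch], px[d[1], d[2], ch])
      bg <- min(corners)
      px[, , ch] <- EBImage::affine(px[, , ch], m, filter = "bilinear",
                                    bg.col = bg)
    }
  }
  if (tr$brightness != 0) px <- px + tr$brightness * (hi - lo)
  if (tr$contrast != 1) {
    mu <- mean(px)
    px <- (px - mu) * tr$contrast + mu
  }
  if (tr$saturation != 1) {
    y <- 0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
    for (ch in 1:3) px[, , ch] <- y + tr$saturation * (px[, , ch] - y)
  }
  clipRange(px, lo, hi)
}

#' Label-preserving random augmentation
#'
#' Applies one random geometric + photometric transform drawn from `params`.
#' The severity grade is unchanged (all transforms are label-preserving);
#' borders exposed by rotation/scaling/translation are filled with the
#' image's darkest corner value, and photometric jitter is clipped back to
#' the declared value range. With all transforms disabled the input is
#' returned bitwise-identical. Deterministic given `seed` (or the current
#' RNG state when `seed` is NULL).
#'
#' @param img a [FundusImage-class].
#' @param params an [AugmentationParams-class] object.
#' @param seed optional integer seed.
#' @return an augmented [FundusImage-class] with the same grade. The drawn
#'   transform is attached as attribute `"transform"`.
#' @export
augmentImage <- function(img, params = augmentationParams(), seed = NULL) {
  stopifnot(is(img, "FundusImage"))
  tr <- withSeed(seed, sampleAugmentation(params))
  if (.isIdentityTransform(tr)) {
    out <- img
  } else {
    px <- .applyTransform(img@pixels, tr, img@valueRange[1], img@valueRange[2])
    out <- fundusImage(px, img@grade, img@id, img@valueRange, img@meta)
  }
  attr(out, "transform") <- tr
  out
}

#' Read a fundus image from PNG/JPEG
#'
#' Reads the pixel data and, when present, a JSON sidecar
#' (`<path>.json`) recording the declared value range, grade and id.
#'
#' @param path PNG file path.
#' @param grade severity grade (overridden by the sidecar if present).
#' @param id identifier (default: file name).
#' @return a [FundusImage-class].
#' @export
readFundusImage <- function(path, grade = 0, id = NULL) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 2) px <- array(rep(px, 3), c(dim(px), 3))
  if (dim(px)[3] > 3) px <- px[, , 1:3]
  vr <- c(0, 1)
  if (is.null(id)) id <- sub("\\.[^.]+$", "", basename(path))
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    md <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (!is.null(md$valueRange)) vr <- as.numeric(md$valueRange)
    if (!is.null(md$grade)) grade <- md$grade
    if (!is.null(md$id)) id <- md$id
    if (isTRUE(all.equal(vr, c(-1, 1)))) px <- 2 * px - 1
  }
  fundusImage(px, grade, id, vr)
}

#' Write a fundus image to PNG with a JSON sidecar
#'
#' The PNG always stores \[0,1\] data; the sidecar records the declared
#' value range so a \[-1,1\] image round-trips exactly to within PNG
#' quantization.
#'
#' @param img a [FundusImage-class].
#' @param path output PNG path.
#' @return the path, invisibly.
#' @export
writeFundusImage <- function(img, path) {
  stopifnot(is(img, "FundusImage"))
  px <- img@pixels
  if (isTRUE(all.equal(img@valueRange, c(-1, 1)))) px <- (px + 1) / 2
  png::writePNG(clipRange(px, 0, 1), path)
  jsonlite::write_json(
    list(id = img@id, grade = img@grade, valueRange = img@valueRange),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
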