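## Synthetic graded fundus-like images: a dark circular retinal field with
## radial vignette, one bright elliptical optic disc, curvilinear vessels,
## and grade-dependent lesion primitives (microaneurysms, hemorrhages,
## exudates, neovascular tufts at grade 4). Not photorealistic; the goal is
## a controllable, learnable severity signal for end-to-end testing.

## Stamp a soft-edged elliptical blob onto a pixel array (alpha blending).
## Returns the array plus the stamped pixel area.
.stampBlob <- function(px, cx, cy, rx, ry, color, alpha = 0.9, soft = 0.35) {
  d <- dim(px)
  x0 <- max(1L, floor(cx - rx - 2)); x1 <- min(d[1], ceiling(cx + rx + 2))
  y0 <- max(1L, floor(cy - ry - 2)); y1 <- min(d[2], ceiling(cy + ry + 2))
  if (x0 > x1 || y0 > y1) return(list(px = px, area = 0))
  xs <- x0:x1; ys <- y0:y1
  rr <- outer(((xs - cx) / rx)^2, ((ys - cy) / ry)^2, "+")
  a <- alpha * clipRange((1 - sqrt(rr)) / soft + 1, 0, 1)
  area <- sum(a > 0.5)
  for (ch in 1:3)
    px[xs, ys, ch] <- px[xs, ys, ch] * (1 - a) + color[ch] * a
  list(px = px, area = area)
}

## Accumulate a quadratic Bezier stroke into a single-channel alpha canvas
## (max-blended soft disks along the curve); the caller blends the canvas
## into the image once per stroke color.
.curveAlpha <- function(canvas, p0, p1, p2, width, alpha = 0.8) {
  d <- dim(canvas)
  len <- sqrt(sum((p2 - p0)^2))
  ts <- seq(0, 1, length.out = max(8, ceiling(len / 2)))
  w2 <- width + 1.5
  for (t in ts) {
    p <- (1 - t)^2 * p0 + 2 * t * (1 - t) * p1 + t^2 * p2
    x0 <- max(1L, floor(p[1] - w2)); x1 <- min(d[1], ceiling(p[1] + w2))
    y0 <- max(1L, floor(p[2] - w2)); y1 <- min(d[2], ceiling(p[2] + w2))
    if (x0 > x1 || y0 > y1) next
    xs <- x0:x1; ys <- y0:y1
    rr <- sqrt(outer((xs - p[1])^2, (ys - p[2])^2, "+")) / width
    a <- alpha * clipRange((1 - rr) / 0.8 + 1, 0, 1)
    canvas[xs, ys] <- pmax(canvas[xs, ys], a)
  }
  canvas
}

.blendAlpha <- function(px, canvas, color) {
  for (ch in 1:3)
    px[, , ch] <- px[, , ch] * (1 - canvas) + color[ch] * canvas
  px
}

#' Generate one synthetic graded fundus image
#'
#' Builds a dark circular retinal field with radial vignette, one bright
#' elliptical optic disc and 3-8 curvilinear vessel strokes, then places
#' lesion primitives with counts drawn from Poisson distributions whose
#' means depend on the grade per the [LesionModel-class]: grade 0 images
#' contain no lesions at all. Deterministic given `(grade, seed)`.
#'
#' @param grade integer severity grade in 0..4.
#' @param size image side in pixels (>= 64).
#' @param model a [LesionModel-class].
#' @param seed optional integer seed.
#' @param id identifier string.
#' @return a [FundusImage-class] in \[0,1\] with `meta` recording the seed,
#'   lesion counts and total stamped lesion area.
#' @export
generateFundusImage <- function(grade, size = 224, model = lesionModel(),
                                seed = NULL, id = NULL) {
  stopifnot(grade %in% 0:4)
  if (size < 64) stop("size must be >= 64 pixels")
  if (is.null(id)) id <- sprintf("synth_g%d_s%s", grade, seed %||% "NA")
  withSeed(seed, {
    s <- size
    cen <- (s + 1) / 2
    fieldR <- 0.48 * s
    xs <- seq_len(s)
    r2 <- outer((xs - cen)^2, (xs - cen)^2, "+")
    rad <- sqrt(r2) / fieldR
    inField <- rad <= 1
    vignette <- clipRange(1 - 0.55 * rad^2, 0, 1) * inField
    base <- c(0.72, 0.34, 0.12)             # fundus orange
    px <- array(0.02, c(s, s, 3))
    noise <- array(rnorm(s * s * 3, 0, 0.015), c(s, s, 3))
    for (ch in 1:3)
      px[, , ch] <- px[, , ch] + inField * (base[ch] * vignette) + noise[, , ch] * inField

    ## optic disc: bright ellipse offset from center
    discAng <- runif(1, 0, 2 * pi)
    discD <- runif(1, 0.15, 0.3) * fieldR
    dc <- cen + discD * c(cos(discAng), sin(discAng))
    discR <- runif(1, 0.06, 0.08) * s
    px <- .stampBlob(px, dc[1], dc[2], discR * runif(1, 0.9, 1.1), discR,
                     c(0.98, 0.78, 0.50), alpha = 0.95, soft = 0.5)$px

    ## vessels: curvilinear strokes radiating from the disc, accumulated
    ## on one alpha canvas and blended in a single pass
    nVessel <- sample(3:8, 1)
    vcanvas <- matrix(0, s, s)
    for (v in seq_len(nVessel)) {
      ang <- runif(1, 0, 2 * pi)
      reach <- runif(1, 0.5, 0.95) * fieldR
      p0 <- dc
      p2 <- cen + reach * c(cos(ang), sin(ang))
      mid <- (p0 + p2) / 2
      perp <- c(-(p2 - p0)[2], (p2 - p0)[1])
      p1 <- mid + perp * runif(1, -0.25, 0.25)
      vcanvas <- .curveAlpha(vcanvas, p0, p1, p2,
                             width = runif(1, 0.004, 0.009) * s)
    }
    px <- .blendAlpha(px, vcanvas, c(0.38, 0.07, 0.05))

    ## lesions with grade-dependent Poisson counts
    g1 <- grade + 1L
    counts <- c(ma = rpois(1, model@maRate[g1]),
                hem = rpois(1, model@hemRate[g1]),
                ex = rpois(1, model@exRate[g1]),
                tuft = rpois(1, model@tuftRate[g1]))
    lesionArea <- 0
    placeIn <- function() {
      repeat {
        p <- cen + runif(2, -0.85, 0.85) * fieldR
        if (sum((p - cen)^2) <= (0.85 * fieldR)^2) return(p)
      }
    }
    scl <- s / 224                          # radii specified at 224 px scale
    stampLesion <- function(px, n, radRange, colMean, alpha) {
      for (i in seq_len(n)) {
        p <- placeIn()
        r <- runif(1, radRange[1], radRange[2]) * scl
        col <- clipRange(colMean + rnorm(3, 0, model@colorSd), 0, 1)
        st <- .stampBlob(px, p[1], p[2], r * runif(1, 0.8, 1.2), r, col, alpha)
        lesionArea <<- lesionArea + st$area
        px <- st$px
      }
      px
    }
    px <- stampLesion(px, counts["ma"], model@maRadius, model@maColor, 0.9)
    px <- stampLesion(px, counts["hem"], model@hemRadius, model@hemColor, 0.85)
    px <- stampLesion(px, counts["ex"], model@exRadius, model@exColor, 0.95)
    ## neovascular tufts: small tangled bright-red curve clusters
    if (counts["tuft"] > 0) {
      tcanvas <- matrix(0, s, s)
      for (i in seq_len(counts["tuft"])) {
        p <- placeIn()
        for (k in 1:3) {
          q <- p + runif(2, -4, 4) * scl
          m <- p + runif(2, -6, 6) * scl
          tcanvas <- .curveAlpha(tcanvas, p, m, q, width = 1.2 * scl)
        }
        lesionArea <- lesionArea + 20 * scl^2
      }
      px <- .blendAlpha(px, tcanvas, c(0.55, 0.1, 0.08))
    }

    px <- clipRange(px, 0, 1)
    fundusImage(px, grade, id, c(0, 1),
                meta = list(seed = seed, lesionCounts = as.list(counts),
                            lesionArea = lesionArea, nVessels = nVessel))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a synthetic graded dataset
#'
#' Class composition matches `spec@classCounts` exactly when counts are
#' given, or is drawn multinomially from `spec@classProbs`. Each image gets
#' its own child seed derived from the dataset seed, so manifests and
#' images are reproducible image-by-image.
#'
#' @param spec a [DatasetSpec-class].
#' @param model a [LesionModel-class].
#' @return a list with `images` (list of [FundusImage-class]) and
#'   `manifest` (data.frame with id, grade, seed).
#' @export
generateFundusDataset <- function(spec, model = lesionModel()) {
  stopifnot(is(spec, "DatasetSpec"))
  validObject(spec)
  if (spec@nImages == 0)
    return(list(images = list(),
                manifest = data.frame(id = character(), grade = integer(),
                                      seed = integer())))
  grades <- withSeed(spec@seed, {
    if (!all(is.na(spec@classCounts))) {
      g <- rep(0:4, times = spec@classCounts)
      sample(g)
    } else {
      g <- sample(0:4, spec@nImages, replace = TRUE, prob = spec@classProbs)
      missing <- setdiff(which(spec@classProbs > 0) - 1L, unique(g))
      if (length(missing))
        warning(sprintf("no images drawn for grade(s) %s despite positive probability",
                        paste(missing, collapse = ", ")))
      g
    }
  })
  n <- length(grades)
  seeds <- vapply(seq_len(n), function(i) childSeed(spec@seed, i), integer(1))
  ids <- sprintf("img%05d_g%d", seq_len(n), grades)
  images <- vector("list", n)
  for (i in seq_len(n))
    images[[i]] <- generateFundusImage(grades[i], spec@imageSize, model,
                                       seed = seeds[i], id = ids[i])
  manifest <- data.frame(id = ids, grade = as.integer(grades), seed = seeds,
                         stringsAsFactors = FALSE)
  list(images = images, manifest = manifest)
}

#' Write a synthetic dataset to disk
#'
#' PNG images (with JSON sidecars) plus a CSV manifest (id, grade, seed).
#'
#' @param dataset result of [generateFundusDataset()].
#' @param dir output directory (created if missing).
#' @return the manifest path, invisibly.
#' @export
writeFundusDataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (img in dataset$images)
    writeFundusImage(img, file.path(dir, paste0(img@id, ".png")))
  mp <- file.path(dir, "manifest.csv")
  write.csv(dataset$manifest, mp, row.names = FALSE)
  invisible(mp)
}

#' Read a dataset specification from YAML
#'
#' Recognized fields: `n_images`, `class_counts`, `class_probs`,
#' `image_size`, `seed`.
#'
#' @param path YAML file path.
#' @return a [DatasetSpec-class].
#' @export
datasetSpecFromYaml <- function(path) {
  y <- yaml::read_yaml(path)
  datasetSpec(nImages = y$n_images, classCounts = y$class_counts,
              classProbs = y$class_probs, imageSize = y$image_size %||% 224,
              seed = y$seed %||% 1)
}
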