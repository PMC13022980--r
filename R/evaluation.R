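## Classification metrics for five-grade severity evaluation: confusion
## matrices, one-vs-rest binary metrics (accuracy, precision, recall, F1,
## MCC, Cohen's kappa), multiclass macro averages and full-matrix kappa,
## AUROC/AUPRC, stratified k-fold assignment with an inner 90/10
## train/validation split, and fold-level summary statistics.

#' Confusion matrix of grade predictions
#'
#' counts\[i, j\] = number of samples with true class i predicted as j
#' (classes 0..nClasses-1; rows = truth).
#'
#' @param labels true integer classes.
#' @param predictions predicted integer classes (same length).
#' @param nClasses number of classes (default 5).
#' @return an nClasses x nClasses integer matrix with dimnames.
#' @export
confusionCounts <- function(labels, predictions, nClasses = 5) {
  if (length(labels) != length(predictions))
    stop("labels and predictions must have equal length")
  labels <- as.integer(labels); predictions <- as.integer(predictions)
  if (length(labels) && (any(labels < 0 | labels >= nClasses) ||
                         any(predictions < 0 | predictions >= nClasses)))
    stop(sprintf("classes must lie in 0..%d", nClasses - 1))
  cm <- matrix(0L, nClasses, nClasses,
               dimnames = list(true = 0:(nClasses - 1),
                               predicted = 0:(nClasses - 1)))
  for (i in seq_along(labels))
    cm[labels[i] + 1L, predictions[i] + 1L] <- cm[labels[i] + 1L,
                                                  predictions[i] + 1L] + 1L
  cm
}

#' Binary classification metrics from 2x2 counts
#'
#' Accuracy, precision, recall, F1, Matthews correlation coefficient and
#' Cohen's kappa from true/false positive/negative counts. Zero-denominator
#' conventions: precision and recall are 0 when undefined; MCC is 0 when
#' its denominator vanishes; kappa is 0 when Pe = 1.
#'
#' @param tp,tn,fp,fn nonnegative counts, total > 0.
#' @return named numeric with accuracy, precision, recall, f1, mcc, kappa.
#' @export
binaryMetrics <- function(tp, tn, fp, fn) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  n <- tp + tn + fp + fn
  if (n == 0) stop("total count must be positive")
  accuracy <- (tp + tn) / n
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  mccDen <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  mcc <- if (mccDen > 0) (tp * tn - fp * fn) / mccDen else 0
  po <- accuracy
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  kappa <- if (pe < 1) (po - pe) / (1 - pe) else 0
  c(accuracy = accuracy, precision = precision, recall = recall, f1 = f1,
    mcc = mcc, kappa = kappa)
}

#' Multiclass metrics from a confusion matrix
#'
#' Per-class one-vs-rest reduction to [binaryMetrics()], unweighted macro
#' averages over the classes, overall accuracy (trace / total) and the
#' multiclass Cohen's kappa computed from the full matrix with
#' marginal-product expected agreement.
#'
#' @param cm square confusion matrix (rows = truth).
#' @return list(perClass (class x metric data.frame), macro (named
#'   numeric), accuracy, kappa).
#' @export
multiclassMetrics <- function(cm) {
  cm <- as.matrix(cm)
  n <- sum(cm)
  if (n == 0) stop("confusion matrix total must be positive")
  k <- nrow(cm)
  perClass <- t(vapply(seq_len(k), function(i) {
    tp <- cm[i, i]
    fn <- sum(cm[i, ]) - tp
    fp <- sum(cm[, i]) - tp
    tn <- n - tp - fn - fp
    binaryMetrics(tp, tn, fp, fn)
  }, numeric(6)))
  rownames(perClass) <- rownames(cm) %||% as.character(0:(k - 1))
  macro <- colMeans(perClass)
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  kappa <- if (pe < 1) (po - pe) / (1 - pe) else 0
  list(perClass = as.data.frame(perClass), macro = macro,
       accuracy = po, kappa = kappa)
}

#' One-vs-rest AUROC and AUPRC
#'
#' AUROC via the Mann-Whitney statistic with ties counted 1/2; AUPRC by
#' step-wise precision-recall integration over descending score
#' thresholds (tied scores processed as one group). A class absent from
#' the labels is reported as NA with a warning rather than 0.
#'
#' @param labels true integer classes 0..(ncol(scores)-1).
#' @param scores n x nClasses score matrix (higher = more confident).
#' @return data.frame with class, auroc, auprc, n (positives).
#' @export
aurocAuprc <- function(labels, scores) {
  scores <- as.matrix(scores)
  stopifnot(all(is.finite(scores)), length(labels) == nrow(scores))
  labels <- as.integer(labels)
  k <- ncol(scores)
  out <- data.frame(class = 0:(k - 1), auroc = NA_real_, auprc = NA_real_,
                    n = 0L)
  for (i in seq_len(k)) {
    pos <- labels == (i - 1)
    n1 <- sum(pos); n0 <- sum(!pos)
    out$n[i] <- n1
    if (n1 == 0 || n0 == 0) {
      warning(sprintf("class %d absent from labels (or no negatives); AUROC/AUPRC undefined",
                      i - 1))
      next
    }
    sc <- scores[, i]
    r <- rank(sc)                       # midranks handle ties as 1/2
    out$auroc[i] <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    ## stepwise AUPRC over descending unique thresholds
    ord <- order(sc, decreasing = TRUE)
    y <- pos[ord]; s <- sc[ord]
    grp <- cumsum(!duplicated(s))
    tpCum <- cumsum(y); allCum <- seq_along(y)
    last <- !duplicated(grp, fromLast = TRUE)
    tp <- tpCum[last]; nn <- allCum[last]
    prec <- tp / nn
    rec <- tp / n1
    dRec <- diff(c(0, rec))
    out$auprc[i] <- sum(prec * dRec)
  }
  out
}

#' Stratified k-fold assignment with inner train/validation split
#'
#' Shuffled per-class round-robin assignment of samples to k test folds,
#' so every fold's per-class test proportions match the global proportions
#' to within one sample. Within each fold the remaining samples are split
#' (1 - valFraction)/valFraction into train/validation, again stratified
#' by class.
#'
#' @param labels integer class labels.
#' @param k number of folds (default 5).
#' @param valFraction validation fraction of the non-test samples
#'   (default 0.1).
#' @param seed optional integer seed.
#' @return a [FoldAssignment-class].
#' @export
stratifiedKFold <- function(labels, k = 5, valFraction = 0.1, seed = NULL) {
  labels <- as.integer(labels)
  n <- length(labels)
  classes <- sort(unique(labels))
  for (cl in classes) {
    if (sum(labels == cl) < k)
      stop(sprintf("class %d has %d samples; need at least k = %d",
                   cl, sum(labels == cl), k))
  }
  withSeed(seed, {
    testFold <- integer(n)
    for (cl in classes) {
      idx <- sample(which(labels == cl))
      ## shuffled round robin: every fold gets floor or ceil of n_c / k of
      ## class cl, with the remainder folds chosen at random
      testFold[idx] <- rep_len(sample.int(k), length(idx))
    }
    folds <- vector("list", k)
    for (f in seq_len(k)) {
      test <- which(testFold == f)
      rest <- which(testFold != f)
      val <- integer(0)
      for (cl in classes) {
        restCl <- sample(rest[labels[rest] == cl])
        nVal <- floor(valFraction * length(restCl) + 0.5)
        val <- c(val, restCl[seq_len(nVal)])
      }
      train <- setdiff(rest, val)
      folds[[f]] <- list(train = sort(train), val = sort(val),
                         test = sort(test))
    }
    new("FoldAssignment", testFold = testFold, folds = folds,
        k = as.integer(k))
  })
}

#' Fold-level summary statistics
#'
#' Mean, sample standard deviation (n - 1) and the 95% Student-t
#' confidence-interval half-width `t_{0.975, k-1} * SD / sqrt(k)` of a
#' per-fold metric.
#'
#' @param values per-fold metric values (length >= 2).
#' @param conf confidence level (default 0.95).
#' @return named numeric with mean, sd, ciHalfWidth, k.
#' @export
foldSummary <- function(values, conf = 0.95) {
  k <- length(values)
  if (k < 2) stop("need at least 2 folds to summarize")
  s <- sd(values)
  hw <- qt(1 - (1 - conf) / 2, df = k - 1) * s / sqrt(k)
  c(mean = mean(values), sd = s, ciHalfWidth = hw, k = k)
}

#' Plot one-vs-rest ROC and precision-recall curves
#'
#' Base-graphics curves per class, written to a PNG when `path` is given.
#'
#' @param labels true integer classes.
#' @param scores n x nClasses score matrix.
#' @param path optional PNG output path.
#' @return invisibly, the [aurocAuprc()] table.
#' @export
plotRocPr <- function(labels, scores, path = NULL) {
  if (!is.null(path)) {
    grDevices::png(path, width = 900, height = 450)
    on.exit(grDevices::dev.off())
  }
  graphics::par(mfrow = c(1, 2))
  k <- ncol(scores)
  cols <- grDevices::hcl.colors(k, "Dark 3")
  graphics::plot(c(0, 1), c(0, 1), type = "l", lty = 2, col = "grey",
                 xlab = "False positive rate", ylab = "True positive rate",
                 main = "One-vs-rest ROC")
  for (i in seq_len(k)) {
    pos <- labels == (i - 1)
    if (!any(pos) || all(pos)) next
    ord <- order(scores[, i], decreasing = TRUE)
    y <- pos[ord]
    graphics::lines(cumsum(!y) / sum(!y), cumsum(y) / sum(y), col = cols[i])
  }
  graphics::plot(NULL, xlim = c(0, 1), ylim = c(0, 1), xlab = "Recall",
                 ylab = "Precision", main = "One-vs-rest PR")
  for (i in seq_len(k)) {
    pos <- labels == (i - 1)
    if (!any(pos) || all(pos)) next
    ord <- order(scores[, i], decreasing = TRUE)
    y <- pos[ord]
    graphics::lines(cumsum(y) / sum(y), cumsum(y) / seq_along(y),
                    col = cols[i])
  }
  invisible(suppressWarnings(aurocAuprc(labels, scores)))
}
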