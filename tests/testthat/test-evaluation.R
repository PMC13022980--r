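test_that("confusion counts are conserved and validated", {
  ## perfect predictions give a diagonal matrix
  lab <- rep(0:4, each = 3)
  cm <- confusionCounts(lab, lab)
  expect_identical(unname(diag(cm)), rep(3L, 5))
  expect_identical(sum(cm) - sum(diag(cm)), 0L)
  ## empty input gives the zero matrix
  expect_identical(sum(confusionCounts(integer(0), integer(0))), 0L)
  ## totals are conserved
  set.seed(71)
  l <- sample(0:4, 100, TRUE); p <- sample(0:4, 100, TRUE)
  expect_identical(sum(confusionCounts(l, p)), 100L)
  expect_error(confusionCounts(c(0, 5), c(0, 1)), "0\\.\\.4")
  expect_error(confusionCounts(0:2, 0:1), "equal length")
})

test_that("binary metrics reproduce the worked 2x2 example to 4 decimals", {
  m <- binaryMetrics(tp = 40, tn = 45, fp = 10, fn = 5)
  expect_equal(unname(round(m, 4)),
               c(0.85, 0.8, 0.8889, 0.8421, 0.7035, 0.7))
  ## perfect classifier scores 1 on all six metrics
  expect_equal(unname(binaryMetrics(10, 20, 0, 0)), rep(1, 6))
  ## an all-one-class predictor on balanced data has kappa 0
  m0 <- binaryMetrics(tp = 50, tn = 0, fp = 50, fn = 0)
  expect_identical(unname(m0["kappa"]), 0)
  ## zero-denominator conventions
  expect_identical(unname(binaryMetrics(0, 10, 0, 0)[c("precision", "recall")]),
                   c(0, 0))
  expect_error(binaryMetrics(0, 0, 0, 0), "positive")
})

test_that("multiclass metrics reduce one-vs-rest and macro-average correctly", {
  cmI <- diag(10L, 5)
  mm <- multiclassMetrics(cmI)
  expect_true(all(abs(as.matrix(mm$perClass) - 1) < 1e-12))
  expect_equal(unname(mm$macro), rep(1, 6))
  expect_identical(mm$accuracy, 1)
  expect_identical(mm$kappa, 1)
  ## macro recall is exactly the mean of per-class recalls
  set.seed(72)
  cm <- matrix(rpois(25, 6), 5, 5)
  mm2 <- multiclassMetrics(cm)
  expect_identical(unname(mm2$macro["recall"]), mean(mm2$perClass$recall))
  ## overall accuracy is trace / total
  expect_identical(mm2$accuracy, sum(diag(cm)) / sum(cm))
})

test_that("multiclass kappa matches a brute-force implementation and oracles", {
  set.seed(73)
  for (i in 1:100) {
    cm <- matrix(rpois(25, sample(1:10, 1)), 5, 5)
    if (sum(cm) == 0) next
    expect_lt(abs(multiclassMetrics(cm)$kappa - bruteKappa(cm)), 1e-10)
  }
  ## independent library oracle on one matrix
  cm <- matrix(c(30, 3, 1, 0, 0,
                 4, 20, 2, 1, 0,
                 2, 3, 25, 2, 1,
                 0, 1, 2, 15, 2,
                 0, 0, 1, 2, 10), 5, 5, byrow = TRUE)
  expect_equal(multiclassMetrics(cm)$kappa,
               e1071::classAgreement(cm)$kappa, tolerance = 1e-10)
  ## kappa and MCC are invariant to simultaneous class permutation
  pr <- sample(5)
  expect_equal(multiclassMetrics(cm[pr, pr])$kappa, multiclassMetrics(cm)$kappa)
  expect_equal(sort(multiclassMetrics(cm[pr, pr])$perClass$mcc),
               sort(multiclassMetrics(cm)$perClass$mcc))
})

test_that("AUROC matches the pairwise oracle and handles ties and absences", {
  set.seed(74)
  n <- 200
  lab <- sample(0:4, n, TRUE)
  sc <- matrix(rnorm(n * 5), n, 5)
  sc[cbind(seq_len(n), lab + 1)] <- sc[cbind(seq_len(n), lab + 1)] + 1
  res <- aurocAuprc(lab, sc)
  for (k in 1:5) {
    expect_lt(abs(res$auroc[k] - bruteAuroc(sc[, k], lab == k - 1)), 1e-12)
  }
  ## independent library oracle
  expect_equal(res$auroc[1],
               as.numeric(suppressMessages(pROC::auc(lab == 0, sc[, 1]))),
               tolerance = 1e-10)
  ## perfectly separating scores
  sep <- matrix(0, 10, 5); lab2 <- rep(0:4, 2)
  sep[cbind(1:10, lab2 + 1)] <- 1
  resSep <- aurocAuprc(lab2, sep)
  expect_true(all(abs(resSep$auroc - 1) < 1e-12))
  expect_true(all(abs(resSep$auprc - 1) < 1e-12))
  ## identical scores for everyone: all ties, AUROC 1/2
  same <- matrix(1, 20, 5)
  resT <- aurocAuprc(rep(0:4, 4), same)
  expect_true(all(abs(resT$auroc - 0.5) < 1e-12))
  ## an absent class is flagged NA, not 0
  w <- capture_warnings(resA <- aurocAuprc(rep(0, 6), matrix(rnorm(30), 6, 5)))
  expect_true(any(grepl("absent", w)))
  expect_true(is.na(resA$auroc[2]))
})

test_that("stratified folds cover every sample once with balanced class shares", {
  lab <- rep(0:4, each = 20)
  fa <- stratifiedKFold(lab, k = 5, seed = 75)
  ## exact divisibility: 4 of each class per test fold
  for (f in 1:5) {
    tst <- fa@folds[[f]]$test
    expect_identical(as.integer(unname(table(factor(lab[tst], levels = 0:4)))),
                     rep(4L, 5))
  }
  ## every sample is a test sample exactly once
  allTest <- sort(unlist(lapply(fa@folds, `[[`, "test")))
  expect_identical(allTest, seq_along(lab))
  ## train/val/test partition the samples within each fold
  for (f in 1:5) {
    fd <- fa@folds[[f]]
    expect_identical(sort(c(fd$train, fd$val, fd$test)), seq_along(lab))
  }
  expect_error(stratifiedKFold(c(rep(0, 10), rep(1, 3)), k = 5), "class 1")
})

test_that("fold-level proportions stay within one sample of global shares", {
  counts <- c(258, 25, 53, 9, 7)
  lab <- rep(0:4, counts)
  fa <- stratifiedKFold(lab, k = 5, seed = 76)
  for (f in 1:5) {
    tst <- fa@folds[[f]]$test
    got <- table(factor(lab[tst], levels = 0:4))
    expected <- counts / 5      # global composition per equal fold share
    expect_true(all(abs(got - expected) <= 1 + 1e-9))
  }
})

test_that("fold summaries follow the Student-t interval", {
  s <- foldSummary(c(1, 2, 3, 4, 5))
  expect_equal(unname(s["mean"]), 3)
  expect_equal(unname(s["sd"]), 1.5811, tolerance = 1e-4)
  expect_equal(unname(s["ciHalfWidth"]), 1.963, tolerance = 1e-3)
  ## identical fold values: zero spread
  s0 <- foldSummary(rep(0.9, 5))
  expect_identical(unname(s0["sd"]), 0)
  expect_identical(unname(s0["ciHalfWidth"]), 0)
  ## half-width scales as 1/sqrt(k) for fixed SD (same t quantile)
  expect_error(foldSummary(1), "2 folds")
})

test_that("ROC/PR curves render to PNG", {
  set.seed(81)
  lab <- rep(0:4, 10)
  sc <- matrix(runif(250), 50, 5)
  path <- file.path(withr::local_tempdir(), "roc.png")
  res <- plotRocPr(lab, sc, path)
  expect_true(file.exists(path))
  expect_identical(nrow(res), 5L)
})
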