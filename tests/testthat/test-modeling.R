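test_that("correlation pruning keeps one member per over-threshold pair", {
  set.seed(1)
  n <- 400
  a <- rnorm(n)
  x <- cbind(A = a, B = a, C = rnorm(n), Creatinine = rnorm(n),
             `e GFR` = rnorm(n))
  sel <- correlationPrune(x, missingness = c(A = 0.1, B = 0.5))
  expect_true(xor("A" %in% sel@kept, "B" %in% sel@kept))
  # tie-break: the member with higher original missingness (B) is dropped
  expect_true("A" %in% sel@kept)
  expect_true("correlated_with:A" %in% sel@dropped$reason)
  expect_true(all(c("Creatinine", "e GFR") %in% sel@dropped$variable))
  expect_false("Creatinine" %in% sel@kept)
})

test_that("pruning is a no-op below threshold and flags constants", {
  set.seed(2)
  x <- cbind(A = rnorm(300), B = rnorm(300), C = rnorm(300),
             K = rep(1, 300), Creatinine = rnorm(300))
  expect_warning(sel <- correlationPrune(x, forcedExclusions = character(0)),
                 "constant")
  expect_setequal(sel@kept, c("A", "B", "C"))
  expect_equal(sel@dropped$reason[sel@dropped$variable == "K"], "constant")
})

test_that("an r = 0.92 analyte pair is pruned like MCV/MCH", {
  cfg <- defaultPanelConfig(nRecords = 2000, seed = 3)
  X <- labValues(completeTable(generateComplete(cfg)))
  sel <- correlationPrune(X[, setdiff(colnames(X),
                                      c("Age", "Weight", "Sex"))])
  expect_true(xor("MCV" %in% sel@kept, "MCH" %in% sel@kept))
  drop <- sel@dropped
  expect_true(any(grepl("^correlated_with:", drop$reason)))
})

test_that("min-max scaling maps training to [0,1] and leaves tests unclipped", {
  x <- cbind(v = c(2, 4, 6))
  sc <- minmaxScale(x)
  expect_equal(as.numeric(sc$scaled), c(0, 0.5, 1))
  mapped <- (8 - sc$scaler$lo) / (sc$scaler$hi - sc$scaler$lo)
  expect_equal(as.numeric(mapped), 1.5)
  expect_warning(sc0 <- minmaxScale(cbind(v = rep(3, 5))), "zero-range")
  expect_true(all(sc0$scaled == 0))
  expect_error(minmaxScale(x, fitRows = integer(0)), "non-empty")
})

test_that("macro-F1 matches Eq-style hand arithmetic and the brute force", {
  expect_equal(macroF1(diag(c(5, 8, 2))), 1)
  # all predictions in one class on balanced labels: F1 = 0.5 for that
  # class, 0 elsewhere
  cm <- matrix(0, 3, 3)
  cm[, 1] <- 10
  f <- macroF1(cm)
  expect_equal(f, 0.5 / 3, tolerance = 1e-12)
  # a class absent from truth and predictions contributes 0 with a warning
  cmAbsent <- rbind(c(5, 2, 0), c(1, 6, 0), c(0, 0, 0))
  expect_warning(macroF1(cmAbsent), "contributes F1 = 0")
  set.seed(4)
  for (i in 1:200) {
    cm <- matrix(sample(0:30, 9, TRUE), 3)
    if (sum(cm) == 0) next
    oracle <- mean(vapply(1:3, function(k) {
      tp <- cm[k, k]
      fp <- sum(cm[, k]) - tp
      fn <- sum(cm[k, ]) - tp
      if (tp + 0.5 * (fp + fn) == 0) 0 else tp / (tp + 0.5 * (fp + fn))
    }, numeric(1)))
    expect_lt(abs(suppressWarnings(macroF1(cm)) - oracle), 1e-12)
  }
  expect_error(macroF1(matrix(0, 3, 3)), "empty")
})

test_that("multiclass ROC hits the perfect and chance anchors", {
  set.seed(5)
  labels <- sample(1:3, 400, TRUE)
  onehot <- t(vapply(labels, function(k) as.numeric(1:3 == k), numeric(3)))
  expect_equal(multiclassRoc(onehot, labels, "micro")$auc, 1)
  expect_equal(multiclassRoc(onehot, labels, "macro")$auc, 1)
  # label-independent scores sit at chance
  n <- 10000
  labels2 <- sample(1:3, n, TRUE)
  sc <- matrix(runif(3 * n), n)
  sc <- sc / rowSums(sc)
  expect_gt(multiclassRoc(sc, labels2, "micro")$auc, 0.47)
  expect_lt(multiclassRoc(sc, labels2, "micro")$auc, 0.53)
  expect_gt(multiclassRoc(sc, labels2, "macro")$auc, 0.47)
  expect_lt(multiclassRoc(sc, labels2, "macro")$auc, 0.53)
  # balanced labels: the two averages nearly coincide
  expect_lt(abs(multiclassRoc(sc, labels2, "micro")$auc -
                  multiclassRoc(sc, labels2, "macro")$auc), 0.02)
})

test_that("ROC agrees with the rank-statistic oracle, including ties", {
  set.seed(6)
  for (i in 1:50) {
    n <- 200
    labels <- sample(1:3, n, TRUE)
    sc <- matrix(round(runif(3 * n), 2), n) # rounding forces ties
    sc <- sc / rowSums(sc)
    mic <- multiclassRoc(sc, labels, "micro")$auc
    oracleMic <- mwAuc(as.vector(vapply(1:3, function(k) labels == k,
                                        logical(n))), as.vector(sc))
    expect_lt(abs(mic - oracleMic), 1e-9)
    mac <- multiclassRoc(sc, labels, "macro")$auc
    oracleMac <- mean(vapply(1:3, function(k)
      mwAuc(labels == k, sc[, k]), numeric(1)))
    expect_lt(abs(mac - oracleMac), 1e-9)
  }
})

test_that("a missing class yields a warning and averaging over the rest", {
  labels <- c(1, 1, 2, 2)
  sc <- matrix(c(.8, .7, .2, .1, .2, .3, .8, .9, 0, 0, 0, 0), 4)
  expect_warning(r <- multiclassRoc(sc, labels, "macro"), "absent")
  expect_equal(r$auc, 1)
})

test_that("grid search honours singleton, tie and recovery contracts", {
  set.seed(7)
  n <- 300
  x <- matrix(rnorm(2 * n), n, dimnames = list(NULL, c("f1", "f2")))
  labels <- ifelse(x[, 1] < -0.4, 1L, ifelse(x[, 1] < 0.4, 2L, 3L))
  single <- gridSearchCv("rf", list(list(numTrees = 30)), x, labels,
                         seed = 1)
  expect_identical(single$best, list(numTrees = 30))
  twin <- gridSearchCv("rf", list(list(numTrees = 40), list(numTrees = 40)),
                       x, labels, folds = 3, seed = 1)
  expect_identical(twin$scores[1], twin$scores[2])
  expect_identical(twin$best, list(numTrees = 40))
  # a separable problem picks a grid point scoring as well as the best
  gs <- gridSearchCv("rf", list(list(numTrees = 5, maxDepth = 1),
                                list(numTrees = 60)),
                     x, labels, folds = 3, seed = 2)
  expect_equal(max(gs$scores), gs$scores[which.max(gs$scores)])
  expect_error(gridSearchCv("rf", list(), x, labels), "non-empty")
  expect_error(gridSearchCv("nope", list(list(), list()), x, labels,
                            folds = 2, seed = 1), "unknown model family")
})

test_that("cross-validation nails a separable problem and reports sanely", {
  set.seed(8)
  n <- 300
  x <- matrix(rnorm(2 * n), n, dimnames = list(NULL, c("f1", "f2")))
  labels <- ifelse(x[, 1] < -0.4, 1L, ifelse(x[, 1] < 0.4, 2L, 3L))
  rep <- crossValidate(x, labels, family = "rf",
                       grid = list(list(numTrees = 60)), k = 5, seed = 3)
  expect_gt(rep@accuracy, 0.9)
  expect_gt(rep@microAUC, 0.95)
  expect_equal(rowSums(rep@confusion), rep(1, 3), ignore_attr = TRUE,
               tolerance = 1e-9)
  expect_equal(nrow(rep@foldMetrics), 5)
})

test_that("permuted labels drop cross-validation to chance", {
  set.seed(9)
  n <- 360
  x <- matrix(rnorm(3 * n), n, dimnames = list(NULL, paste0("f", 1:3)))
  labels <- sample(rep(1:3, n / 3))
  rep <- crossValidate(x, labels, family = "logreg", k = 6, seed = 4)
  expect_lt(rep@accuracyCI[1], 1 / 3)
  expect_gt(rep@accuracyCI[2], 1 / 3)
  expect_gt(rep@microAUC, 0.4)
  expect_lt(rep@microAUC, 0.6)
})

test_that("fold hygiene: scaling is fitted on training folds only", {
  # a huge outlier in the test fold must not rescale its own fold
  x <- cbind(f1 = c(rnorm(99), 1000), f2 = rnorm(100))
  labels <- rep(1:3, length.out = 100)
  sc <- minmaxScale(x, fitRows = 1:99)
  mapped <- creatinet:::applyScaler(x, sc$scaler)
  expect_gt(mapped[100, "f1"], 1) # unclipped, outside the training range
})

test_that("degenerate fold requests fail loudly", {
  x <- matrix(rnorm(60), 30, dimnames = list(NULL, c("a", "b")))
  labels <- rep(1:3, each = 10)
  expect_warning(rep <- crossValidate(x, labels, family = "logreg", k = 30,
                                      seed = 1), "unstratified")
  expect_s4_class(rep, "ClassificationReport")
  bad <- c(rep(1L, 14), rep(2L, 15), 3L)
  expect_error(crossValidate(x, bad, family = "logreg", k = 10, seed = 1),
               "stratification failure")
  expect_error(crossValidate(x, labels, family = "logreg", k = 1), "k must")
})

test_that("every model family trains and emits calibrated-shape probabilities", {
  set.seed(10)
  n <- 150
  x <- matrix(rnorm(2 * n), n, dimnames = list(NULL, c("f1", "f2")))
  labels <- ifelse(x[, 1] + 0.3 * rnorm(n) < 0, 1L,
                   ifelse(x[, 2] < 0, 2L, 3L))
  for (fam in c("logreg", "svm", "rf", "gbt", "mlp")) {
    m <- creatinet:::fitModel(fam, x, labels, list(), seed = 1)
    p <- creatinet:::predictProbs(m, x)
    expect_identical(dim(p), as.integer(c(n, 3)))
    expect_equal(rowSums(p), rep(1, n), tolerance = 1e-3,
                 label = paste("probability rows of", fam))
  }
})
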