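test_that("initial mean fill reproduces hand means and flags dead columns", {
  x <- cbind(a = c(1, 3, NA), b = c(0.5, 1.0, 1.5))
  f <- initialFill(LabTable(x))
  expect_equal(unname(labValues(f)[3, "a"]), 2)
  x2 <- cbind(a = c(0.5, 1.0, 1.5, NA, NA))
  expect_equal(unname(labValues(initialFill(LabTable(x2)))[4:5, "a"]),
               c(1, 1))
  full <- LabTable(cbind(a = 1:3, b = 4:6))
  expect_identical(labValues(initialFill(full)), labValues(full))
  dead <- LabTable(cbind(a = c(NA, NA), b = c(1, 2)))
  expect_error(initialFill(dead), "'a'")
})

test_that("a table with no missing values passes through unchanged", {
  tab <- LabTable(cbind(a = rnorm(10), b = rnorm(10)))
  res <- multipleImpute(tab, exclude = character(0))
  expect_identical(labValues(res@table), labValues(tab))
  expect_identical(res@iterations, 0L)
  expect_true(res@converged)
})

test_that("chained regression recovers an exact linear relation", {
  set.seed(3)
  x <- runif(200)
  y <- 2 * x
  ym <- y
  ym[sample(200, 60)] <- NA
  res <- multipleImpute(LabTable(cbind(x = x, y = ym)),
                        core = "chained_regression", exclude = character(0),
                        seed = 1)
  expect_lt(max(abs(labValues(res@table)[, "y"] - y)), 1e-6)
  expect_true(res@converged)
})

test_that("observed cells are conserved bit-exactly by every method", {
  cfg <- gaussCopulaConfig(150, p = 4, seed = 5)
  tab <- maskedTable(generateLabPanel(cfg))
  obs <- !missingMask(tab)
  for (m in c("mean", "knn", "chained_regression", "random_forest",
              "bayesian_network", "autoencoder")) {
    out <- imputerFor(m, exclude = character(0), seed = 2, maxIter = 2,
                      options = list(numTrees = 20, aeEpochs = 30))(tab)
    expect_identical(labValues(out)[obs], labValues(tab)[obs],
                     label = paste("observed cells under", m))
  }
})

test_that("excluding creatinine makes imputation blind to it", {
  cfg <- gaussCopulaConfig(200, p = 5, seed = 6)
  vals <- labValues(maskedTable(generateLabPanel(cfg)))
  colnames(vals)[5] <- "Creatinine"
  tab1 <- LabTable(vals)
  vals2 <- vals
  set.seed(99)
  vals2[, "Creatinine"] <- sample(vals2[, "Creatinine"])
  tab2 <- LabTable(vals2)
  for (core in c("chained_regression", "random_forest")) {
    r1 <- multipleImpute(tab1, core = core, exclude = "Creatinine",
                         seed = 11, maxIter = 2,
                         options = list(numTrees = 20))
    r2 <- multipleImpute(tab2, core = core, exclude = "Creatinine",
                         seed = 11, maxIter = 2,
                         options = list(numTrees = 20))
    pred <- setdiff(colnames(vals), "Creatinine")
    expect_identical(labValues(r1@table)[, pred],
                     labValues(r2@table)[, pred],
                     label = paste("leakage guard under", core))
    # the excluded column itself passes through untouched
    expect_identical(labValues(r1@table)[, "Creatinine"],
                     vals[, "Creatinine"])
  }
  expect_identical(labValues(knnImpute(tab1, k = 3))[, "Creatinine"],
                   vals[, "Creatinine"])
})

test_that("core predictors honour their contracts on degenerate targets", {
  trainX <- matrix(rnorm(200), ncol = 2,
                   dimnames = list(NULL, c("p1", "p2")))
  queryX <- matrix(rnorm(20), ncol = 2,
                   dimnames = list(NULL, c("p1", "p2")))
  for (core in c("chained_regression", "random_forest", "bayesian_network",
                 "autoencoder")) {
    pred <- coreFitPredict(core, trainX, rep(7, 100), queryX, seed = 1,
                           options = list(aeEpochs = 50))
    expect_equal(pred, rep(7, 10), tolerance = 1e-6,
                 label = paste("constant target under", core))
  }
  expect_error(coreFitPredict("nope", trainX, rnorm(100), queryX),
               "unknown core")
})

test_that("chained regression is exact on y = 2x and falls back to ridge", {
  trainX <- matrix(c(1, 2, 4, 5), ncol = 1, dimnames = list(NULL, "x"))
  pred <- coreFitPredict("chained_regression", trainX, c(2, 4, 8, 10),
                         matrix(3, dimnames = list(NULL, "x")))
  expect_lt(abs(pred - 6), 1e-9)
  wide <- matrix(rnorm(12), nrow = 2,
                 dimnames = list(NULL, paste0("x", 1:6)))
  expect_warning(coreFitPredict("chained_regression", wide, c(1, 2),
                                wide), "ridge")
})

test_that("the BN core emits class-conditional medians", {
  set.seed(8)
  x <- c(rnorm(300, -5, 0.3), rnorm(300, 0, 0.3), rnorm(300, 5, 0.3))
  y <- c(rnorm(300, 10, 0.1), rnorm(300, 20, 0.1), rnorm(300, 30, 0.1))
  noise <- rnorm(900)
  trainX <- cbind(x = x, noise = noise)
  queryX <- cbind(x = c(-5, 0, 5), noise = c(0, 0, 0))
  pred <- coreFitPredict("bayesian_network", trainX, y, queryX, seed = 2)
  # mirror the core's discretization path (peaks, tercile fallback)
  sch <- tryCatch(peakCutpoints(y, variable = "y"),
                  error = function(e) quantileCutpoints(y, "y"))
  cls <- assignClasses(y, sch)
  meds <- tapply(y, cls, median)
  expect_equal(unname(pred), as.numeric(meds[c("1", "2", "3")]),
               tolerance = 1e-9)
})

test_that("KNN imputation matches hand-computed neighbours", {
  # duplicate rows: k = 1 copies the duplicate's value
  x <- cbind(a = c(1, 1, 5), b = c(10, NA, 50))
  out <- knnImpute(LabTable(x), k = 1, exclude = character(0))
  expect_equal(unname(labValues(out)[2, "b"]), 10)
  # k = n - 1 equals the column mean of the other rows' observed values
  x2 <- cbind(a = c(0, 0.5, 1, 0.2), b = c(4, 8, 12, NA))
  out2 <- knnImpute(LabTable(x2), k = 3, exclude = character(0))
  expect_equal(unname(labValues(out2)[4, "b"]), 8)
  # hand distance computation on a 4-row example (normalized scale):
  # row 4 (a=0.9) is nearest rows 3 (a=1) then 2 (a=0.5); k=2 averages them
  out3 <- knnImpute(LabTable(cbind(a = c(0, 0.5, 1, 0.9),
                                   b = c(4, 8, 12, NA))),
                    k = 2, exclude = character(0))
  expect_equal(unname(labValues(out3)[4, "b"]), 10)
  expect_error(knnImpute(LabTable(x), k = 0), "at least 1")
})

test_that("iterative changes shrink and the loop terminates", {
  cfg <- gaussCopulaConfig(800, p = 6, seed = 12)
  tab <- maskedTable(generateLabPanel(cfg))
  res <- multipleImpute(tab, core = "chained_regression",
                        exclude = character(0), maxIter = 8, tol = 1e-9,
                        seed = 3)
  ch <- res@changes
  expect_lte(res@iterations, 8L)
  if (length(ch) > 2) {
    # non-increasing after the second sweep, with 5% relative slack
    expect_true(all(diff(ch[-1]) <= 0.05 * ch[seq_len(length(ch) - 2) + 1]))
  }
})

test_that("model-based cores beat the mean baseline on correlated data", {
  cfg <- gaussCopulaConfig(1200, p = 8, r = 0.6, rate = 0.3, seed = 31)
  truth <- generateLabPanel(cfg)
  tab <- maskedTable(truth)
  base <- truthMse(imputerFor("mean", exclude = character(0))(tab), truth)
  for (core in c("chained_regression", "random_forest",
                 "bayesian_network", "autoencoder")) {
    m <- truthMse(imputerFor(core, exclude = character(0), seed = 4,
                             maxIter = 3,
                             options = list(numTrees = 50))(tab), truth)
    expect_lt(m, base, label = paste("masked MSE of", core))
  }
})
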