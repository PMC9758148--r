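test_that("Cockcroft-Gault formula reproduces worked values", {
  expect_equal(cockcroftGault(40, 72, 1.0, "male"), 100)
  expect_equal(cockcroftGault(40, 72, 1.0, "female"), 85)
  expect_equal(cockcroftGault(140, 80, 1.0, "male"), 0)
  expect_equal(cockcroftGault(40, 72, 1.0, 1), 85) # numeric sex coding
  expect_error(cockcroftGault(40, 72, 0, "male"), "positive")
})

test_that("generation is deterministic given config and seed", {
  cfg <- defaultPanelConfig(nRecords = 300, seed = 11)
  a <- generateLabPanel(cfg)
  b <- generateLabPanel(cfg)
  expect_identical(labValues(completeTable(a)), labValues(completeTable(b)))
  expect_identical(labValues(maskedTable(a)), labValues(maskedTable(b)))
  cfg2 <- defaultPanelConfig(nRecords = 300, seed = 12)
  c2 <- generateLabPanel(cfg2)
  expect_false(identical(labValues(completeTable(a)),
                         labValues(completeTable(c2))))
})

test_that("independent variables come out uncorrelated", {
  marg <- list(a = list(marginal = "gaussian", mean = 0, sd = 1),
               b = list(marginal = "gaussian", mean = 5, sd = 2))
  cfg <- labPanelConfig(10000, marg, seed = 2)
  X <- labValues(completeTable(generateComplete(cfg)))
  expect_lt(abs(cor(X[, "a"], X[, "b"])), 0.03)
})

test_that("latent correlations are realized (MCV-MCH block)", {
  cfg <- defaultPanelConfig(nRecords = 10000, seed = 5)
  X <- labValues(completeTable(generateComplete(cfg)))
  r <- cor(X[, "MCV"], X[, "MCH"])
  expect_gte(r, 0.89)
  expect_lte(r, 0.95)
  expect_gt(cor(X[, "Hemoglobin"], X[, "Hematocrit"]), 0.9)
})

test_that("marginals match their specs (KS < 0.05 at n = 5000)", {
  cfg <- defaultPanelConfig(nRecords = 5000, seed = 8)
  X <- labValues(completeTable(generateComplete(cfg)))
  ks <- suppressWarnings(ks.test(X[, "Hemoglobin"], "pnorm", 14, 1.7))
  expect_lt(unname(ks$statistic), 0.05)
  ksl <- suppressWarnings(ks.test(log(X[, "Ferritin"]), "pnorm", 4.1, 0.95))
  expect_lt(unname(ksl$statistic), 0.05)
  # creatinine keeps its stated trimodal mixture despite the planted effects
  m <- panelMarginals()$Creatinine
  pmix <- function(q) {
    rowSums(vapply(1:3, function(k)
      m$weights[k] * pnorm(q, m$means[k], m$sds[k]),
      numeric(length(q))))
  }
  cre <- X[, "Creatinine"]
  grid <- sort(cre)
  ksc <- max(abs(seq_along(grid) / length(grid) - pmix(grid)))
  expect_lt(ksc, 0.05)
})

test_that("planted vitamin-D effect is recovered by an OLS oracle", {
  cfg <- defaultPanelConfig(nRecords = 10000, seed = 3)
  X <- labValues(completeTable(generateComplete(cfg)))
  fit <- lm(X[, "Creatinine"] ~ X[, "Vitamin D (25 OH)"] + X[, "Ferritin"])
  expect_gt(coef(fit)[2], 0)
  expect_gt(coef(fit)[3], 0)
  # planted magnitude: latent correlation 0.8 survives the marginal
  # transforms to within 20%
  r <- cor(X[, "Vitamin D (25 OH)"], X[, "Creatinine"])
  expect_lt(abs(r - 0.8) / 0.8, 0.2)
})

test_that("non-PSD correlation and unknown marginals are rejected", {
  marg <- list(a = list(marginal = "gaussian", mean = 0, sd = 1),
               b = list(marginal = "gaussian", mean = 0, sd = 1))
  R <- matrix(c(1, 2, 2, 1), 2)
  expect_error(labPanelConfig(100, marg, R), "positive semi-definite")
  bad <- list(a = list(marginal = "weibull", shape = 1),
              b = list(marginal = "gaussian", mean = 0, sd = 1))
  cfg <- labPanelConfig(100, bad, seed = 1)
  expect_error(generateComplete(cfg), "unknown marginal")
})

test_that("MCAR missingness hits its target rates and is value-independent", {
  marg <- list(Hemoglobin = list(marginal = "gaussian", mean = 14, sd = 1.7),
               Other = list(marginal = "gaussian", mean = 0, sd = 1))
  cfg <- labPanelConfig(20000, marg,
                        missingRates = c(Hemoglobin = 0.4165),
                        seed = 6)
  tr <- generateLabPanel(cfg)
  frac <- missingFraction(maskedTable(tr))["Hemoglobin"]
  expect_gte(unname(frac), 0.397)
  expect_lte(unname(frac), 0.437)
  # independence of missingness from the underlying value (terciles)
  X <- labValues(completeTable(tr))
  m <- missingMask(maskedTable(tr))[, "Hemoglobin"]
  terc <- cut(X[, "Hemoglobin"],
              quantile(X[, "Hemoglobin"], c(0, 1 / 3, 2 / 3, 1)),
              include.lowest = TRUE)
  expect_gt(chisq.test(table(terc, m))$p.value, 0.01)
})

test_that("edge rates 0 and 1 behave as no-op and full mask", {
  marg <- list(a = list(marginal = "gaussian", mean = 0, sd = 1),
               b = list(marginal = "gaussian", mean = 0, sd = 1))
  cfg0 <- labPanelConfig(200, marg, missingRates = c(a = 0, b = 0), seed = 1)
  tr0 <- generateLabPanel(cfg0)
  expect_identical(labValues(maskedTable(tr0)), labValues(completeTable(tr0)))
  cfg1 <- labPanelConfig(200, marg, missingRates = c(a = 1), seed = 1)
  tr1 <- generateLabPanel(cfg1)
  expect_true(all(is.na(labValues(maskedTable(tr1))[, "a"])))
  expect_error(labPanelConfig(200, marg, missingRates = c(a = 1.2)),
               "\\[0, 1\\]")
})

test_that("MAR missingness tracks its driver and keeps the marginal rate", {
  marg <- list(driver = list(marginal = "gaussian", mean = 0, sd = 1),
               v = list(marginal = "gaussian", mean = 0, sd = 1))
  cfg <- labPanelConfig(8000, marg, missingRates = c(v = 0.4),
                        mechanism = "MAR", marDriver = "driver",
                        marSlope = 1.5, seed = 9)
  tr <- generateLabPanel(cfg)
  m <- missingMask(maskedTable(tr))[, "v"]
  expect_lt(abs(mean(m) - 0.4), 0.02)
  d <- labValues(completeTable(tr))[, "driver"]
  expect_gt(mean(d[m]), mean(d[!m]) + 0.3) # positive slope: high driver hides
})

test_that("masked and observed cells partition each column", {
  cfg <- defaultPanelConfig(nRecords = 400, seed = 13)
  tr <- generateLabPanel(cfg)
  X <- labValues(completeTable(tr))
  Xm <- labValues(maskedTable(tr))
  M <- tr@missingMask
  expect_true(all(is.na(Xm[M])))
  expect_identical(Xm[!M], X[!M])
})

test_that("planted effect pairs carry the highest mutual information", {
  cfg <- defaultPanelConfig(nRecords = 5000, seed = 21)
  X <- labValues(completeTable(generateComplete(cfg)))
  vars <- c("Creatinine", "Vitamin D (25 OH)", "Iron", "TSH", "Calcium",
            "Sodium", "Uric Acid")
  disc <- vapply(vars, function(v) {
    q <- quantile(X[, v], c(1 / 3, 2 / 3))
    findInterval(X[, v], q) + 1L
  }, integer(nrow(X)))
  miOf <- function(a, b) {
    tab <- table(a, b) / length(a)
    pa <- rowSums(tab); pb <- colSums(tab)
    sum(tab[tab > 0] * log(tab[tab > 0] / outer(pa, pb)[tab > 0]))
  }
  planted <- miOf(disc[, "Vitamin D (25 OH)"], disc[, "Creatinine"])
  others <- combn(setdiff(vars, "Creatinine"), 2, function(p)
    miOf(disc[, p[1]], disc[, p[2]]))
  expect_gt(planted, max(others))
})

test_that("CSV round-trip and truth sidecar preserve the panel", {
  cfg <- defaultPanelConfig(nRecords = 60, seed = 2)
  tr <- generateLabPanel(cfg)
  csv <- tempfile(fileext = ".csv"); json <- tempfile(fileext = ".json")
  writeTruth(tr, csv, json)
  back <- readLabTable(csv)
  expect_equal(labValues(back), labValues(maskedTable(tr)),
               ignore_attr = TRUE, tolerance = 1e-12)
  meta <- jsonlite::read_json(json, simplifyVector = TRUE)
  expect_equal(meta$n_records, 60)
  expect_true(all(c("parent", "child") %in% names(meta$true_graph)))
})
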