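#' Per-variable missingness profile of a routine blood-test panel
#'
#' The 46 blood-test parameters with their fraction of unrecorded values, as
#' observed in a large routine laboratory panel (~36k visits): the complete
#' blood count block is the best observed (~42% missing) and rarely ordered
#' chemistry such as serum albumin or basophil count exceeds 96%.
#'
#' @return named numeric vector of missing fractions in `[0, 1]`.
#' @export
panelMissingRates <- function() {
  c(Hemoglobin = 41.65, Hematocrit = 41.67, Lymphocyte = 41.77, MCV = 41.79,
    Platelets = 41.81, MCH = 41.81, Neutrophils = 41.83, MCHC = 41.86,
    Monocyte = 41.86, WBC = 42.05, RBC = 42.09, TSH = 55.63, FBS = 59.22,
    Creatinine = 62.84, `Blood Urea Nitrogen` = 63.30, `e GFR` = 65.06,
    Eosinophil = 65.96, Cholesterol = 70.27, Triglycerides = 70.36,
    `SGPT (ALT)` = 70.41, `Vitamin D (25 OH)` = 71.15, `SGOT (AST)` = 71.65,
    `LDL Cholesterol` = 75.47, `HDL Cholesterol` = 75.56, T4 = 77.50,
    T3 = 78.27, `Alkaline Phosphatase` = 78.54, `ESR 1 h` = 83.83,
    Ferritin = 84.64, `Uric Acid` = 86.52, Calcium = 87.93, Phosphorus = 90.44,
    Potassium = 91.68, Iron = 91.88, pH = 92.37, Sodium = 92.63,
    Prolactin = 92.71, `Bilirubin Total` = 92.98, `Bilirubin Direct` = 93.06,
    `Hb A1C` = 93.37, `Bilirubin Indirect` = 93.43, TIBC = 94.43,
    `Glucose (2 h p.p.)` = 96.11, `Anti TPO Antibody` = 96.22,
    `Serum Albumin` = 96.37, Basophil = 98.22) / 100
}

# plausible adult marginals for the 46 panel analytes (conventional units)
panelMarginals <- function() {
  g <- function(mean, sd) list(marginal = "gaussian", mean = mean, sd = sd)
  ln <- function(meanlog, sdlog) list(marginal = "lognormal",
                                      meanlog = meanlog, sdlog = sdlog)
  list(
    Hemoglobin = g(14, 1.7), Hematocrit = g(42, 4.5), Lymphocyte = g(32, 8),
    MCV = g(88, 6), Platelets = g(250, 60), MCH = g(29, 2.5),
    Neutrophils = g(58, 9), MCHC = g(33, 1.2), Monocyte = g(7, 2.2),
    WBC = ln(1.93, 0.28), RBC = g(4.9, 0.5), TSH = ln(0.6, 0.7),
    FBS = ln(4.58, 0.22), Creatinine = list(
      marginal = "mixture3", means = c(0.8, 1.0, 1.35),
      sds = c(0.045, 0.05, 0.25), weights = c(0.52, 0.27, 0.21)),
    `Blood Urea Nitrogen` = ln(2.73, 0.35), `e GFR` = g(90, 25),
    Eosinophil = ln(0.7, 0.7), Cholesterol = g(190, 38),
    Triglycerides = ln(4.92, 0.45), `SGPT (ALT)` = ln(3.1, 0.5),
    `Vitamin D (25 OH)` = ln(3.3, 0.55), `SGOT (AST)` = ln(3.1, 0.4),
    `LDL Cholesterol` = g(112, 32), `HDL Cholesterol` = g(48, 12),
    T4 = g(8.3, 1.8), T3 = g(1.2, 0.3), `Alkaline Phosphatase` = ln(5.3, 0.35),
    `ESR 1 h` = ln(2.6, 0.75), Ferritin = ln(4.1, 0.95),
    `Uric Acid` = g(5.4, 1.4), Calcium = g(9.5, 0.5), Phosphorus = g(3.6, 0.6),
    Potassium = g(4.3, 0.4), Iron = g(90, 32), pH = g(6.0, 0.7),
    Sodium = g(140, 3), Prolactin = ln(2.7, 0.6),
    `Bilirubin Total` = ln(-0.3, 0.45), `Bilirubin Direct` = ln(-1.5, 0.4),
    `Hb A1C` = ln(1.77, 0.2), `Bilirubin Indirect` = ln(-0.65, 0.45),
    TIBC = g(330, 50), `Glucose (2 h p.p.)` = ln(4.85, 0.3),
    `Anti TPO Antibody` = ln(2.8, 1.2), `Serum Albumin` = g(4.3, 0.4),
    Basophil = ln(-1.0, 0.5))
}

# latent correlation over the panel: strong CBC inter-correlations (MCV-MCH
# 0.92, Hb-Hct 0.96), lipid / liver / thyroid / bilirubin blocks, and zeros
# elsewhere (planted effects are added on top of this matrix at generation).
panelCorrelation <- function(vars) {
  R <- diag(length(vars))
  dimnames(R) <- list(vars, vars)
  setr <- function(a, b, r) {
    if (a %in% vars && b %in% vars) {
      R[a, b] <<- r; R[b, a] <<- r
    }
  }
  cbc <- intersect(c("Hemoglobin", "Hematocrit", "RBC", "MCV", "MCH", "MCHC"),
                   vars)
  for (i in seq_along(cbc)) for (j in seq_len(i - 1L))
    setr(cbc[i], cbc[j], 0.45)
  setr("Hemoglobin", "Hematocrit", 0.96)
  setr("Hemoglobin", "RBC", 0.75)
  setr("Hematocrit", "RBC", 0.78)
  setr("MCV", "MCH", 0.92)
  setr("MCH", "MCHC", 0.55)
  setr("Neutrophils", "Lymphocyte", -0.85)
  setr("Neutrophils", "WBC", 0.35)
  setr("Cholesterol", "LDL Cholesterol", 0.9)
  setr("Cholesterol", "HDL Cholesterol", 0.25)
  setr("Cholesterol", "Triglycerides", 0.35)
  setr("LDL Cholesterol", "Triglycerides", 0.25)
  setr("SGOT (AST)", "SGPT (ALT)", 0.7)
  setr("T3", "T4", 0.45)
  setr("Bilirubin Total", "Bilirubin Direct", 0.8)
  setr("Bilirubin Total", "Bilirubin Indirect", 0.9)
  setr("Bilirubin Direct", "Bilirubin Indirect", 0.55)
  setr("FBS", "Hb A1C", 0.65)
  setr("FBS", "Glucose (2 h p.p.)", 0.55)
  setr("Iron", "TIBC", -0.3)
  setr("Iron", "Ferritin", 0.35)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-8) {
    e <- eigen(R, symmetric = TRUE)
    R <- e$vectors %*% diag(pmax(e$values, 1e-6)) %*% t(e$vectors)
    d <- sqrt(diag(R))
    R <- R / outer(d, d)
    dimnames(R) <- list(vars, vars)
  }
  R
}

#' Build a generator configuration
#'
#' @param nRecords number of records (visits) to generate.
#' @param variables named list of marginal specs (see [panelMarginals()] for
#'   the format: `gaussian`, `lognormal` or `mixture3`).
#' @param correlation latent correlation matrix over `names(variables)`.
#' @param effects data.frame (`source`, `target`, `size`) of planted directed
#'   effects; `size` is signed and expressed in target-SD units per source-SD.
#' @param missingRates named numeric vector of per-variable missing fractions.
#' @param mechanism `"MCAR"`, or `"MAR"` with `marDriver`/`marSlope` giving the
#'   observed variable whose standardized value drives the logistic missingness
#'   probability.
#' @param marDriver,marSlope MAR mechanism parameters.
#' @param seed integer seed; the whole generation is deterministic given the
#'   configuration and this seed.
#' @return a \linkS4class{GeneratorConfig}.
#' @export
labPanelConfig <- function(nRecords, variables, correlation = NULL,
                           effects = NULL, missingRates = NULL,
                           mechanism = c("MCAR", "MAR"), marDriver = NULL,
                           marSlope = 1, seed = 1) {
  mechanism <- match.arg(mechanism)
  vn <- names(variables)
  if (is.null(correlation)) {
    correlation <- diag(length(vn))
    dimnames(correlation) <- list(vn, vn)
  }
  if (is.null(effects))
    effects <- data.frame(source = character(0), target = character(0),
                          size = numeric(0))
  if (is.null(missingRates)) missingRates <- stats::setNames(numeric(0), character(0))
  bad <- names(missingRates)[!names(missingRates) %in% vn]
  if (length(bad)) stop("missing rates name unknown variables: ",
                        paste(bad, collapse = ", "))
  mech <- list(kind = mechanism, driver = marDriver, slope = marSlope)
  if (mechanism == "MAR" && (is.null(marDriver) || !marDriver %in% vn))
    stop("MAR mechanism needs a driver variable present in the panel")
  new("GeneratorConfig", nRecords = nRecords, variables = variables,
      correlation = correlation, effects = effects,
      missingRates = missingRates, mechanism = mech, seed = seed)
}

#' The default desk-scale panel configuration
#'
#' The full 46-parameter panel with the observed missingness profile
#' ([panelMissingRates()]), block-structured latent correlations
#' ([panelCorrelation()]), a trimodal creatinine marginal, and two planted
#' positive effects on creatinine: vitamin D (+0.8 SD) and ferritin (+0.5 SD).
#'
#' @param nRecords rows to generate (default 3000; the full-size study scale
#'   of ~36k rows is supported but not the default).
#' @param subset optional character vector restricting the panel to a subset
#'   of the 46 parameters (effect variables are retained automatically).
#' @param vitaminDEffect,ferritinEffect planted effect sizes on creatinine.
#' @param seed integer seed.
#' @inheritParams labPanelConfig
#' @return a \linkS4class{GeneratorConfig}.
#' @export
defaultPanelConfig <- function(nRecords = 3000, subset = NULL,
                               vitaminDEffect = 0.8, ferritinEffect = 0.5,
                               mechanism = "MCAR", marDriver = NULL,
                               marSlope = 1, seed = 1) {
  marg <- panelMarginals()
  if (!is.null(subset)) {
    subset <- union(subset, c("Creatinine", "Vitamin D (25 OH)", "Ferritin",
                              "e GFR"))
    marg <- marg[intersect(names(marg), subset)]
  }
  vn <- names(marg)
  eff <- data.frame(
    source = c("Vitamin D (25 OH)", "Ferritin"),
    target = c("Creatinine", "Creatinine"),
    size = c(vitaminDEffect, ferritinEffect))
  eff <- eff[eff$size != 0, , drop = FALSE]
  labPanelConfig(nRecords, marg, panelCorrelation(vn), eff,
                 panelMissingRates()[vn], mechanism = mechanism,
                 marDriver = marDriver, marSlope = marSlope, seed = seed)
}

#' Cockcroft-Gault estimated glomerular filtration rate
#'
#' eGFR = ((140 - age) x weight) / (72 x creatinine), multiplied by 0.85 for
#' females. Inversely related to serum creatinine by construction.
#'
#' @param age years; @param weight kilograms.
#' @param creatinine serum creatinine (mg/dL), strictly positive.
#' @param sex `"male"`/`"female"` (or 0/1 with 1 = female).
#' @return eGFR estimate (mL/min).
#' @examples
#' cockcroftGault(40, 72, 1.0, "male")   # 100
#' cockcroftGault(40, 72, 1.0, "female") # 85
#' @export
cockcroftGault <- function(age, weight, creatinine, sex) {
  if (any(creatinine <= 0)) stop("creatinine must be strictly positive")
  female <- if (is.character(sex) || is.factor(sex))
    as.character(sex) == "female" else sex == 1
  val <- ((140 - age) * weight) / (72 * creatinine)
  ifelse(female, 0.85 * val, val)
}

# quantile function for one marginal spec
marginalQuantile <- function(spec, u) {
  switch(spec$marginal,
    gaussian = stats::qnorm(u, spec$mean, spec$sd),
    lognormal = stats::qlnorm(u, spec$meanlog, spec$sdlog),
    mixture3 = {
      lo <- min(spec$means - 6 * spec$sds)
      hi <- max(spec$means + 6 * spec$sds)
      grid <- seq(lo, hi, length.out = 4096)
      p <- rowSums(vapply(seq_along(spec$means), function(k)
        spec$weights[k] * stats::pnorm(grid, spec$means[k], spec$sds[k]),
        numeric(length(grid))))
      stats::approx(p, grid, xout = u, rule = 2, ties = "ordered")$y
    },
    stop("unknown marginal family: ", spec$marginal))
}

marginalSd <- function(spec) {
  switch(spec$marginal,
    gaussian = spec$sd,
    lognormal = sqrt((exp(spec$sdlog^2) - 1) *
                       exp(2 * spec$meanlog + spec$sdlog^2)),
    mixture3 = {
      m <- sum(spec$weights * spec$means)
      sqrt(sum(spec$weights * (spec$sds^2 + spec$means^2)) - m^2)
    })
}

# fold planted effects into the latent layer: the target's latent normal is
# rebuilt as sum(size_e * z_source) + b * z_target with b chosen to restore
# unit variance, so the stated marginal shape is preserved exactly while the
# association is planted at the stated magnitude.
applyLatentEffects <- function(Z, R, effects) {
  for (tgt in unique(effects$target)) {
    rows <- effects[effects$target == tgt, , drop = FALSE]
    s <- stats::setNames(rows$size, rows$source)
    Rss <- R[rows$source, rows$source, drop = FALSE]
    Rst <- R[rows$source, tgt]
    q <- drop(t(s) %*% Rss %*% s)
    cc <- drop(crossprod(s, Rst))
    disc <- cc^2 - (q - 1)
    if (disc < 0)
      stop("planted effects on '", tgt, "' are too large to keep unit variance")
    b <- -cc + sqrt(disc)
    Z[, tgt] <- Z[, rows$source, drop = FALSE] %*% s + b * Z[, tgt]
  }
  Z
}

#' Generate the complete (fully observed) synthetic panel
#'
#' Draws correlated latent normals (Gaussian copula), transforms each column
#' through its marginal quantile function, plants the configured directed
#' effects in the latent layer, simulates demographics (age, weight, sex) and
#' derives the `e GFR` column from creatinine via Cockcroft-Gault.
#'
#' @param config a \linkS4class{GeneratorConfig}.
#' @return a \linkS4class{SyntheticTruth} with `complete` filled and `masked`
#'   still empty.
#' @export
generateComplete <- function(config) {
  validObject(config)
  vn <- names(config@variables)
  n <- as.integer(config@nRecords)
  R <- config@correlation
  dimnames(R) <- list(vn, vn)
  withSeed(config@seed, {
    ch <- tryCatch(chol(R), error = function(e) {
      e2 <- eigen(R, symmetric = TRUE)
      chol(e2$vectors %*% diag(pmax(e2$values, 1e-8)) %*% t(e2$vectors) +
             diag(1e-10, nrow(R)))
    })
    Z <- matrix(stats::rnorm(n * length(vn)), n) %*% ch
    colnames(Z) <- vn
    if (nrow(config@effects)) Z <- applyLatentEffects(Z, R, config@effects)
    U <- stats::pnorm(Z)
    X <- vapply(vn, function(v) marginalQuantile(config@variables[[v]], U[, v]),
                numeric(n))
    colnames(X) <- vn
    age <- pmin(pmax(stats::rnorm(n, 46, 17), 18), 90)
    weight <- pmin(pmax(stats::rnorm(n, 72, 14), 40), 140)
    sex <- stats::rbinom(n, 1, 0.5) # 1 = female
    if ("Creatinine" %in% vn) {
      X[, "Creatinine"] <- pmax(X[, "Creatinine"], 0.05)
      if ("e GFR" %in% vn)
        X[, "e GFR"] <- cockcroftGault(age, weight, X[, "Creatinine"], sex)
    }
    X <- cbind(X, Age = age, Weight = weight, Sex = sex)
    trueEdges <- as.matrix(config@effects[, c("source", "target")])
    if (all(c("Creatinine", "e GFR") %in% vn))
      trueEdges <- rbind(trueEdges,
                         cbind(c("Creatinine", "Age", "Weight", "Sex"), "e GFR"))
    colnames(trueEdges) <- c("parent", "child")
    new("SyntheticTruth", complete = LabTable(X), masked = LabTable(X),
        missingMask = matrix(FALSE, n, ncol(X),
                             dimnames = list(NULL, colnames(X))),
        trueGraph = trueEdges, config = config)
  })
}

#' Apply the configured missingness mechanism
#'
#' Under MCAR each cell of a variable is hidden independently with the
#' configured rate; under MAR the hiding probability is a logistic function of
#' the standardized driver variable, with the intercept calibrated so the
#' marginal rate is preserved.
#'
#' @param truth a \linkS4class{SyntheticTruth} from [generateComplete()].
#' @param config the same \linkS4class{GeneratorConfig} (defaults to the one
#'   recorded in `truth`).
#' @return `truth` with `masked` and `missingMask` populated.
#' @export
applyMissingness <- function(truth, config = truth@config) {
  X <- labValues(truth@complete)
  n <- nrow(X)
  rates <- config@missingRates
  if (length(rates) && (min(rates) < 0 || max(rates) > 1))
    stop("missing rates must lie in [0, 1]")
  mask <- matrix(FALSE, n, ncol(X), dimnames = list(NULL, colnames(X)))
  withSeed(config@seed + 1000003, {
    for (v in names(rates)) {
      r <- rates[[v]]
      if (r <= 0) next
      if (config@mechanism$kind == "MCAR") {
        mask[, v] <- stats::runif(n) < r
      } else {
        d <- X[, config@mechanism$driver]
        z <- as.numeric(scale(d))
        slope <- config@mechanism$slope
        a <- stats::uniroot(function(a0) mean(stats::plogis(a0 + slope * z)) - r,
                            c(-40, 40))$root
        mask[, v] <- stats::runif(n) < stats::plogis(a + slope * z)
      }
    }
  })
  Xm <- X
  Xm[mask] <- NA_real_
  truth@masked <- LabTable(Xm)
  truth@missingMask <- mask
  truth
}

#' Generate a masked synthetic lab panel in one call
#'
#' @inheritParams generateComplete
#' @return a \linkS4class{SyntheticTruth} with both tables populated.
#' @examples
#' cfg <- defaultPanelConfig(nRecords = 500, seed = 7)
#' truth <- generateLabPanel(cfg)
#' missingFraction(maskedTable(truth))[c("Hemoglobin", "Creatinine")]
#' @export
generateLabPanel <- function(config) {
  applyMissingness(generateComplete(config), config)
}

#' @rdname completeTable
#' @export
setMethod("completeTable", "SyntheticTruth", function(x) x@complete)

#' @rdname maskedTable
#' @export
setMethod("maskedTable", "SyntheticTruth", function(x) x@masked)

#' @rdname trueGraph
#' @export
setMethod("trueGraph", "SyntheticTruth", function(x) x@trueGraph)

setMethod("show", "SyntheticTruth", function(object) {
  d <- dim(labValues(object@complete))
  cat(sprintf("SyntheticTruth: %d records x %d columns, %d planted edges\n",
              d[1], d[2], nrow(object@trueGraph)))
})

#' Export a synthetic panel as CSV plus JSON ground-truth sidecar
#'
#' @param truth a \linkS4class{SyntheticTruth}.
#' @param csv,json output paths; blank CSV cells encode missing values.
#' @export
writeTruth <- function(truth, csv, json) {
  writeLabTable(truth@masked, csv)
  pos <- which(truth@missingMask, arr.ind = TRUE)
  meta <- list(
    seed = truth@config@seed,
    n_records = nrow(labValues(truth@complete)),
    true_graph = as.data.frame(truth@trueGraph),
    missing_positions = data.frame(row = pos[, 1],
                                   variable = colnames(truth@missingMask)[pos[, 2]]),
    missing_rates = as.list(truth@config@missingRates),
    mechanism = truth@config@mechanism$kind)
  jsonlite::write_json(meta, json, auto_unbox = TRUE, digits = NA)
  invisible(csv)
}
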