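#' Correlation-based predictor pruning
#'
#' Drops the target and forced exclusions first (blood urea nitrogen and eGFR
#' are excluded by default as factors already known to reflect kidney
#' function), then scans predictor pairs with absolute Pearson correlation
#' above the threshold in decreasing-|r| order, dropping one member per pair
#' until no pair exceeds the threshold. Within a pair the member with the
#' higher original missingness is dropped (better-observed predictors are
#' favoured); equal missingness falls back to alphabetical order.
#'
#' @param table completed \linkS4class{LabTable} (or numeric matrix).
#' @param threshold absolute correlation threshold (default 0.5).
#' @param forcedExclusions variables always dropped.
#' @param target the outcome variable, always dropped.
#' @param missingness named numeric vector of original missing fractions used
#'   for the tie-break (defaults to the panel profile; unknown names count 0).
#' @return a \linkS4class{FeatureSelection}.
#' @export
correlationPrune <- function(table, threshold = 0.5,
                             forcedExclusions = c("Blood Urea Nitrogen",
                                                  "e GFR"),
                             target = "Creatinine", missingness = NULL) {
  vals <- if (is(table, "LabTable")) labValues(table) else as.matrix(table)
  if (is.null(missingness)) missingness <- panelMissingRates()
  missOf <- function(v) {
    m <- missingness[v]
    ifelse(is.na(m), 0, m)
  }
  dropped <- data.frame(variable = character(0), reason = character(0))
  addDrop <- function(v, reason)
    dropped <<- rbind(dropped, data.frame(variable = v, reason = reason))
  cand <- colnames(vals)
  if (target %in% cand) addDrop(target, "target")
  for (v in intersect(forcedExclusions, cand))
    addDrop(v, "forced_exclusion")
  cand <- setdiff(cand, c(target, forcedExclusions))
  const <- cand[apply(vals[, cand, drop = FALSE], 2,
                      function(x) stats::sd(x, na.rm = TRUE) == 0 ||
                        all(is.na(x)))]
  if (length(const)) {
    warning("constant columns dropped: ", paste(const, collapse = ", "))
    for (v in const) addDrop(v, "constant")
    cand <- setdiff(cand, const)
  }
  if (length(cand) > 1) {
    cm <- suppressWarnings(stats::cor(vals[, cand, drop = FALSE],
                                      use = "pairwise.complete.obs"))
    diag(cm) <- 0
    cm[is.na(cm)] <- 0
    repeat {
      top <- which(abs(cm) == max(abs(cm)), arr.ind = TRUE)[1, ]
      if (abs(cm[top[1], top[2]]) <= threshold) break
      a <- rownames(cm)[top[1]]; b <- colnames(cm)[top[2]]
      victim <- if (missOf(a) > missOf(b)) a
                else if (missOf(b) > missOf(a)) b
                else max(a, b)
      keeper <- setdiff(c(a, b), victim)
      addDrop(victim, paste0("correlated_with:", keeper))
      keep <- setdiff(rownames(cm), victim)
      cm <- cm[keep, keep, drop = FALSE]
      if (nrow(cm) < 2) break
    }
    cand <- rownames(cm)
  }
  new("FeatureSelection", kept = cand, dropped = dropped,
      threshold = threshold)
}

setMethod("show", "FeatureSelection", function(object) {
  cat(sprintf("FeatureSelection: %d kept, %d dropped (|r| > %.2f)\n",
              length(object@kept), nrow(object@dropped), object@threshold))
})

#' Min-max scaling fitted on training rows only
#'
#' @param table \linkS4class{LabTable} or numeric matrix.
#' @param fitRows row indices the scaler is fitted on (training fold);
#'   transformed values of other rows may fall outside `[0, 1]` and are not
#'   clipped.
#' @return list with `scaled` (full matrix) and `scaler` (`lo`, `hi`).
#' @export
minmaxScale <- function(table, fitRows = NULL) {
  vals <- if (is(table, "LabTable")) labValues(table) else as.matrix(table)
  if (is.null(fitRows)) fitRows <- seq_len(nrow(vals))
  if (!length(fitRows)) stop("fit rows must be non-empty")
  lo <- apply(vals[fitRows, , drop = FALSE], 2, min)
  hi <- apply(vals[fitRows, , drop = FALSE], 2, max)
  zero <- hi - lo <= 0
  if (any(zero))
    warning("zero-range columns mapped to 0: ",
            paste(colnames(vals)[zero], collapse = ", "))
  scaled <- vals
  for (j in seq_len(ncol(vals))) {
    scaled[, j] <- if (zero[j]) 0 else (vals[, j] - lo[j]) / (hi[j] - lo[j])
  }
  list(scaled = scaled, scaler = list(lo = lo, hi = hi, zero = zero))
}

applyScaler <- function(vals, scaler) {
  out <- vals
  for (j in seq_len(ncol(vals))) {
    out[, j] <- if (scaler$zero[j]) 0
                else (vals[, j] - scaler$lo[j]) / (scaler$hi[j] - scaler$lo[j])
  }
  out
}

# ---- model family adapter ---------------------------------------------------

treeBased <- function(family) family %in% c("rf", "gbt")

# uniform fit/predict seam over the classifier libraries
fitModel <- function(family, x, y, params = list(), seed = 1) {
  y <- factor(y, levels = 1:3)
  df <- data.frame(x, check.names = TRUE)
  withSeed(seed, switch(family,
    logreg = {
      df2 <- df
      df2$.cls <- y
      fit <- nnet::multinom(.cls ~ ., data = df2,
                            maxit = params$maxit %||% 200, trace = FALSE)
      list(family = family, fit = fit, cols = colnames(df))
    },
    svm = {
      fit <- e1071::svm(x = as.matrix(df), y = y, probability = TRUE,
                        kernel = params$kernel %||% "radial",
                        cost = params$cost %||% 1,
                        gamma = params$gamma %||% (1 / ncol(df)))
      list(family = family, fit = fit, cols = colnames(df))
    },
    rf = {
      fit <- ranger::ranger(x = df, y = y, probability = TRUE,
                            num.trees = params$numTrees %||% 200,
                            mtry = params$mtry %||%
                              max(1, floor(sqrt(ncol(df)))),
                            min.node.size = params$minNode %||% 10,
                            seed = seed, num.threads = 1)
      list(family = family, fit = fit, cols = colnames(df))
    },
    gbt = {
      dtrain <- xgboost::xgb.DMatrix(as.matrix(df),
                                     label = as.integer(y) - 1)
      fit <- xgboost::xgb.train(
        params = list(objective = "multi:softprob", num_class = 3,
                      max_depth = params$maxDepth %||% 4,
                      eta = params$eta %||% 0.2,
                      subsample = params$subsample %||% 1,
                      nthread = 1, seed = seed),
        data = dtrain, nrounds = params$nrounds %||% 60, verbose = 0)
      list(family = family, fit = fit, cols = colnames(df))
    },
    mlp = {
      fit <- nnet::nnet(x = as.matrix(df), y = stats::model.matrix(~ y - 1),
                        size = params$size %||% 8,
                        decay = params$decay %||% 1e-3,
                        maxit = params$maxit %||% 200, trace = FALSE,
                        softmax = TRUE, MaxNWts = 10000)
      list(family = family, fit = fit, cols = colnames(df))
    },
    stop("unknown model family: ", family)))
}

predictProbs <- function(model, x) {
  df <- data.frame(x, check.names = TRUE)
  colnames(df) <- model$cols
  p <- switch(model$family,
    logreg = stats::predict(model$fit, newdata = df, type = "probs"),
    svm = {
      pr <- stats::predict(model$fit, as.matrix(df), probability = TRUE)
      at <- attr(pr, "probabilities")
      at[, as.character(1:3), drop = FALSE]
    },
    rf = stats::predict(model$fit, df, num.threads = 1)$predictions,
    gbt = {
      pr <- stats::predict(model$fit, xgboost::xgb.DMatrix(as.matrix(df)))
      if (is.null(dim(pr))) pr <- matrix(pr, ncol = 3, byrow = TRUE)
      pr
    },
    mlp = stats::predict(model$fit, as.matrix(df)))
  if (is.null(dim(p))) p <- matrix(p, nrow = 1, dimnames = list(NULL, names(p)))
  p <- as.matrix(p)
  colnames(p) <- 1:3
  unname(p)
}

# ---- metrics ----------------------------------------------------------------

#' Confusion matrix of multiclass predictions
#' @param truth,predicted integer class labels in `{1, 2, 3}`.
#' @return 3x3 count matrix (rows = true class, cols = predicted class).
#' @export
confusionCounts <- function(truth, predicted) {
  m <- table(factor(truth, 1:3), factor(predicted, 1:3))
  matrix(as.integer(m), 3, 3, dimnames = list(true = 1:3, pred = 1:3))
}

#' Macro-averaged F1 from a 3x3 confusion matrix
#'
#' Per class, one-vs-rest F1 = TP / (TP + (FP + FN) / 2); the macro score is
#' their unweighted mean. A class with no true or predicted samples
#' contributes F1 = 0 with a warning.
#'
#' @param cm 3x3 count matrix, rows = true class, cols = predicted class.
#' @return macro-F1 in `[0, 1]`.
#' @export
macroF1 <- function(cm) {
  cm <- as.matrix(cm)
  if (sum(cm) == 0) stop("empty confusion matrix")
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  denom <- tp + 0.5 * (fp + fn)
  f1 <- ifelse(denom > 0, tp / denom, 0)
  if (any(denom == 0))
    warning("class with no true or predicted samples contributes F1 = 0")
  mean(f1)
}

#' Accuracy from a confusion matrix
#' @param cm count matrix.
#' @export
accuracyOf <- function(cm) sum(diag(as.matrix(cm))) / sum(cm)

# exact binary ROC with tie handling; returns curve (fpr, tpr) and
# trapezoid AUC (equals the Mann-Whitney statistic with 0.5 tie credit)
binaryRoc <- function(pos, score) {
  ord <- order(score, decreasing = TRUE)
  pos <- pos[ord]; score <- score[ord]
  P <- sum(pos); N <- length(pos) - P
  if (P == 0 || N == 0) return(NULL)
  grp <- cumsum(!duplicated(score))
  tp <- cumsum(pos); fp <- cumsum(!pos)
  last <- !duplicated(grp, fromLast = TRUE)
  tpr <- c(0, tp[last] / P)
  fpr <- c(0, fp[last] / N)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(curve = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' Multiclass ROC curve and AUC by micro or macro averaging
#'
#' Per-class curves are one-vs-rest (the class against the two others
#' pooled). Micro averaging pools the flattened indicator/score pairs of all
#' classes into one binary problem; macro averaging takes the unweighted mean
#' of the per-class AUCs, with the reported macro curve interpolated on a
#' common grid of 101 false-positive points.
#'
#' @param scores n x 3 matrix of class probabilities (rows sum to ~1).
#' @param labels integer true classes in `{1, 2, 3}`.
#' @param averaging `"micro"` or `"macro"`.
#' @return list with `auc`, `curve` (data.frame fpr/tpr) and `perClass`
#'   (per-class curves and AUCs). A class absent from the labels is skipped
#'   with a warning under macro averaging.
#' @export
multiclassRoc <- function(scores, labels, averaging = c("micro", "macro")) {
  averaging <- match.arg(averaging)
  scores <- as.matrix(scores)
  perClass <- lapply(1:3, function(k) binaryRoc(labels == k, scores[, k]))
  names(perClass) <- paste0("class", 1:3)
  present <- !vapply(perClass, is.null, logical(1))
  if (!all(present))
    warning("class absent from labels; averaging over present classes")
  if (averaging == "micro") {
    pooledPos <- as.vector(vapply(1:3, function(k) labels == k,
                                  logical(length(labels))))
    pooledScore <- as.vector(scores)
    r <- binaryRoc(pooledPos, pooledScore)
    list(auc = r$auc, curve = r$curve, perClass = perClass)
  } else {
    grid <- seq(0, 1, length.out = 101)
    tprs <- vapply(perClass[present], function(r)
      stats::approx(r$curve$fpr, r$curve$tpr, xout = grid, ties = max,
                    yleft = 0, yright = 1)$y, numeric(101))
    auc <- mean(vapply(perClass[present], `[[`, numeric(1), "auc"))
    list(auc = auc,
         curve = data.frame(fpr = grid, tpr = rowMeans(tprs)),
         perClass = perClass)
  }
}

#' Exhaustive grid search by internal cross-validation
#'
#' Evaluates every grid point with stratified k-fold cross-validation on the
#' supplied training data and returns the arg-max by the metric; ties are
#' broken toward the first-listed grid point.
#'
#' @param family model family (`"logreg"`, `"svm"`, `"rf"`, `"gbt"`,
#'   `"mlp"`).
#' @param grid list of named hyperparameter lists (non-empty).
#' @param x predictor matrix (already scaled where the family needs it).
#' @param labels integer classes.
#' @param folds internal folds (default 10).
#' @param metric `"accuracy"` or `"macroF1"`.
#' @param seed integer seed.
#' @return list with `best` (the chosen parameter list) and `scores`.
#' @export
gridSearchCv <- function(family, grid, x, labels, folds = 10,
                         metric = c("accuracy", "macroF1"), seed = 1) {
  metric <- match.arg(metric)
  if (!length(grid)) stop("grid must be non-empty")
  if (length(grid) == 1)
    return(list(best = grid[[1]], scores = NA_real_))
  fold <- stratifiedFolds(labels, folds, seed)
  scores <- vapply(seq_along(grid), function(g) {
    preds <- integer(length(labels))
    for (f in sort(unique(fold))) {
      te <- fold == f
      m <- fitModel(family, x[!te, , drop = FALSE], labels[!te],
                    grid[[g]], seed = seed)
      p <- predictProbs(m, x[te, , drop = FALSE])
      preds[te] <- max.col(p, ties.method = "first")
    }
    cm <- confusionCounts(labels, preds)
    if (metric == "accuracy") accuracyOf(cm) else suppressWarnings(macroF1(cm))
  }, numeric(1))
  list(best = grid[[which.max(scores)]], scores = scores)
}

stratifiedFolds <- function(labels, k, seed) {
  n <- length(labels)
  if (k > n) stop("more folds than samples")
  fold <- integer(n)
  withSeed(seed, {
    if (k == n) {
      fold <- sample(n) # leave-one-out: no stratification possible
    } else {
      for (cl in unique(labels)) {
        idx <- sample(which(labels == cl))
        fold[idx] <- rep_len(seq_len(k), length(idx))
      }
    }
  })
  fold
}

#' Tenfold cross-validated evaluation of one classification pipeline
#'
#' Stratified folds; min-max scaling (for non-tree families) and grid search
#' are fitted within each training fold only, so no test-fold statistic leaks
#' into training. Reports fold-averaged accuracy and macro-F1 with
#' normal-approximation 95 percent confidence intervals, pooled micro/macro
#' ROC-AUC, and the pooled row-normalized confusion matrix.
#'
#' @param table completed predictor \linkS4class{LabTable} or matrix.
#' @param labels integer target classes in `{1, 2, 3}`.
#' @param family model family, see [gridSearchCv()].
#' @param grid hyperparameter grid (default a single empty point, meaning the
#'   family defaults).
#' @param k outer folds (default 10); `k = n` runs leave-one-out without
#'   stratification, with a warning.
#' @param innerFolds folds of the internal grid search (default 3).
#' @param seed fold-assignment seed.
#' @return a \linkS4class{ClassificationReport}.
#' @export
crossValidate <- function(table, labels, family = "rf", grid = list(list()),
                          k = 10, innerFolds = 3, seed = 1) {
  vals <- if (is(table, "LabTable")) labValues(table) else as.matrix(table)
  n <- nrow(vals)
  if (k < 2 || k > n) stop("k must lie in [2, n]")
  if (k == n) warning("leave-one-out requested; folds are unstratified")
  fold <- stratifiedFolds(labels, k, seed)
  if (k < n) {
    for (f in seq_len(k)) {
      if (length(setdiff(unique(labels), unique(labels[fold != f]))))
        stop("stratification failure: class absent from a training fold")
    }
  }
  probs <- matrix(NA_real_, n, 3)
  preds <- integer(n)
  foldAcc <- foldF1 <- numeric(k)
  chosen <- NULL
  for (f in seq_len(k)) {
    te <- fold == f
    xtr <- vals[!te, , drop = FALSE]
    xte <- vals[te, , drop = FALSE]
    if (!treeBased(family)) {
      sc <- suppressWarnings(minmaxScale(xtr))
      xtr <- sc$scaled
      xte <- applyScaler(xte, sc$scaler)
    }
    gs <- gridSearchCv(family, grid, xtr, labels[!te], folds = innerFolds,
                       seed = seed + f)
    chosen <- gs$best
    m <- fitModel(family, xtr, labels[!te], gs$best, seed = seed + 100 + f)
    p <- predictProbs(m, xte)
    probs[te, ] <- p
    preds[te] <- max.col(p, ties.method = "first")
    cm <- confusionCounts(labels[te], preds[te])
    foldAcc[f] <- accuracyOf(cm)
    foldF1[f] <- suppressWarnings(macroF1(cm))
  }
  ciOf <- function(xs) mean(xs) + c(-1, 1) * 1.96 * stats::sd(xs) / sqrt(k)
  cm <- confusionCounts(labels, preds)
  cmNorm <- cm / pmax(rowSums(cm), 1)
  micro <- multiclassRoc(probs, labels, "micro")
  macro <- suppressWarnings(multiclassRoc(probs, labels, "macro"))
  new("ClassificationReport", model = family,
      accuracy = mean(foldAcc), accuracyCI = ciOf(foldAcc),
      macroF1 = mean(foldF1), macroF1CI = ciOf(foldF1),
      microAUC = micro$auc, macroAUC = macro$auc,
      confusion = cmNorm,
      rocCurves = list(micro = micro$curve, macro = macro$curve,
                       perClass = macro$perClass),
      params = if (is.null(chosen)) list() else chosen,
      foldMetrics = data.frame(fold = seq_len(k), accuracy = foldAcc,
                               macroF1 = foldF1),
      seed = seed)
}

setMethod("show", "ClassificationReport", function(object) {
  cat(sprintf("ClassificationReport[%s]\n", object@model))
  cat(sprintf("  accuracy %.3f (95%% CI %.3f-%.3f)\n", object@accuracy,
              object@accuracyCI[1], object@accuracyCI[2]))
  cat(sprintf("  macro-F1 %.3f (95%% CI %.3f-%.3f)\n", object@macroF1,
              object@macroF1CI[1], object@macroF1CI[2]))
  cat(sprintf("  micro-AUC %.3f  macro-AUC %.3f\n", object@microAUC,
              object@macroAUC))
})
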