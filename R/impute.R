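#' Mean-impute every missing cell (the initial fill of the engine)
#'
#' @param table a \linkS4class{LabTable}.
#' @param variables variables to fill (default: all columns).
#' @return a \linkS4class{LabTable} with those columns complete; observed
#'   cells untouched.
#' @export
initialFill <- function(table, variables = colnames(labValues(table))) {
  v <- labValues(table)
  for (nm in variables) {
    col <- v[, nm]
    if (all(is.na(col))) stop("variable '", nm, "' has no observed values")
    col[is.na(col)] <- mean(col, na.rm = TRUE)
    v[, nm] <- col
  }
  LabTable(v)
}

# ---- core predictors --------------------------------------------------------

#' Fit a core predictor on observed rows and predict the missing ones
#'
#' The pluggable prediction model of the multiple-imputation engine. All
#' cores are deterministic given `seed`.
#'
#' \describe{
#'   \item{chained_regression}{least-squares linear prediction (ridge
#'     fallback with a warning when there are fewer training rows than
#'     predictors + 1).}
#'   \item{random_forest}{random-forest regression (missForest-style), via
#'     ranger.}
#'   \item{bayesian_network}{discretizes the target and its strongest
#'     predictors into three classes, learns and fits a small discrete
#'     Bayesian network, predicts the target class by exact inference and
#'     emits the class-conditional median of the observed target values.}
#'   \item{autoencoder}{a shallow (one hidden layer) denoising autoencoder
#'     trained by seeded full-batch gradient descent; the target column is
#'     masked at prediction time and read off the reconstruction.}
#' }
#'
#' @param core one of `"chained_regression"`, `"random_forest"`,
#'   `"bayesian_network"`, `"autoencoder"`.
#' @param trainX numeric predictor matrix for rows observing the target.
#' @param trainY observed target values.
#' @param queryX predictor matrix for the rows to predict.
#' @param seed integer seed.
#' @param options named list of core hyperparameters (`numTrees`,
#'   `bnMaxPredictors`, `aeHidden`, `aeEpochs`, `aeLearningRate`,
#'   `aeNoise`).
#' @return numeric predictions for the query rows.
#' @export
coreFitPredict <- function(core, trainX, trainY, queryX, seed = 1,
                           options = list()) {
  trainX <- as.matrix(trainX); queryX <- as.matrix(queryX)
  if (anyNA(trainX) || anyNA(queryX))
    stop("core predictors must be complete on training and query rows")
  pred <- switch(core,
    chained_regression = coreChainedRegression(trainX, trainY, queryX),
    random_forest = coreRandomForest(trainX, trainY, queryX, seed, options),
    bayesian_network = coreBayesNet(trainX, trainY, queryX, seed, options),
    autoencoder = coreAutoencoder(trainX, trainY, queryX, seed, options),
    stop("unknown core kind: ", core))
  if (any(!is.finite(pred)))
    stop("core '", core, "' produced non-finite predictions")
  pred
}

coreChainedRegression <- function(trainX, trainY, queryX) {
  X <- cbind(1, trainX)
  if (nrow(X) < ncol(X) + 1) {
    warning("fewer training rows than predictors + 1; ridge fallback")
    XtX <- crossprod(X) + diag(1e-2, ncol(X))
    beta <- solve(XtX, crossprod(X, trainY))
  } else {
    fit <- stats::lm.fit(X, trainY)
    beta <- fit$coefficients
    beta[is.na(beta)] <- 0
  }
  drop(cbind(1, queryX) %*% beta)
}

coreRandomForest <- function(trainX, trainY, queryX, seed, options) {
  nt <- options$numTrees %||% 100
  df <- data.frame(trainX, check.names = TRUE)
  qf <- data.frame(queryX, check.names = TRUE)
  colnames(qf) <- colnames(df)
  df$.target <- trainY
  fit <- ranger::ranger(dependent.variable.name = ".target", data = df,
                        num.trees = nt, seed = seed, num.threads = 1,
                        respect.unordered.factors = FALSE)
  stats::predict(fit, qf, num.threads = 1)$predictions
}

coreBayesNet <- function(trainX, trainY, queryX, seed, options) {
  kmax <- options$bnMaxPredictors %||% 5
  ysch <- tryCatch(peakCutpoints(trainY, variable = ".y"),
                   error = function(e) quantileCutpoints(trainY, ".y"))
  ycls <- assignClasses(trainY, ysch)
  if (length(unique(ycls)) < 2) {
    # degenerate target: every class identical, emit its median
    return(rep(stats::median(trainY), nrow(queryX)))
  }
  sel <- order(-abs(suppressWarnings(
    stats::cor(trainX, trainY, use = "complete.obs"))))
  sel <- sel[seq_len(min(kmax, length(sel)))]
  sel <- sel[!is.na(sel)]
  xcls <- matrix(NA_integer_, nrow(trainX), length(sel))
  qcls <- matrix(NA_integer_, nrow(queryX), length(sel))
  for (j in seq_along(sel)) {
    col <- trainX[, sel[j]]
    sch <- tryCatch(peakCutpoints(col, variable = paste0(".x", j)),
                    error = function(e)
                      quantileCutpoints(col, paste0(".x", j)))
    xcls[, j] <- assignClasses(col, sch)
    qcls[, j] <- assignClasses(queryX[, sel[j]], sch)
  }
  dat <- cbind(xcls, ycls)
  colnames(dat) <- c(paste0(".x", seq_along(sel)), ".y")
  dag <- suppressWarnings(
    learnStructure(dat, maxParents = 2, restarts = 0, seed = seed,
                   screen = FALSE))
  # full 3-class cardinalities: a query row may land in a class the
  # training rows never produced
  bn <- fitParameters(dag, dat, alpha = 1,
                      cardinalities = stats::setNames(rep(3L, ncol(dat)),
                                                      colnames(dat)))
  classMed <- vapply(1:3, function(k) {
    if (any(ycls == k)) stats::median(trainY[ycls == k]) else
      stats::median(trainY)
  }, numeric(1))
  # group query rows by evidence configuration so inference runs once each
  key <- apply(qcls, 1, paste, collapse = "/")
  pred <- numeric(nrow(queryX))
  for (kk in unique(key)) {
    rows <- which(key == kk)
    ev <- as.list(qcls[rows[1], ])
    names(ev) <- paste0(".x", seq_along(sel))
    ev <- ev[!vapply(ev, is.na, logical(1))]
    cls <- predictClass(bn, ev, ".y")$class
    pred[rows] <- classMed[cls]
  }
  pred
}

coreAutoencoder <- function(trainX, trainY, queryX, seed, options) {
  hidden <- options$aeHidden %||% 8
  epochs <- options$aeEpochs %||% 200
  lr <- options$aeLearningRate %||% 0.05
  noise <- options$aeNoise %||% 0.2
  M <- cbind(trainX, .y = trainY)
  lo <- apply(M, 2, min); hi <- apply(M, 2, max)
  normCol <- function(mat) {
    out <- mat
    for (j in seq_len(ncol(mat))) out[, j] <- minmaxNorm(mat[, j], lo[j], hi[j])
    out
  }
  Xn <- normCol(M)
  n <- nrow(Xn); p <- ncol(Xn)
  withSeed(seed, {
    W1 <- matrix(stats::rnorm(p * hidden, 0, 0.1), p, hidden)
    b1 <- numeric(hidden)
    W2 <- matrix(stats::rnorm(hidden * p, 0, 0.1), hidden, p)
    b2 <- numeric(p)
    for (ep in seq_len(epochs)) {
      corrupt <- Xn * (matrix(stats::runif(n * p), n, p) > noise)
      H <- tanh(sweep(corrupt %*% W1, 2, b1, `+`))
      O <- sweep(H %*% W2, 2, b2, `+`)
      E <- O - Xn
      gW2 <- crossprod(H, E) / n
      gb2 <- colMeans(E)
      dH <- (E %*% t(W2)) * (1 - H^2)
      gW1 <- crossprod(corrupt, dH) / n
      gb1 <- colMeans(dH)
      W2 <- W2 - lr * gW2; b2 <- b2 - lr * gb2
      W1 <- W1 - lr * gW1; b1 <- b1 - lr * gb1
    }
    Q <- cbind(queryX, .y = 0)
    Qn <- normCol(Q)
    Qn[, p] <- 0 # target masked at prediction time
    H <- tanh(sweep(Qn %*% W1, 2, b1, `+`))
    O <- sweep(H %*% W2, 2, b2, `+`)
    yhat <- O[, p]
    if (hi[p] - lo[p] <= 0) rep(unname(lo[p]), nrow(queryX))
    else unname(lo[p] + pmin(pmax(yhat, 0), 1) * (hi[p] - lo[p]))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- the iterative engine ---------------------------------------------------

#' Iterative multiple imputation with a pluggable core
#'
#' The engine first mean-fills every missing cell, then repeatedly cycles over
#' the variables (most-observed first): the variable's previously imputed
#' values are removed, the core is trained on the rows that observe it (with
#' all other variables at their current filled values), and its missing cells
#' are re-predicted. Iteration stops when the mean absolute change of imputed
#' cells on the min-max-normalized scale falls below `tol`, or at `maxIter`.
#'
#' Excluded variables (by default the analysis target, serum creatinine, to
#' prevent any leakage into its predictors) are neither imputed nor ever used
#' as predictors: they are removed from the working matrix before anything
#' else happens.
#'
#' @param table a \linkS4class{LabTable}.
#' @param core core kind, see [coreFitPredict()].
#' @param exclude variables to keep out of the process entirely.
#' @param maxIter maximum engine iterations (default 10).
#' @param tol normalized mean-absolute-change stopping threshold (default
#'   1e-3).
#' @param seed integer seed; the whole run is deterministic given it.
#' @param options core hyperparameters, see [coreFitPredict()].
#' @return an \linkS4class{ImputationResult}; excluded columns pass through
#'   untouched (including their missing cells).
#' @examples
#' x <- cbind(a = c(1, 2, 3, 4, NA, 6), b = c(2, 4, NA, 8, 10, 12))
#' res <- multipleImpute(LabTable(x), core = "chained_regression",
#'                       exclude = character(0))
#' labValues(res@table)
#' @export
multipleImpute <- function(table, core = "chained_regression",
                           exclude = "Creatinine", maxIter = 10, tol = 1e-3,
                           seed = 1, options = list()) {
  vals <- labValues(table)
  exclude <- intersect(exclude, colnames(vals))
  work <- vals[, setdiff(colnames(vals), exclude), drop = FALSE]
  if (ncol(work) < 2) stop("need at least two non-excluded variables")
  missRate <- colMeans(is.na(work))
  targets <- names(missRate)[missRate > 0]
  obsRange <- apply(work, 2, function(x) range(x, na.rm = TRUE))
  masks <- lapply(targets, function(v) which(is.na(work[, v])))
  names(masks) <- targets

  if (!length(targets)) {
    out <- vals
    return(new("ImputationResult", table = LabTable(out), iterations = 0L,
               changes = numeric(0), converged = TRUE, core = core))
  }

  filled <- labValues(initialFill(LabTable(work)))
  visit <- targets[order(missRate[targets], targets)]
  changes <- numeric(0)
  converged <- FALSE
  withSeed(seed, {
    for (it in seq_len(maxIter)) {
      delta <- 0
      ncell <- 0
      for (v in visit) {
        rows <- masks[[v]]
        obs <- setdiff(seq_len(nrow(filled)), rows)
        predCols <- setdiff(colnames(filled), v)
        old <- filled[rows, v]
        coreSeed <- (seed + 7919L * it + match(v, visit)) %%
          .Machine$integer.max
        newv <- coreFitPredict(core, filled[obs, predCols, drop = FALSE],
                               work[obs, v], filled[rows, predCols,
                                                    drop = FALSE],
                               seed = coreSeed, options = options)
        filled[rows, v] <- newv
        rng <- obsRange[2, v] - obsRange[1, v]
        if (rng > 0) {
          delta <- delta + sum(abs(newv - old)) / rng
          ncell <- ncell + length(rows)
        }
      }
      changes[it] <- if (ncell > 0) delta / ncell else 0
      if (changes[it] < tol) {
        converged <- TRUE
        break
      }
    }
  })
  out <- vals
  out[, colnames(filled)] <- filled
  new("ImputationResult", table = LabTable(out),
      iterations = length(changes), changes = changes,
      converged = converged, core = core)
}

setMethod("show", "ImputationResult", function(object) {
  cat(sprintf("ImputationResult[%s]: %d iterations, %s (last change %.2e)\n",
              object@core, object@iterations,
              if (object@converged) "converged" else "max iterations",
              if (length(object@changes)) utils::tail(object@changes, 1)
              else NA_real_))
})

#' K-nearest-neighbour imputation (non-iterative baseline)
#'
#' Each missing cell is replaced by the mean of its variable over the `k`
#' nearest rows that observe it. Distance is the root-mean-square difference
#' over the mutually observed, min-max-normalized, non-excluded variables.
#'
#' @param table a \linkS4class{LabTable}.
#' @param k number of neighbours (>= 1).
#' @param exclude variables kept out of imputation and distance computation.
#' @return a completed \linkS4class{LabTable} (excluded columns untouched).
#' @export
knnImpute <- function(table, k = 5, exclude = "Creatinine") {
  if (k < 1) stop("k must be at least 1")
  vals <- labValues(table)
  exclude <- intersect(exclude, colnames(vals))
  work <- vals[, setdiff(colnames(vals), exclude), drop = FALSE]
  n <- nrow(work)
  obsMat <- !is.na(work)
  lo <- apply(work, 2, min, na.rm = TRUE)
  hi <- apply(work, 2, max, na.rm = TRUE)
  Nrm <- work
  for (j in seq_len(ncol(work)))
    Nrm[, j] <- minmaxNorm(work[, j], lo[j], hi[j])
  Z <- Nrm; Z[!obsMat] <- 0
  O <- obsMat * 1
  # pairwise mean squared difference over mutually observed variables
  ZZ <- Z * Z
  cross <- tcrossprod(Z)
  sq <- tcrossprod(ZZ, O)
  shared <- tcrossprod(O)
  D2 <- (sq + t(sq) - 2 * cross) / pmax(shared, 1)
  D2[shared == 0] <- Inf
  diag(D2) <- Inf
  out <- work
  for (v in colnames(work)) {
    rows <- which(is.na(work[, v]))
    if (!length(rows)) next
    cand <- which(obsMat[, v])
    if (!length(cand)) stop("variable '", v, "' has no observed values")
    for (i in rows) {
      d <- D2[i, cand]
      usable <- cand[is.finite(d)]
      if (!length(usable)) {
        warning("no comparable neighbour observes '", v,
                "'; column-mean fallback")
        out[i, v] <- mean(work[, v], na.rm = TRUE)
      } else {
        ord <- usable[order(D2[i, usable], usable)]
        nb <- ord[seq_len(min(k, length(ord)))]
        out[i, v] <- mean(work[nb, v])
      }
    }
  }
  full <- vals
  full[, colnames(out)] <- out
  LabTable(full)
}
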