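#' Hide observed values of a variable for masked-value evaluation
#'
#' Flips `nHide` observed cells of one variable to missing (chosen uniformly
#' at random with the given seed) and records their true values, so an
#' imputation method can be scored on cells whose truth is known.
#'
#' @param table a \linkS4class{LabTable}.
#' @param variable variable to mask.
#' @param nHide number of observed cells to hide (default 100); if fewer are
#'   observed, all of them are hidden with a warning.
#' @param seed integer seed.
#' @return list with `table` (the masked \linkS4class{LabTable}), and `eval`:
#'   `variable`, `rows` (hidden row indices), `truth` (hidden values), and
#'   the pre-masking observed `range` used later for normalization.
#' @export
maskObserved <- function(table, variable, nHide = 100, seed = 1) {
  vals <- labValues(table)
  obs <- which(!is.na(vals[, variable]))
  if (length(obs) < nHide) {
    warning("only ", length(obs), " observed cells in '", variable,
            "'; hiding all of them")
    nHide <- length(obs)
  }
  rng <- range(vals[, variable], na.rm = TRUE)
  rows <- if (nHide > 0)
    withSeed(seed, sort(sample(obs, nHide))) else integer(0)
  truth <- vals[rows, variable]
  vals[rows, variable] <- NA_real_
  list(table = LabTable(vals),
       eval = list(variable = variable, rows = rows, truth = truth,
                   range = rng))
}

#' Normalized mean squared error of imputed values
#'
#' Truth and estimates are min-max normalized against the variable's
#' pre-masking observed range, then scored by mean squared error; the value
#' lies in `[0, 1]` whenever the estimates stay inside the observed range.
#' A zero-range (constant) variable normalizes to all zeros and scores 0,
#' with a warning.
#'
#' @param eval the `eval` element returned by [maskObserved()] (fields
#'   `truth` and `range`), or a list with those fields.
#' @param estimates imputed values aligned with `eval$truth`.
#' @return the normalized MSE.
#' @examples
#' maskedMse(list(truth = c(1, 2, 3), range = c(1, 4)),
#'           estimates = c(1, 2, 4)) # (1/3)^2 / 3 = 0.037037
#' @export
maskedMse <- function(eval, estimates) {
  truth <- eval$truth
  if (!length(truth)) stop("no hidden cells to score")
  if (length(estimates) != length(truth))
    stop("estimates and truth must align by position")
  rng <- eval$range[2] - eval$range[1]
  if (!is.finite(rng) || rng <= 0) {
    warning("zero observed range; normalized values defined as 0")
    return(0)
  }
  t0 <- (truth - eval$range[1]) / rng
  e0 <- (estimates - eval$range[1]) / rng
  mean((t0 - e0)^2)
}

#' The CBC variable set used for imputation scoring
#' @return character vector of the twelve complete-blood-count variables.
#' @export
cbcVariables <- function() {
  c("RBC", "WBC", "Hemoglobin", "Hematocrit", "Lymphocyte", "Neutrophils",
    "Platelets", "MCV", "MCH", "MCHC", "Monocyte", "Eosinophil")
}

#' Score imputation methods by the masked-value protocol
#'
#' For each seed, hides `nHide` observed cells of every evaluation variable
#' (the same cells for every method — a paired design), runs each method once
#' on the masked table, and scores each variable by [maskedMse()]. Per-method
#' scores are the mean and sample variance of the per-variable MSEs
#' (averaged over seeds first when several are given).
#'
#' @param table a \linkS4class{LabTable}.
#' @param methods named list of imputer functions `LabTable -> LabTable`
#'   (see [imputerFor()]).
#' @param evalVars variables to mask and score (default [cbcVariables()]
#'   intersected with the table; the analysis target is never included by
#'   default).
#' @param nHide observed cells hidden per variable (default 100).
#' @param seeds integer vector of masking seeds.
#' @return list with `scores` (data.frame: method, average_mse,
#'   variance_mse) and `detail` (per method x variable x seed).
#' @export
evaluateMethods <- function(table, methods, evalVars = NULL, nHide = 100,
                            seeds = 1) {
  vals <- labValues(table)
  if (is.null(evalVars))
    evalVars <- intersect(cbcVariables(), colnames(vals))
  if (!length(evalVars)) stop("no evaluation variables available")
  if (is.null(names(methods)) || any(!nzchar(names(methods))))
    stop("methods must be a named list of imputer functions")
  detail <- expand.grid(method = names(methods), variable = evalVars,
                        seed = seeds, stringsAsFactors = FALSE)
  detail$mse <- NA_real_
  for (s in seeds) {
    masked <- table
    evals <- list()
    for (v in evalVars) {
      mk <- maskObserved(masked, v, nHide = nHide,
                         seed = s + 31L * match(v, evalVars))
      masked <- mk$table
      evals[[v]] <- mk$eval
    }
    for (m in names(methods)) {
      completed <- tryCatch(methods[[m]](masked), error = function(e) {
        warning("method '", m, "' failed: ", conditionMessage(e))
        NULL
      })
      for (v in evalVars) {
        row <- detail$method == m & detail$variable == v & detail$seed == s
        if (is.null(completed)) next
        est <- labValues(completed)[evals[[v]]$rows, v]
        if (anyNA(est)) next
        detail$mse[row] <- maskedMse(evals[[v]], est)
      }
    }
  }
  perVar <- stats::aggregate(mse ~ method + variable, detail, mean,
                             na.action = stats::na.omit)
  scores <- do.call(rbind, lapply(names(methods), function(m) {
    x <- perVar$mse[perVar$method == m]
    data.frame(method = m, average_mse = mean(x),
               variance_mse = if (length(x) > 1) stats::var(x) else 0)
  }))
  list(scores = scores, detail = detail)
}

#' Build an imputer function for use with [evaluateMethods()]
#'
#' @param method `"mean"`, `"knn"`, or a core kind accepted by
#'   [multipleImpute()].
#' @param exclude variables excluded from imputation (default the analysis
#'   target, creatinine).
#' @param seed,maxIter,tol,k,options forwarded to the underlying imputer.
#' @return a function `LabTable -> LabTable`.
#' @export
imputerFor <- function(method, exclude = "Creatinine", seed = 1, maxIter = 5,
                       tol = 1e-3, k = 5, options = list()) {
  force(method); force(exclude); force(seed)
  switch(method,
    mean = function(tab) initialFill(tab, setdiff(colnames(labValues(tab)),
                                                  exclude)),
    knn = function(tab) knnImpute(tab, k = k, exclude = exclude),
    function(tab) multipleImpute(tab, core = method, exclude = exclude,
                                 maxIter = maxIter, tol = tol, seed = seed,
                                 options = options)@table)
}

#' Write a method-comparison table (method, average MSE, variance of MSE)
#' @param scores result of [evaluateMethods()]; @param csv,json output paths.
#' @export
writeMethodScores <- function(scores, csv = NULL, json = NULL) {
  if (!is.null(csv)) utils::write.csv(scores$scores, csv, row.names = FALSE)
  if (!is.null(json))
    jsonlite::write_json(scores, json, auto_unbox = TRUE, digits = NA)
  invisible(scores)
}
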