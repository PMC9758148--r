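#' @import methods
NULL

#' LabTable: a rectangular numeric laboratory panel with missing cells
#'
#' The universal currency of the pipeline: one row per record (visit), one
#' column per blood-test parameter. Missing measurements are `NA`; the
#' missingness mask is therefore `is.na(labValues(x))`, so mask and values can
#' never disagree.
#'
#' @slot values numeric matrix; `NA` marks an unrecorded measurement.
#' @export
setClass("LabTable", representation(values = "matrix"))

setValidity("LabTable", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("values must be a numeric matrix")
  cn <- colnames(v)
  if (is.null(cn) || anyDuplicated(cn) || any(!nzchar(cn)))
    return("column names must be present, non-empty and unique")
  TRUE
})

#' GeneratorConfig: recipe for a synthetic lab-panel table
#'
#' Describes the Gaussian-copula generator: per-variable marginals, the latent
#' correlation matrix, planted directed effects (in target-SD units), the
#' per-variable missingness rates and the missingness mechanism.
#'
#' @slot nRecords number of rows to generate.
#' @slot variables named list; each element a list with `marginal` (one of
#'   `"gaussian"`, `"lognormal"`, `"mixture3"`) and its parameters.
#' @slot correlation latent correlation matrix over the variables.
#' @slot effects data.frame with columns `source`, `target`, `size` (signed,
#'   target-SD units per source-SD).
#' @slot missingRates named numeric in `[0, 1]`.
#' @slot mechanism list: `kind` `"MCAR"` or `"MAR"`, plus `driver` and `slope`
#'   for MAR.
#' @slot seed integer seed.
#' @export
setClass("GeneratorConfig", representation(
  nRecords = "numeric", variables = "list", correlation = "matrix",
  effects = "data.frame", missingRates = "numeric", mechanism = "list",
  seed = "numeric"))

setValidity("GeneratorConfig", function(object) {
  vn <- names(object@variables)
  if (object@nRecords < 1) return("nRecords must be positive")
  if (is.null(vn) || anyDuplicated(vn)) return("variables must be uniquely named")
  R <- object@correlation
  if (!identical(dim(R), c(length(vn), length(vn))))
    return("correlation dimension must match the number of variables")
  if (max(abs(R - t(R))) > 1e-8) return("correlation matrix must be symmetric")
  if (max(abs(diag(R) - 1)) > 1e-8) return("correlation diagonal must be 1")
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    return("correlation matrix must be positive semi-definite")
  if (length(object@missingRates) &&
      (min(object@missingRates) < 0 || max(object@missingRates) > 1))
    return("missing rates must lie in [0, 1]")
  if (nrow(object@effects)) {
    ev <- c(object@effects$source, object@effects$target)
    if (!all(ev %in% vn)) return("planted-effect variables must be declared variables")
  }
  if (!object@mechanism$kind %in% c("MCAR", "MAR"))
    return("mechanism kind must be MCAR or MAR")
  TRUE
})

#' SyntheticTruth: a generated panel with its ground truth
#'
#' @slot complete [LabTable] with zero missingness (analytes, demographics,
#'   derived eGFR).
#' @slot masked [LabTable] after the missingness mechanism (empty until
#'   [applyMissingness()] runs).
#' @slot missingMask logical matrix marking masked cells.
#' @slot trueGraph two-column character matrix of planted directed edges
#'   (includes the deterministic creatinine/demographics -> eGFR derivations).
#' @slot config the [GeneratorConfig] echo.
#' @export
setClass("SyntheticTruth", representation(
  complete = "LabTable", masked = "LabTable", missingMask = "matrix",
  trueGraph = "matrix", config = "GeneratorConfig"))

#' DiscretizationScheme: peak-based three-class cut points for one variable
#'
#' Classes follow the convention `[min, c1)` / `[c1, c2]` / `(c2, max]`; cut
#' points carry exactly one decimal.
#'
#' @slot variable variable name.
#' @slot cutpoints numeric length 2, `c1 < c2`, one-decimal values.
#' @slot binWidth histogram bin width that produced the peaks.
#' @slot histRange range of the histogram.
#' @slot classCounts integer counts of the three classes on the fitting data.
#' @slot method `"peaks"` or `"quantile"` (the documented fallback).
#' @export
setClass("DiscretizationScheme", representation(
  variable = "character", cutpoints = "numeric", binWidth = "numeric",
  histRange = "numeric", classCounts = "integer", method = "character"))

setValidity("DiscretizationScheme", function(object) {
  cp <- object@cutpoints
  if (length(cp) != 2 || !cp[1] < cp[2]) return("need two increasing cut points")
  if (max(abs(cp - round(cp, 1))) > 1e-9) return("cut points must carry one decimal")
  TRUE
})

#' DAG: a directed acyclic graph over named variables
#'
#' @slot nodes character vector of variable names.
#' @slot edges two-column character matrix (parent, child).
#' @export
setClass("DAG", representation(nodes = "character", edges = "matrix"))

setValidity("DAG", function(object) {
  e <- object@edges
  if (ncol(e) != 2) return("edges must be a two-column (parent, child) matrix")
  if (nrow(e)) {
    if (!all(e %in% object@nodes)) return("edge endpoints must be nodes")
    if (any(e[, 1] == e[, 2])) return("self-loops are not allowed")
    if (anyDuplicated(paste(e[, 1], e[, 2]))) return("duplicate edges")
    if (is.null(topoSort(object@nodes, e))) return("graph contains a directed cycle")
  }
  TRUE
})

#' DiscreteBN: a discrete Bayesian network
#'
#' Each node carries a conditional probability table P(node | parents); for
#' every parent configuration the distribution over node classes sums to one.
#'
#' @slot dag [DAG].
#' @slot cardinalities named integer, classes per node (default 3 throughout
#'   the pipeline).
#' @slot cpts named list of arrays; first dimension indexes the node's own
#'   classes, remaining dimensions its parents in `parents(dag, node)` order.
#' @export
setClass("DiscreteBN", representation(
  dag = "DAG", cardinalities = "integer", cpts = "list"))

setValidity("DiscreteBN", function(object) {
  for (v in object@dag@nodes) {
    cpt <- object@cpts[[v]]
    if (is.null(cpt)) return(paste0("missing CPT for ", v))
    pa <- dagParents(object@dag, v)
    want <- c(object@cardinalities[[v]],
              if (length(pa)) unname(object@cardinalities[pa]))
    if (!identical(as.integer(dim(as.array(cpt))), as.integer(want)))
      return(paste0("CPT dimensions of ", v, " do not match parents"))
    s <- if (length(pa) == 0) sum(cpt)
         else apply(as.array(cpt), seq_along(want)[-1], sum)
    if (max(abs(s - 1)) > 1e-9) return(paste0("CPT of ", v, " rows must sum to 1"))
  }
  TRUE
})

#' PosteriorTable: P(target class | given class)
#'
#' The matrix is laid out with one row per class of the conditioning variable
#' and one column per class of the target, so every row sums to one.
#'
#' @slot given conditioning variable name.
#' @slot target target variable name.
#' @slot probs numeric matrix, rows = given classes, cols = target classes.
#' @export
setClass("PosteriorTable", representation(
  given = "character", target = "character", probs = "matrix"))

setValidity("PosteriorTable", function(object) {
  p <- object@probs
  if (min(p) < -1e-12 || max(p) > 1 + 1e-12) return("entries must lie in [0, 1]")
  if (max(abs(rowSums(p) - 1)) > 1e-9) return("rows must sum to 1")
  TRUE
})

#' ImputationResult: a completed table plus convergence trace
#'
#' @slot table completed [LabTable] (zero missingness on imputed variables).
#' @slot iterations number of engine iterations run.
#' @slot changes mean absolute change of imputed cells (min-max-normalized
#'   scale) per iteration.
#' @slot converged whether the change fell below the tolerance.
#' @slot core core predictor used.
#' @export
setClass("ImputationResult", representation(
  table = "LabTable", iterations = "integer", changes = "numeric",
  converged = "logical", core = "character"))

#' FeatureSelection: result of correlation pruning
#'
#' @slot kept retained predictor names.
#' @slot dropped data.frame with columns `variable`, `reason`.
#' @slot threshold absolute Pearson correlation threshold used.
#' @export
setClass("FeatureSelection", representation(
  kept = "character", dropped = "data.frame", threshold = "numeric"))

#' ClassificationReport: cross-validated multiclass performance
#'
#' @slot model model family name.
#' @slot accuracy mean fold accuracy.
#' @slot accuracyCI normal-approximation 95 percent CI over folds.
#' @slot macroF1 mean fold macro-F1.
#' @slot macroF1CI 95 percent CI.
#' @slot microAUC pooled one-vs-rest ROC-AUC.
#' @slot macroAUC unweighted mean of per-class ROC-AUCs.
#' @slot confusion row-normalized pooled 3x3 confusion matrix.
#' @slot rocCurves per-class and averaged ROC curves (list of data.frames).
#' @slot params chosen hyperparameters.
#' @slot foldMetrics per-fold accuracy/macro-F1.
#' @slot seed fold-assignment seed.
#' @export
setClass("ClassificationReport", representation(
  model = "character", accuracy = "numeric", accuracyCI = "numeric",
  macroF1 = "numeric", macroF1CI = "numeric", microAUC = "numeric",
  macroAUC = "numeric", confusion = "matrix", rocCurves = "list",
  params = "list", foldMetrics = "data.frame", seed = "numeric"))
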