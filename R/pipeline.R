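#' Run the full association-discovery pipeline on a completed panel
#'
#' The end-to-end analysis: discretize the target at its two distribution
#' peaks, prune correlated/forced predictors, train the interpretable rule
#' forest, extract rules, importances and directions, learn a discrete
#' Bayesian network over the discretized panel, and consolidate rule-based
#' and posterior-based evidence into one report.
#'
#' @param table a completed \linkS4class{LabTable} (run [multipleImpute()]
#'   first when the panel has missing cells).
#' @param target target variable (default `"Creatinine"`).
#' @param forcedExclusions predictors never used by the classifier; defaults
#'   to the kidney-function-derived and demographic columns.
#' @param posteriorVars variables to compute posterior tables against the
#'   top-ranked predictor for; defaults to the target plus `"e GFR"` when
#'   present.
#' @param bnMaxNodes cap on Bayesian-network size: the target, the posterior
#'   variables and the strongest remaining predictors by mutual information
#'   (default 12 nodes).
#' @param numTrees,maxDepth rule-forest size.
#' @param seed integer seed driving every stochastic stage.
#' @return list with `report` (the consolidated `associationReport`),
#'   `scheme` (target discretization), `selection`, `forest`, `rules`,
#'   `importances`, `bn` and `labels`.
#' @export
runAssociationStudy <- function(table, target = "Creatinine",
                                forcedExclusions = c("Blood Urea Nitrogen",
                                                     "e GFR", "Age",
                                                     "Weight", "Sex"),
                                posteriorVars = NULL, bnMaxNodes = 12,
                                numTrees = 25, maxDepth = 4, seed = 1) {
  vals <- labValues(table)
  if (!target %in% colnames(vals)) stop("target not in table")
  scheme <- peakCutpoints(vals[, target], variable = target)
  labels <- assignClasses(vals[, target], scheme)

  sel <- suppressWarnings(
    correlationPrune(table, target = target,
                     forcedExclusions = forcedExclusions))
  x <- vals[, sel@kept, drop = FALSE]
  forest <- ruleForest(x, labels, numTrees = numTrees, maxDepth = maxDepth,
                       seed = seed)
  rules <- extractRules(forest, maxDepth = min(3, maxDepth))
  imps <- importanceRanking(forest)

  if (is.null(posteriorVars))
    posteriorVars <- intersect(c(target, "e GFR"), colnames(vals))
  lead <- imps$variable[1]
  bnVars <- unique(c(target, posteriorVars, lead))
  disc <- discretizeTable(LabTable(vals[, unique(c(bnVars, sel@kept)),
                                        drop = FALSE]))
  cls <- disc$classes
  # rank remaining predictors by mutual information with the target classes
  rest <- setdiff(colnames(cls), bnVars)
  if (length(rest) && length(bnVars) < bnMaxNodes) {
    mi <- vapply(rest, function(v)
      mutualInfo(cls[, target], cls[, v]), numeric(1))
    bnVars <- c(bnVars, rest[order(-mi)][seq_len(min(length(rest),
                                                     bnMaxNodes -
                                                       length(bnVars)))])
  }
  dag <- suppressWarnings(learnStructure(cls[, bnVars, drop = FALSE],
                                         maxParents = 3, restarts = 1,
                                         seed = seed))
  bn <- fitParameters(dag, cls[, bnVars, drop = FALSE], alpha = 1)
  posteriors <- list()
  for (pv in posteriorVars) {
    nm <- paste0(pv, "|", lead)
    posteriors[[nm]] <- posteriorTable(bn, target = pv, given = lead)
  }
  report <- consolidatedReport(rules, imps, posteriors, target = target)
  list(report = report, scheme = scheme, selection = sel, forest = forest,
       rules = rules, importances = imps, bn = bn, labels = labels,
       schemes = disc$schemes)
}
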