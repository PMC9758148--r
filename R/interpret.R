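#' Train an interpretable bagged-tree forest
#'
#' A bootstrap ensemble of depth-limited CART trees (rpart) that exposes full
#' node statistics (split variable, cut point, per-class counts, Gini
#' impurity) for rule extraction. Each tree sees a bootstrap sample of the
#' rows and a random subset of `mtry` predictors.
#'
#' @param x predictor matrix or data.frame.
#' @param labels integer classes in `{1, 2, 3}`.
#' @param numTrees trees in the ensemble (default 25).
#' @param maxDepth maximum tree depth (default 4).
#' @param mtry predictors sampled per tree (default `floor(sqrt(p))`, at
#'   least 2).
#' @param minSplit minimum node size to attempt a split.
#' @param seed integer seed.
#' @return object of class `ruleForest`.
#' @export
ruleForest <- function(x, labels, numTrees = 25, maxDepth = 4, mtry = NULL,
                       minSplit = 40, seed = 1) {
  x <- as.data.frame(x, check.names = FALSE)
  p <- ncol(x)
  if (is.null(mtry)) mtry <- max(2, floor(sqrt(p)))
  mtry <- min(mtry, p)
  n <- nrow(x)
  trees <- withSeed(seed, lapply(seq_len(numTrees), function(b) {
    rows <- sample.int(n, n, replace = TRUE)
    feats <- sort(sample.int(p, mtry))
    df <- x[rows, feats, drop = FALSE]
    names(df) <- make.names(names(df))
    df$.cls <- factor(labels[rows], levels = 1:3)
    fit <- rpart::rpart(.cls ~ ., data = df, method = "class",
                        control = rpart::rpart.control(
                          maxdepth = maxDepth, cp = 0.001,
                          minsplit = minSplit, maxcompete = 0,
                          maxsurrogate = 0, xval = 0))
    list(fit = fit, features = names(x)[feats],
         safeNames = make.names(names(x)[feats]))
  }))
  structure(list(trees = trees, predictors = names(x), maxDepth = maxDepth),
            class = "ruleForest")
}

#' @export
print.ruleForest <- function(x, ...) {
  cat(sprintf("ruleForest: %d trees, depth <= %d, %d predictors\n",
              length(x$trees), x$maxDepth, length(x$predictors)))
  invisible(x)
}

setOldClass("ruleForest")

# convert one rpart fit into a flat walkable node list
rpartWalk <- function(fit, featureMap) {
  frame <- fit$frame
  nodeIds <- as.integer(rownames(frame))
  nlev <- 3L
  counts <- frame$yval2[, 2:(1 + nlev), drop = FALSE]
  isLeaf <- frame$var == "<leaf>"
  splitVar <- splitCut <- rep(NA_character_, nrow(frame))
  cutNum <- rep(NA_real_, nrow(frame))
  ltGoesLeft <- rep(NA, nrow(frame))
  if (!all(isLeaf)) {
    sp <- fit$splits
    internal <- which(!isLeaf)
    # with maxcompete = maxsurrogate = 0, splits rows align with internal nodes
    for (k in seq_along(internal)) {
      i <- internal[k]
      v <- as.character(frame$var[i])
      splitVar[i] <- if (v %in% names(featureMap)) featureMap[[v]] else v
      cutNum[i] <- sp[k, "index"]
      ltGoesLeft[i] <- sp[k, "ncat"] < 0
    }
  }
  nodes <- lapply(seq_len(nrow(frame)), function(i) {
    id <- nodeIds[i]
    gini <- 1 - sum((counts[i, ] / max(sum(counts[i, ]), 1))^2)
    list(id = id, leaf = isLeaf[i], variable = splitVar[i],
         threshold = cutNum[i], ltGoesLeft = ltGoesLeft[i],
         left = 2L * id, right = 2L * id + 1L,
         counts = as.numeric(counts[i, ]), gini = gini)
  })
  names(nodes) <- as.character(nodeIds)
  nodes
}

#' @rdname treeWalks
#' @export
setMethod("treeWalks", "ruleForest", function(x) {
  lapply(x$trees, function(tr) {
    fm <- stats::setNames(tr$features, tr$safeNames)
    rpartWalk(tr$fit, fm)
  })
})

#' @rdname treeWalks
#' @export
setMethod("treeWalks", "list", function(x) x) # hand-built walks pass through

#' Extract decision rules from the top levels of a tree ensemble
#'
#' Emits every root-to-node path of length up to `maxDepth` as a rule: the
#' ordered conditions (variable, `<` or `>=`, cut point), the node's dominant
#' class (arg-max of the class counts, ties toward the lower class), its
#' support and Gini impurity. Rules are deduplicated across trees by their
#' (variable, comparator) sequence and one-decimal-rounded cut points,
#' keeping the median cut point of the merged instances (individual trees of
#' a forest pick slightly different cut points for the same split because
#' they train on different bootstrap samples).
#'
#' @param forest a [ruleForest()] fit, or a list of walkable trees (each a
#'   node list as produced by [treeWalks()]).
#' @param maxDepth maximum number of conditions per rule (default 3).
#' @param minSupport minimum samples a rule must cover (default 1).
#' @return data.frame of rules (`rule`, `depth`, `class`, `support`, `gini`,
#'   `nTrees`), with the structured conditions in the `conditions`
#'   list-column.
#' @export
extractRules <- function(forest, maxDepth = 3, minSupport = 1) {
  walks <- treeWalks(forest)
  if (!length(walks)) stop("no trees to extract rules from")
  inst <- list()
  for (w in walks) {
    root <- w[["1"]]
    if (is.null(root)) stop("walkable tree must contain a root node '1'")
    recurse <- function(node, conds, depth) {
      if (depth > 0 && length(conds)) {
        inst[[length(inst) + 1L]] <<- list(conds = conds,
                                           counts = node$counts,
                                           gini = node$gini)
      }
      if (node$leaf || depth >= maxDepth) return(invisible())
      for (side in c("left", "right")) {
        child <- w[[as.character(node[[side]])]]
        if (is.null(child)) next
        ltLeft <- isTRUE(node$ltGoesLeft)
        cmp <- if ((side == "left") == ltLeft) "<" else ">="
        recurse(child, c(conds, list(list(variable = node$variable,
                                          comparator = cmp,
                                          cutpoint = node$threshold))),
                depth + 1)
      }
    }
    recurse(root, list(), 0)
  }
  if (!length(inst))
    return(emptyRules())
  key <- vapply(inst, function(r) paste(vapply(r$conds, function(cn)
    paste0(cn$variable, cn$comparator, round(cn$cutpoint, 1)), character(1)),
    collapse = " & "), character(1))
  merged <- lapply(split(seq_along(inst), key), function(ix) {
    rs <- inst[ix]
    counts <- Reduce(`+`, lapply(rs, `[[`, "counts"))
    conds <- lapply(seq_along(rs[[1]]$conds), function(j) {
      cps <- vapply(rs, function(r) r$conds[[j]]$cutpoint, numeric(1))
      c0 <- rs[[1]]$conds[[j]]
      list(variable = c0$variable, comparator = c0$comparator,
           cutpoint = stats::median(cps))
    })
    support <- sum(counts)
    cls <- which.max(counts) # ties break toward the lower class
    list(conds = conds, class = cls, support = support,
         gini = stats::weighted.mean(vapply(rs, `[[`, numeric(1), "gini"),
                                     vapply(rs, function(r) sum(r$counts),
                                            numeric(1))),
         nTrees = length(ix))
  })
  merged <- merged[vapply(merged, `[[`, numeric(1), "support") >= minSupport]
  if (!length(merged)) return(emptyRules())
  df <- data.frame(
    rule = vapply(merged, function(r) paste(vapply(r$conds, function(cn)
      sprintf("%s %s %.3f", cn$variable, cn$comparator, cn$cutpoint),
      character(1)), collapse = " & "), character(1)),
    depth = vapply(merged, function(r) length(r$conds), integer(1)),
    class = vapply(merged, `[[`, integer(1), "class"),
    support = vapply(merged, `[[`, numeric(1), "support"),
    gini = vapply(merged, `[[`, numeric(1), "gini"),
    nTrees = vapply(merged, `[[`, numeric(1), "nTrees"),
    row.names = NULL)
  df$conditions <- I(lapply(merged, `[[`, "conds"))
  df[order(df$depth, -df$support), ]
}

emptyRules <- function() {
  df <- data.frame(rule = character(0), depth = integer(0),
                   class = integer(0), support = numeric(0),
                   gini = numeric(0), nTrees = numeric(0))
  df$conditions <- I(list())
  df
}

#' Direction of association of a predictor from extracted rules
#'
#' Looks at every sibling rule pair that splits on the predictor (identical
#' preceding conditions, one `<` and one `>=` branch). The association is
#' `direct` when in every such pair with differing dominant classes the
#' `>=` branch's class is the higher one, `inverse` when it is always the
#' lower one, and `indeterminate` when informative pairs conflict or none
#' exist.
#'
#' @param rules data.frame from [extractRules()].
#' @param predictor variable name.
#' @return `"direct"`, `"inverse"` or `"indeterminate"`.
#' @export
directionOfAssociation <- function(rules, predictor) {
  conds <- rules$conditions
  mentions <- vapply(conds, function(cs)
    any(vapply(cs, function(cn) cn$variable == predictor, logical(1))),
    logical(1))
  if (!any(mentions)) stop("no extracted rule mentions '", predictor, "'")
  # pair rules by prefix + cut point, comparing the < and >= branches
  sigOf <- function(cs) {
    last <- cs[[length(cs)]]
    prefix <- if (length(cs) > 1)
      paste(vapply(cs[-length(cs)], function(cn)
        paste0(cn$variable, cn$comparator, round(cn$cutpoint, 1)),
        character(1)), collapse = "&") else ""
    if (last$variable != predictor) return(NA_character_)
    paste0(prefix, "||", round(last$cutpoint, 1))
  }
  sigs <- vapply(conds, sigOf, character(1))
  votes <- integer(0)
  for (s in unique(sigs[!is.na(sigs)])) {
    ix <- which(!is.na(sigs) & sigs == s)
    lastCmp <- vapply(conds[ix], function(cs)
      cs[[length(cs)]]$comparator, character(1))
    lo <- rules$class[ix[lastCmp == "<"]]
    hi <- rules$class[ix[lastCmp == ">="]]
    if (!length(lo) || !length(hi)) next
    if (hi[1] == lo[1]) next # uninformative pair
    votes <- c(votes, sign(hi[1] - lo[1]))
  }
  if (!length(votes)) return("indeterminate")
  if (all(votes > 0)) return("direct")
  if (all(votes < 0)) return("inverse")
  "indeterminate"
}

#' Impurity-decrease importance ranking of a rule forest
#'
#' Sums the Gini impurity decrease of every split per variable across the
#' ensemble, normalizes to sum 1, and orders descending (ties
#' alphabetical).
#'
#' @param forest a [ruleForest()] fit.
#' @return data.frame (`variable`, `importance`) in decreasing order.
#' @export
importanceRanking <- function(forest) {
  tally <- stats::setNames(numeric(length(forest$predictors)),
                           forest$predictors)
  for (tr in forest$trees) {
    fit <- tr$fit
    if (is.null(fit$splits) || !nrow(fit$splits)) next
    frame <- fit$frame
    internal <- which(frame$var != "<leaf>")
    fm <- stats::setNames(tr$features, tr$safeNames)
    for (k in seq_along(internal)) {
      v0 <- as.character(frame$var[internal[k]])
      v <- if (v0 %in% names(fm)) fm[[v0]] else v0
      imp <- fit$splits[k, "improve"]
      # rpart stores relative improvement; weight by node size
      tally[v] <- tally[v] + imp * frame$n[internal[k]]
    }
  }
  if (sum(tally) > 0) tally <- tally / sum(tally)
  ord <- order(-tally, names(tally))
  data.frame(variable = names(tally)[ord], importance = unname(tally[ord]),
             row.names = NULL)
}

#' Monotonicity verdict of a posterior table
#'
#' Reads the direction of the dependence encoded in P(target | given): the
#' verdict is `direct`/`inverse` when the expected target class is strictly
#' monotone across the given classes and the class-index correlation
#' (weighted by the posterior, rows equally weighted) is at least 0.2 in
#' absolute value; `none` otherwise.
#'
#' @param posterior a \linkS4class{PosteriorTable}.
#' @param minCor minimum absolute weighted class-index correlation.
#' @return list with `verdict` and `rho`.
#' @export
posteriorVerdict <- function(posterior, minCor = 0.2) {
  P <- posterior@probs
  G <- nrow(P); K <- ncol(P)
  w <- as.vector(P / G)
  g <- rep(seq_len(G), times = K)
  t <- rep(seq_len(K), each = G)
  mg <- sum(w * g) / sum(w); mt <- sum(w * t) / sum(w)
  rho <- sum(w * (g - mg) * (t - mt)) /
    sqrt(sum(w * (g - mg)^2) * sum(w * (t - mt)^2))
  expect <- P %*% seq_len(K)
  d <- diff(as.vector(expect))
  verdict <- if (all(d > 0) && rho >= minCor) "direct"
             else if (all(d < 0) && rho <= -minCor) "inverse"
             else "none"
  list(verdict = verdict, rho = rho)
}

#' Consolidate rule-based and posterior-based evidence into one report
#'
#' Merges the importance ranking, per-predictor rule directions and the
#' Bayesian-network posterior verdicts into a single machine-readable list
#' (and optionally a human-readable markdown file).
#'
#' @param rules data.frame from [extractRules()].
#' @param importances data.frame from [importanceRanking()].
#' @param posteriors named list of \linkS4class{PosteriorTable} objects
#'   (may be empty; the posterior section is then marked unavailable).
#' @param target target variable name (annotation only).
#' @param topN predictors to report directions for (default 5).
#' @return list report (class `associationReport`).
#' @export
consolidatedReport <- function(rules, importances, posteriors = list(),
                               target = "Creatinine", topN = 5) {
  top <- utils::head(importances$variable, topN)
  directions <- lapply(top, function(v)
    tryCatch(directionOfAssociation(rules, v), error = function(e)
      "indeterminate"))
  names(directions) <- top
  post <- lapply(posteriors, function(p)
    list(given = p@given, target = p@target, probs = p@probs,
         verdict = posteriorVerdict(p)))
  structure(list(target = target, importances = importances,
                 directions = directions, rules = rules,
                 posteriors = post,
                 posteriorAvailable = length(post) > 0),
            class = "associationReport")
}

#' @export
print.associationReport <- function(x, ...) {
  cat("Association report for", x$target, "\n")
  cat("Top predictors:\n")
  top <- utils::head(x$importances, 5)
  for (i in seq_len(nrow(top))) {
    v <- top$variable[i]
    d <- x$directions[[v]] %||% "-"
    cat(sprintf("  %d. %s (importance %.3f, rule direction: %s)\n",
                i, v, top$importance[i], d))
  }
  if (x$posteriorAvailable) {
    for (nm in names(x$posteriors)) {
      p <- x$posteriors[[nm]]
      cat(sprintf("Posterior P(%s | %s): verdict %s (rho %.2f)\n",
                  p$target, p$given, p$verdict$verdict, p$verdict$rho))
    }
  } else cat("Posterior evidence: unavailable\n")
  invisible(x)
}

#' Write an association report as markdown and/or JSON
#'
#' @param report an `associationReport`.
#' @param md,json optional output paths.
#' @export
writeReport <- function(report, md = NULL, json = NULL) {
  if (!is.null(json)) {
    out <- report
    out$rules <- report$rules[, setdiff(names(report$rules), "conditions")]
    out$posteriors <- lapply(report$posteriors, function(p)
      list(given = p$given, target = p$target,
           probs = as.data.frame(p$probs),
           verdict = p$verdict$verdict, rho = p$verdict$rho))
    jsonlite::write_json(unclass(out), json, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(md)) {
    lines <- c(paste("# Association report:", report$target), "",
               "## Importance ranking", "",
               sprintf("- %s: %.4f", report$importances$variable,
                       report$importances$importance), "",
               "## Rule directions", "",
               sprintf("- %s: %s", names(report$directions),
                       unlist(report$directions)), "",
               "## Rules", "",
               sprintf("- [%s] -> class %d (support %d)",
                       report$rules$rule, report$rules$class,
                       as.integer(report$rules$support)), "")
    if (report$posteriorAvailable) {
      for (nm in names(report$posteriors)) {
        p <- report$posteriors[[nm]]
        lines <- c(lines, sprintf("## Posterior P(%s | %s): %s", p$target,
                                  p$given, p$verdict$verdict), "",
                   utils::capture.output(print(round(p$probs, 3))), "")
      }
    } else lines <- c(lines, "## Posterior evidence: unavailable", "")
    writeLines(lines, md)
  }
  invisible(report)
}

#' Export extracted rules as a flat CSV
#' @param rules data.frame from [extractRules()]; @param file output path.
#' @export
writeRules <- function(rules, file) {
  utils::write.csv(rules[, setdiff(names(rules), "conditions")], file,
                   row.names = FALSE)
  invisible(file)
}
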