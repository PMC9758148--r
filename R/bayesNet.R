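#' Construct a DAG
#'
#' @param nodes character vector of node names.
#' @param edges two-column (parent, child) character matrix or data.frame;
#'   empty by default.
#' @return a \linkS4class{DAG}.
#' @export
DAG <- function(nodes, edges = NULL) {
  if (is.null(edges)) {
    edges <- matrix(character(0), 0, 2)
  } else {
    edges <- as.matrix(edges)
    storage.mode(edges) <- "character"
  }
  colnames(edges) <- c("parent", "child")
  new("DAG", nodes = nodes, edges = edges)
}

#' @rdname edges
#' @export
setMethod("edges", "DAG", function(x) x@edges)

#' @rdname edges
#' @export
setMethod("edges", "DiscreteBN", function(x) x@dag@edges)

#' @rdname parents
#' @export
setMethod("parents", "DAG", function(x, node) dagParents(x, node))

#' @rdname parents
#' @export
setMethod("parents", "DiscreteBN", function(x, node) dagParents(x@dag, node))

setMethod("show", "DAG", function(object) {
  cat(sprintf("DAG: %d nodes, %d edges\n", length(object@nodes),
              nrow(object@edges)))
  if (nrow(object@edges))
    cat(paste0("  ", object@edges[, 1], " -> ", object@edges[, 2],
               collapse = "\n"), "\n")
})

setMethod("show", "DiscreteBN", function(object) {
  cat(sprintf("DiscreteBN: %d nodes, %d edges, cardinalities %s\n",
              length(object@dag@nodes), nrow(object@dag@edges),
              paste(unique(object@cardinalities), collapse = "/")))
})

# ---- BIC scoring ------------------------------------------------------------

# cell counts of (node | parent configuration); data is an integer matrix with
# classes 1..card per column and no NA
familyCounts <- function(data, node, pars, card) {
  r <- card[[node]]
  x <- data[, node]
  if (!length(pars)) return(matrix(tabulate(x, r), nrow = r))
  q <- 1L
  idx <- integer(nrow(data))
  for (p in pars) {
    idx <- idx + (data[, p] - 1L) * q
    q <- q * card[[p]]
  }
  m <- tabulate(idx * r + x, nbins = r * q)
  matrix(m, nrow = r)
}

# BIC local score of one (node, parents) family: log-likelihood minus
# 0.5 log(N) (r-1) q penalty
bicFamily <- function(data, node, pars, card) {
  cnt <- familyCounts(data, node, pars, card)
  tot <- colSums(cnt)
  ll <- sum(cnt[cnt > 0] * log(cnt[cnt > 0] /
                                 rep(tot, each = nrow(cnt))[cnt > 0]))
  q <- ncol(cnt)
  ll - 0.5 * log(nrow(data)) * (card[[node]] - 1) * q
}

#' BIC score of a DAG on discretized data
#'
#' @param dag a \linkS4class{DAG}.
#' @param data integer matrix of class labels (1..cardinality per column).
#' @return total BIC (sum of local family scores; larger is better).
#' @export
bicScore <- function(dag, data) {
  card <- apply(data, 2, max)
  sum(vapply(dag@nodes, function(v)
    bicFamily(data, v, dagParents(dag, v), card), numeric(1)))
}

# ---- structure learning -----------------------------------------------------

# permutation-null screening: keep pairs whose mutual information exceeds the
# 95th percentile of a 100-permutation null
screenPairs <- function(data, nperm = 100, alpha = 0.95) {
  vars <- colnames(data)
  p <- length(vars)
  card <- apply(data, 2, max)
  keep <- matrix(FALSE, p, p, dimnames = list(vars, vars))
  n <- nrow(data)
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    a <- data[, i]; b <- data[, j]
    if (card[i] < 2 || card[j] < 2) next
    mi <- mutualInfo(a, b, card[i], card[j])
    null <- vapply(seq_len(nperm), function(k)
      mutualInfo(a, b[sample.int(n)], card[i], card[j]), numeric(1))
    if (mi > stats::quantile(null, alpha))
      keep[i, j] <- keep[j, i] <- TRUE
  }
  keep
}

addEdgeCheck <- function(nodes, edges, from, to) {
  e2 <- rbind(edges, c(from, to))
  if (is.null(topoSort(nodes, e2))) NULL else e2
}

#' Learn a discrete Bayesian-network structure
#'
#' Two-stage learner in the spirit of max-min hill-climbing: a
#' mutual-information screen against a seeded permutation null restricts the
#' candidate neighbour set of every node, then greedy hill-climbing over
#' add/delete/reverse moves maximizes the BIC score, with random restarts.
#'
#' @param data integer matrix (or [LabTable] of class labels) of discretized
#'   variables, classes coded 1..k, complete rows only.
#' @param maxParents maximum in-degree (default 3).
#' @param restarts number of perturbed restarts beyond the first climb.
#' @param seed integer seed (screening permutations and restart perturbations).
#' @param screen logical; set `FALSE` to skip the MI screen (all pairs
#'   candidates).
#' @return a \linkS4class{DAG}; columns with a single observed class are left
#'   isolated with a warning.
#' @export
learnStructure <- function(data, maxParents = 3, restarts = 2, seed = 1,
                           screen = TRUE) {
  if (is(data, "LabTable")) data <- labValues(data)
  data <- as.matrix(data)
  if (!nrow(data)) stop("empty data")
  if (anyNA(data)) stop("structure learning needs complete rows")
  storage.mode(data) <- "integer"
  vars <- colnames(data)
  card <- apply(data, 2, max)
  single <- vars[apply(data, 2, function(x) length(unique(x))) < 2]
  if (length(single))
    warning("single-class columns left isolated: ",
            paste(single, collapse = ", "))
  active <- setdiff(vars, single)
  withSeed(seed, {
    cand <- if (screen) screenPairs(data[, , drop = FALSE])
            else matrix(TRUE, length(vars), length(vars),
                        dimnames = list(vars, vars))
    cand[single, ] <- FALSE
    cand[, single] <- FALSE
    candPairs <- which(upper.tri(cand) & cand, arr.ind = TRUE)
    pairList <- cbind(vars[candPairs[, 1]], vars[candPairs[, 2]])

    climb <- function(edges) {
      score <- vapply(vars, function(v)
        bicFamily(data, v, sortedParents(edges, v), card), numeric(1))
      repeat {
        best <- list(gain = 1e-9, edges = NULL, upd = NULL)
        for (k in seq_len(nrow(pairList))) {
          a <- pairList[k, 1]; b <- pairList[k, 2]
          hasAB <- any(edges[, 1] == a & edges[, 2] == b)
          hasBA <- any(edges[, 1] == b & edges[, 2] == a)
          moves <- list()
          if (!hasAB && !hasBA) {
            moves <- list(c("add", a, b), c("add", b, a))
          } else if (hasAB) {
            moves <- list(c("del", a, b), c("rev", a, b))
          } else {
            moves <- list(c("del", b, a), c("rev", b, a))
          }
          for (mv in moves) {
            op <- mv[1]; fr <- mv[2]; to <- mv[3]
            e2 <- switch(op,
              add = {
                if (length(sortedParents(edges, to)) >= maxParents) NULL
                else addEdgeCheck(vars, edges, fr, to)
              },
              del = edges[!(edges[, 1] == fr & edges[, 2] == to), ,
                          drop = FALSE],
              rev = {
                e1 <- edges[!(edges[, 1] == fr & edges[, 2] == to), ,
                            drop = FALSE]
                if (length(sortedParents(e1, fr)) >= maxParents) NULL
                else addEdgeCheck(vars, e1, to, fr)
              })
            if (is.null(e2)) next
            touched <- if (op == "rev") c(fr, to) else to
            newLocal <- vapply(touched, function(v)
              bicFamily(data, v, sortedParents(e2, v), card), numeric(1))
            gain <- sum(newLocal) - sum(score[touched])
            if (gain > best$gain) best <- list(gain = gain, edges = e2,
                                               upd = newLocal)
          }
        }
        if (is.null(best$edges)) break
        edges <- best$edges
        score[names(best$upd)] <- best$upd
      }
      list(edges = edges, score = sum(score))
    }

    empty <- matrix(character(0), 0, 2)
    best <- climb(empty)
    if (restarts > 0 && nrow(pairList)) {
      for (r in seq_len(restarts)) {
        # perturb: random subset of candidate pairs as a seed graph
        sel <- which(stats::runif(nrow(pairList)) < 0.3)
        e0 <- empty
        for (k in sel) {
          dir <- sample(c(TRUE, FALSE), 1)
          fr <- if (dir) pairList[k, 1] else pairList[k, 2]
          to <- if (dir) pairList[k, 2] else pairList[k, 1]
          if (length(sortedParents(e0, to)) >= maxParents) next
          e1 <- addEdgeCheck(vars, e0, fr, to)
          if (!is.null(e1)) e0 <- e1
        }
        cur <- climb(e0)
        if (cur$score > best$score + 1e-9) best <- cur
      }
    }
    out <- best$edges
    colnames(out) <- c("parent", "child")
    new("DAG", nodes = vars, edges = out)
  })
}

sortedParents <- function(edges, node) {
  if (!nrow(edges)) return(character(0))
  sort(unname(edges[edges[, 2] == node, 1]))
}

#' Fit conditional probability tables for a DAG
#'
#' Maximum-likelihood with Laplace smoothing: each CPT entry is
#' (count + alpha) / (config total + alpha x cardinality).
#'
#' @param dag a \linkS4class{DAG}.
#' @param data integer matrix of class labels (complete rows).
#' @param alpha Laplace pseudo-count (>= 0, default 1).
#' @param cardinalities optional named integer vector; defaults to the maxima
#'   observed per column (at least 2).
#' @return a \linkS4class{DiscreteBN}.
#' @export
fitParameters <- function(dag, data, alpha = 1, cardinalities = NULL) {
  if (is(data, "LabTable")) data <- labValues(data)
  data <- as.matrix(data)
  storage.mode(data) <- "integer"
  if (alpha < 0) stop("alpha must be non-negative")
  if (is.null(cardinalities))
    cardinalities <- pmax(apply(data, 2, max), 2L)
  card <- as.integer(cardinalities[dag@nodes])
  names(card) <- dag@nodes
  cpts <- list()
  for (v in dag@nodes) {
    pa <- dagParents(dag, v)
    cnt <- familyCounts(data, v, pa, card)
    r <- card[[v]]
    probs <- (cnt + alpha) / rep(colSums(cnt) + alpha * r, each = r)
    if (alpha == 0 && any(colSums(cnt) == 0))
      probs[, colSums(cnt) == 0] <- 1 / r
    dims <- c(r, if (length(pa)) unname(card[pa]))
    cpts[[v]] <- array(probs, dim = dims,
                       dimnames = c(list(seq_len(r)),
                                    if (length(pa))
                                      lapply(unname(card[pa]), seq_len)))
  }
  new("DiscreteBN", dag = dag, cardinalities = card, cpts = cpts)
}

# ---- exact inference (variable elimination) ---------------------------------

# a factor is list(vars = character, values = array with one dim per var)
cptFactor <- function(bn, v) {
  pa <- dagParents(bn@dag, v)
  list(vars = c(v, pa), values = as.array(bn@cpts[[v]]))
}

factorReduce <- function(f, var, value) {
  i <- match(var, f$vars)
  if (is.na(i)) return(f)
  idx <- rep(list(quote(expr = )), length(f$vars))
  idx[[i]] <- value
  vals <- do.call(`[`, c(list(f$values), idx, list(drop = FALSE)))
  keep <- seq_along(f$vars)[-i]
  if (!length(keep))
    return(list(vars = character(0), values = array(sum(vals), dim = 1)))
  list(vars = f$vars[keep],
       values = array(vals, dim = dim(f$values)[keep]))
}

factorProduct <- function(f, g) {
  if (!length(f$vars))
    return(list(vars = g$vars, values = g$values * sum(f$values)))
  if (!length(g$vars))
    return(list(vars = f$vars, values = f$values * sum(g$values)))
  allv <- union(f$vars, g$vars)
  df <- dim(f$values); dg <- dim(g$values)
  dims <- integer(length(allv))
  dims[match(f$vars, allv)] <- df
  dims[match(g$vars, allv)] <- dg
  expand <- function(h) {
    perm0 <- match(h$vars, allv)
    out <- array(1, dims)
    # broadcast h over the missing dimensions
    grid <- arrayInd(seq_len(prod(dims)), dims)
    sub <- grid[, perm0, drop = FALSE]
    hidx <- 1L + as.vector((sub - 1L) %*%
                             cumprod(c(1L, utils::head(dim(h$values), -1L))))
    array(as.vector(h$values)[hidx], dims)
  }
  list(vars = allv, values = expand(f) * expand(g))
}

factorMarginalize <- function(f, var) {
  i <- match(var, f$vars)
  if (is.na(i)) return(f)
  keep <- seq_along(f$vars)[-i]
  if (!length(keep))
    return(list(vars = character(0),
                values = array(sum(f$values), dim = 1)))
  vals <- apply(f$values, keep, sum)
  list(vars = f$vars[keep], values = array(vals, dim = dim(f$values)[keep]))
}

# exact marginal P(target | evidence) by variable elimination
veQuery <- function(bn, target, evidence = list()) {
  nodes <- bn@dag@nodes
  if (!target %in% nodes) stop("unknown target variable: ", target)
  ev <- names(evidence)
  if (length(setdiff(ev, nodes))) stop("evidence names unknown variables")
  for (v in ev) {
    val <- evidence[[v]]
    if (!val %in% seq_len(bn@cardinalities[[v]]))
      stop("evidence class out of range for ", v)
  }
  factors <- lapply(nodes, function(v) cptFactor(bn, v))
  for (v in ev)
    factors <- lapply(factors, factorReduce, var = v, value = evidence[[v]])
  elim <- setdiff(nodes, c(target, ev))
  # min-degree-ish ordering: fewest connected factors first
  for (v in elim[order(vapply(elim, function(u)
    sum(vapply(factors, function(f) u %in% f$vars, logical(1))), numeric(1)))]) {
    touch <- vapply(factors, function(f) v %in% f$vars, logical(1))
    if (!any(touch)) next
    prod <- Reduce(factorProduct, factors[touch])
    factors <- c(factors[!touch], list(factorMarginalize(prod, v)))
  }
  res <- Reduce(factorProduct, factors)
  for (u in setdiff(res$vars, target)) res <- factorMarginalize(res, u)
  vals <- as.vector(res$values)
  if (sum(vals) <= 0) stop("contradictory evidence: zero-probability event")
  vals / sum(vals)
}

#' Posterior table P(target | given) from a Bayesian network
#'
#' One row per class of the conditioning variable, one column per target
#' class, computed by exact inference over the network.
#'
#' @param bn a \linkS4class{DiscreteBN}.
#' @param target,given variable names in the network.
#' @return a \linkS4class{PosteriorTable}.
#' @export
posteriorTable <- function(bn, target, given) {
  nodes <- bn@dag@nodes
  if (!target %in% nodes || !given %in% nodes)
    stop("both variables must be nodes of the network")
  kg <- bn@cardinalities[[given]]
  kt <- bn@cardinalities[[target]]
  probs <- t(vapply(seq_len(kg), function(g)
    veQuery(bn, target, stats::setNames(list(g), given)), numeric(kt)))
  dimnames(probs) <- list(paste0(given, "=", seq_len(kg)),
                          paste0(target, "=", seq_len(kt)))
  new("PosteriorTable", given = given, target = target, probs = probs)
}

setMethod("show", "PosteriorTable", function(object) {
  cat(sprintf("PosteriorTable: P(%s | %s)\n", object@target, object@given))
  print(round(object@probs, 3))
})

#' Export a posterior table as CSV (rows = given classes, cols = target)
#' @param x a \linkS4class{PosteriorTable}; @param file output path.
#' @export
writePosteriorTable <- function(x, file) {
  utils::write.csv(as.data.frame(x@probs), file, row.names = TRUE)
  invisible(file)
}

#' Predict a class distribution from partial evidence
#'
#' Exact inference for the target's posterior given any partial class
#' assignment; the reported class is the arg-max with ties broken toward the
#' lower class index.
#'
#' @param bn a \linkS4class{DiscreteBN}.
#' @param evidence named list of observed classes (subset of the nodes,
#'   excluding `target`).
#' @param target variable to predict.
#' @return list with `distribution` and `class`.
#' @export
predictClass <- function(bn, evidence, target) {
  if (target %in% names(evidence)) stop("target cannot appear in the evidence")
  d <- veQuery(bn, target, evidence)
  list(distribution = d, class = which.max(d))
}

#' Simulate complete discrete data from a Bayesian network
#'
#' Ancestral sampling in topological order; used as the ground-truth source
#' for structure-recovery checks.
#'
#' @param bn a \linkS4class{DiscreteBN}.
#' @param n rows to draw; @param seed integer seed.
#' @return integer matrix of class labels.
#' @export
simulateBN <- function(bn, n, seed = 1) {
  ord <- topoSort(bn@dag@nodes, bn@dag@edges)
  out <- matrix(NA_integer_, n, length(ord),
                dimnames = list(NULL, bn@dag@nodes))
  withSeed(seed, {
    for (v in ord) {
      pa <- dagParents(bn@dag, v)
      cpt <- as.array(bn@cpts[[v]])
      r <- bn@cardinalities[[v]]
      if (!length(pa)) {
        out[, v] <- sample.int(r, n, replace = TRUE, prob = as.vector(cpt))
      } else {
        cfg <- integer(n)
        q <- 1L
        for (p in pa) {
          cfg <- cfg + (out[, p] - 1L) * q
          q <- q * bn@cardinalities[[p]]
        }
        m <- matrix(cpt, nrow = r)
        u <- stats::runif(n)
        cum <- apply(m, 2, cumsum)
        out[, v] <- vapply(seq_len(n), function(i)
          findInterval(u[i], cum[, cfg[i] + 1L],
                       left.open = TRUE) + 1L, integer(1))
      }
    }
  })
  out
}

#' Export a DAG as a DOT description or JSON edge list
#' @param dag a \linkS4class{DAG}; @param file output path.
#' @export
writeDot <- function(dag, file) {
  lines <- c("digraph bn {",
             paste0("  \"", dag@nodes, "\";"),
             if (nrow(dag@edges))
               paste0("  \"", dag@edges[, 1], "\" -> \"", dag@edges[, 2],
                      "\";"),
             "}")
  writeLines(lines, file)
  invisible(file)
}

#' @rdname writeDot
#' @export
writeEdgeList <- function(dag, file) {
  jsonlite::write_json(list(nodes = dag@nodes,
                            edges = as.data.frame(dag@edges)),
                       file, auto_unbox = TRUE)
  invisible(file)
}
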