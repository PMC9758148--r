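# Independent oracles used across the suite. These deliberately use
# brute-force enumeration / rank statistics rather than the package's own
# code paths.

# full-joint enumeration of a discrete BN: returns data.frame of all class
# configurations with their joint probability
enumJoint <- function(bn) {
  nodes <- bn@dag@nodes
  grid <- expand.grid(lapply(bn@cardinalities[nodes], seq_len))
  names(grid) <- nodes
  p <- apply(grid, 1, function(r) {
    pr <- 1
    for (v in nodes) {
      pa <- parents(bn, v)
      idx <- c(r[[v]], if (length(pa)) unlist(r[pa]))
      pr <- pr * do.call(`[`, c(list(as.array(bn@cpts[[v]])),
                                as.list(as.integer(idx))))
    }
    pr
  })
  cbind(grid, p = p)
}

# oracle conditional P(target | evidence) from the enumerated joint
enumConditional <- function(bn, target, evidence = list()) {
  J <- enumJoint(bn)
  keep <- rep(TRUE, nrow(J))
  for (v in names(evidence)) keep <- keep & J[[v]] == evidence[[v]]
  sub <- J[keep, ]
  out <- tapply(sub$p, factor(sub[[target]],
                              levels = seq_len(bn@cardinalities[[target]])),
                sum)
  out[is.na(out)] <- 0
  as.numeric(out) / sum(out)
}

# Mann-Whitney AUC with midrank tie handling (independent of binaryRoc)
mwAuc <- function(pos, score) {
  r <- rank(score)
  P <- sum(pos); N <- sum(!pos)
  (sum(r[pos]) - P * (P + 1) / 2) / (P * N)
}

# random DAG over k nodes with random 3-class CPTs (Dirichlet via gamma)
randomBN <- function(k, seed, edgeProb = 0.4) {
  set.seed(seed)
  nodes <- LETTERS[seq_len(k)]
  ord <- sample(nodes)
  edges <- matrix(character(0), 0, 2)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    if (stats::runif(1) < edgeProb)
      edges <- rbind(edges, c(ord[i], ord[j]))
  }
  dag <- DAG(nodes, if (nrow(edges)) edges else NULL)
  card <- stats::setNames(rep(3L, k), nodes)
  cpts <- lapply(nodes, function(v) {
    pa <- parents(dag, v)
    q <- prod(c(1, card[pa]))
    m <- matrix(stats::rgamma(3 * q, 1) + 0.05, nrow = 3)
    m <- sweep(m, 2, colSums(m), `/`)
    array(m, dim = c(3, card[pa]))
  })
  names(cpts) <- nodes
  new("DiscreteBN", dag = dag, cardinalities = card, cpts = cpts)
}

# simple correlated-gaussian generator config for imputation tests
gaussCopulaConfig <- function(n, p = 10, r = 0.6, rate = 0.3, seed = 1) {
  marg <- stats::setNames(lapply(seq_len(p), function(i)
    list(marginal = "gaussian", mean = 10, sd = 2)), paste0("V", seq_len(p)))
  R <- matrix(r, p, p)
  diag(R) <- 1
  labPanelConfig(n, marg, R,
                 missingRates = stats::setNames(rep(rate, p), names(marg)),
                 seed = seed)
}

# normalized masked MSE of a completed table against generator ground truth
truthMse <- function(completed, truth, vars = NULL) {
  X <- labValues(completeTable(truth))
  M <- missingMask(maskedTable(truth))
  if (is.null(vars)) vars <- colnames(labValues(completed))
  est <- labValues(completed)
  vals <- vapply(vars, function(v) {
    i <- M[, v]
    if (!any(i)) return(NA_real_)
    rng <- diff(range(X[, v]))
    mean(((est[i, v] - X[i, v]) / rng)^2)
  }, numeric(1))
  mean(vals, na.rm = TRUE)
}

# hand-built two-level walkable tree mirroring the ferritin / vitamin-D rule
# template: root splits on Ferritin, left subtree splits twice on VitD
handRuleTree <- function() {
  node <- function(id, leaf, variable = NA, threshold = NA, counts,
                   ltGoesLeft = TRUE) {
    list(id = id, leaf = leaf, variable = variable, threshold = threshold,
         ltGoesLeft = ltGoesLeft, left = 2L * id, right = 2L * id + 1L,
         counts = counts, gini = 1 - sum((counts / sum(counts))^2))
  }
  w <- list(
    node(1L, FALSE, "Ferritin", 101.578, c(300, 250, 250)),
    node(2L, FALSE, "VitD", 27.812, c(280, 200, 120)),
    node(3L, TRUE, counts = c(20, 50, 130)),
    node(4L, TRUE, counts = c(250, 40, 10)),
    node(5L, FALSE, "VitD", 35.648, c(30, 160, 110)),
    node(10L, TRUE, counts = c(25, 140, 35)),
    node(11L, TRUE, counts = c(5, 20, 75)))
  names(w) <- vapply(w, function(n) as.character(n$id), character(1))
  list(w) # a one-tree ensemble in walkable form
}
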