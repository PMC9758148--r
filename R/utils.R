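# Shared internal helpers.

# Kahn topological sort; returns NULL when the edge set contains a cycle.
topoSort <- function(nodes, edges) {
  if (!nrow(edges)) return(nodes)
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  kids <- split(edges[, 2], factor(edges[, 1], levels = nodes))
  tab <- table(factor(edges[, 2], levels = nodes))
  indeg[names(tab)] <- as.integer(tab)
  queue <- nodes[indeg == 0]
  out <- character(0)
  while (length(queue)) {
    n <- queue[1]; queue <- queue[-1]
    out <- c(out, n)
    for (k in kids[[n]]) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) queue <- c(queue, k)
    }
  }
  if (length(out) != length(nodes)) NULL else out
}

dagParents <- function(dag, node) {
  e <- dag@edges
  if (!nrow(e)) return(character(0))
  sort(unname(e[e[, 2] == node, 1]))
}

dagChildren <- function(dag, node) {
  e <- dag@edges
  if (!nrow(e)) return(character(0))
  sort(unname(e[e[, 1] == node, 2]))
}

# min-max normalization against a stored range; zero-range columns map to 0
minmaxNorm <- function(x, lo, hi) {
  rng <- hi - lo
  if (!is.finite(rng) || rng <= 0) return(rep(0, length(x)))
  (x - lo) / rng
}

# empirical mutual information (nats) of two discrete vectors
mutualInfo <- function(a, b, ka = max(a), kb = max(b)) {
  n <- length(a)
  joint <- tabulate((a - 1L) * kb + b, nbins = ka * kb) / n
  pa <- tabulate(a, nbins = ka) / n
  pb <- tabulate(b, nbins = kb) / n
  pp <- outer(pa, pb)
  jm <- matrix(joint, nrow = ka, byrow = TRUE)
  pos <- jm > 0
  sum(jm[pos] * log(jm[pos] / pp[pos]))
}

# run code under a local, restorable RNG state
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  force(code)
}
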