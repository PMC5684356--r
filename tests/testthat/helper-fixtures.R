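# Shared fixtures and independent oracles used across the suite.

# independent breadth-first-search distance oracle (does not use igraph)
bfsDistance <- function(reactions, from, to, nodes) {
  adj <- lapply(setNames(nodes, nodes), function(x) character())
  for (r in seq_len(nrow(reactions))) {
    s <- reactions$substrate[r]; p <- reactions$product[r]
    adj[[s]] <- c(adj[[s]], p)
    adj[[p]] <- c(adj[[p]], s)
  }
  dist <- setNames(rep(Inf, length(nodes)), nodes)
  dist[from] <- 0
  queue <- from
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    for (w in adj[[v]]) if (!is.finite(dist[w])) {
      dist[w] <- dist[v] + 1
      queue <- c(queue, w)
    }
  }
  unname(dist[to])
}

# exhaustive hypergeometric oracle for the two-sided Fisher 2x2 p-value,
# written from the closed-form table probability (choose products)
fisherOracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; k <- a + c; n <- r1 + r2
  support <- max(0, k - r2):min(k, r1)
  prob <- choose(r1, support) * choose(r2, k - support) / choose(n, k)
  pObs <- prob[support == a]
  sum(prob[prob <= pObs * (1 + 1e-7)])
}

# build a CorrelationNetwork by hand from an edge list (for modularity and
# masking tests)
makeTestNetwork <- function(nodes, edges, coef = 0.5, kind = "ggm",
                            n = 100L) {
  p <- length(nodes)
  dn <- list(nodes, nodes)
  est <- diag(p); dimnames(est) <- dn
  pv <- matrix(NA_real_, p, p, dimnames = dn)
  qv <- matrix(NA_real_, p, p, dimnames = dn)
  mask <- matrix(FALSE, p, p, dimnames = dn)
  if (length(edges)) for (e in edges) {
    i <- e[[1L]]; j <- e[[2L]]
    w <- if (length(e) >= 3L) as.numeric(e[[3L]]) else coef
    est[i, j] <- est[j, i] <- w
    pv[i, j] <- pv[j, i] <- 1e-6
    qv[i, j] <- qv[j, i] <- 1e-6
    mask[i, j] <- mask[j, i] <- TRUE
  }
  new("CorrelationNetwork", estimates = est, pvalues = pv, qvalues = qv,
      mask = mask, kind = kind, lambda = NA_real_, nSamples = as.integer(n),
      confounders = character(), alpha = 0.01)
}

# simulate + preprocess helper used by inference tests
preprocessCohort <- function(se, pqn = TRUE) {
  if (pqn) logTransform(pqnNormalize(dropIncomplete(se)))
  else logTransform(glycoformValues(dropIncomplete(se)))
}

cohortConfounders <- function(se) {
  as.data.frame(SummarizedExperiment::colData(se))[, c("age", "sex")]
}
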