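# Subclass-based Newman modularity with a degree-preserving rewiring null.

# positive significant edges as a two-column matrix of node indices
.positiveEdges <- function(network) {
  stopifnot(is(network, "CorrelationNetwork"))
  sel <- network@mask & network@estimates > 0
  idx <- which(sel & upper.tri(sel), arr.ind = TRUE)
  unname(idx)
}

.edgeLabels <- function(network, labels = NULL) {
  nodes <- nodeLabels(network)
  if (is.null(labels)) {
    labels <- parseGlycoform(nodes)$subclass
    names(labels) <- nodes
  }
  if (is.null(names(labels))) names(labels) <- nodes
  miss <- setdiff(nodes, names(labels))
  if (length(miss))
    stop("unlabeled node(s): ", paste(miss, collapse = ", "))
  labels[nodes]
}

# Q = sum_i (e_ii - a_i^2) for an edge index matrix and node labels
.newmanQ <- function(edges, nodeGroups) {
  groups <- sort(unique(nodeGroups))
  k <- length(groups)
  m <- nrow(edges)
  e <- matrix(0, k, k, dimnames = list(groups, groups))
  g1 <- match(nodeGroups[edges[, 1L]], groups)
  g2 <- match(nodeGroups[edges[, 2L]], groups)
  for (r in seq_len(m)) {
    if (g1[r] == g2[r]) e[g1[r], g1[r]] <- e[g1[r], g1[r]] + 1 / m
    else {
      e[g1[r], g2[r]] <- e[g1[r], g2[r]] + 1 / (2 * m)
      e[g2[r], g1[r]] <- e[g2[r], g1[r]] + 1 / (2 * m)
    }
  }
  a <- rowSums(e)
  list(Q = sum(diag(e)) - sum(a^2), e = e)
}

#' Subclass-based network modularity
#'
#' Newman's modularity \code{Q = sum_i (e_ii - a_i^2)} evaluated for the
#' fixed partition of glycoforms into IgG subclasses, computed from the
#' significantly positive edges of the network. Also returns the
#' row-normalized subclass x subclass edge-fraction matrix (the relative
#' out-degree from each subclass to each other).
#'
#' @param network a \code{\linkS4class{CorrelationNetwork}}.
#' @param labels optional named vector mapping node labels to groups;
#'   defaults to the IgG subclass parsed from the glycoform label.
#' @return list with \code{Q}, \code{edgeFractions} (the e matrix) and
#'   \code{outDegree} (row-normalized).
#' @export
subclassModularity <- function(network, labels = NULL) {
  nodeGroups <- .edgeLabels(network, labels)
  edges <- .positiveEdges(network)
  if (!nrow(edges)) stop("no significantly positive edges")
  nq <- .newmanQ(edges, nodeGroups)
  rs <- rowSums(nq$e)
  out <- nq$e / ifelse(rs > 0, rs, 1)
  list(Q = nq$Q, edgeFractions = nq$e, outDegree = out)
}

# one degree-preserving randomization: 'swaps' accepted double-edge swaps;
# rejected proposals (self-loops or multi-edges) are re-drawn
.rewireEdges <- function(edges, swaps) {
  m <- nrow(edges)
  key <- function(i, j) paste(pmin(i, j), pmax(i, j))
  present <- new.env(hash = TRUE)
  for (r in seq_len(m)) assign(key(edges[r, 1L], edges[r, 2L]), TRUE, present)
  accepted <- 0L
  while (accepted < swaps) {
    rr <- sample.int(m, 2L)
    a <- edges[rr[1L], ]; b <- edges[rr[2L], ]
    # swap end nodes: (a1,a2),(b1,b2) -> (a1,b2),(b1,a2)
    n1 <- c(a[1L], b[2L]); n2 <- c(b[1L], a[2L])
    if (n1[1L] == n1[2L] || n2[1L] == n2[2L]) next
    k1 <- key(n1[1L], n1[2L]); k2 <- key(n2[1L], n2[2L])
    if (k1 == k2 || exists(k1, present, inherits = FALSE) ||
        exists(k2, present, inherits = FALSE)) next
    rm(list = c(key(a[1L], a[2L]), key(b[1L], b[2L])), envir = present)
    assign(k1, TRUE, present); assign(k2, TRUE, present)
    edges[rr[1L], ] <- n1
    edges[rr[2L], ] <- n2
    accepted <- accepted + 1L
  }
  edges
}

#' Degree-preserving rewiring null for subclass modularity
#'
#' Generates \code{nNull} randomized networks by repeated double-edge swaps
#' of the significantly positive edges (each randomization performs
#' \code{swapsFactor} times the number of edges accepted swaps; proposals
#' creating self-loops or multi-edges are re-drawn). The empirical p-value
#' uses the add-one convention \code{p = (1 + #\{Q_null >= Q_obs\}) /
#' (nNull + 1)}, so it is never exactly zero.
#'
#' @param network a \code{\linkS4class{CorrelationNetwork}}.
#' @param labels optional node-to-group labels (see
#'   \code{\link{subclassModularity}}).
#' @param nNull number of null networks (default 1e5).
#' @param swapsFactor accepted swaps per edge (default 10).
#' @param seed optional RNG seed for reproducibility.
#' @return list with \code{Q} (observed), \code{p} (empirical), and
#'   \code{nullQ} (the null distribution).
#' @export
rewireNull <- function(network, labels = NULL, nNull = 1e5,
                       swapsFactor = 10, seed = NULL) {
  nodeGroups <- .edgeLabels(network, labels)
  edges <- .positiveEdges(network)
  if (nrow(edges) < 2L) stop("graph too small to rewire (need >= 2 edges)")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  qObs <- .newmanQ(edges, nodeGroups)$Q
  swaps <- swapsFactor * nrow(edges)
  nullQ <- vapply(seq_len(nNull), function(b)
    .newmanQ(.rewireEdges(edges, swaps), nodeGroups)$Q, 0)
  p <- (1 + sum(nullQ >= qObs)) / (nNull + 1)
  list(Q = qObs, p = p, nullQ = nullQ)
}
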