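# Correlation and shrinkage partial-correlation (GGM) network estimation.

.clamp <- function(x, lo = -1, hi = 1) pmin(pmax(x, lo), hi)

# Pearson correlation with two-sided t-test p-values; errors on zero variance
.fastPearson <- function(x, strict = TRUE) {
  n <- nrow(x)
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0 | is.na(sds))) {
    if (strict)
      stop("zero-variance glycoform(s): ",
           paste(colnames(x)[sds == 0 | is.na(sds)], collapse = ", "))
    sds[sds == 0 | is.na(sds)] <- NA
  }
  r <- .clamp(stats::cor(x))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[r^2 >= 1] <- 0
  diag(p) <- NA
  list(r = r, p = p, n = n)
}

# Schafer-Strimmer analytic shrinkage of the correlation matrix toward the
# identity: lambda* = sum Var(r_ij) / sum r_ij^2 over off-diagonal entries.
.shrinkageIntensity <- function(x) {
  n <- nrow(x)
  w <- scale(x)
  s1 <- crossprod(w)              # sum_k w_ki w_kj = (n-1) r_ij
  s2 <- crossprod(w^2)
  vr <- n / ((n - 1)^3) * (s2 - s1^2 / n)
  r <- s1 / (n - 1)
  off <- upper.tri(r)
  lambda <- sum(vr[off]) / sum(r[off]^2)
  min(1, max(0, lambda))
}

# Partial correlations from the shrunken correlation matrix
.shrinkPcor <- function(x, lambda = NULL) {
  r <- .clamp(stats::cor(x))
  if (is.null(lambda)) lambda <- .shrinkageIntensity(x)
  rs <- (1 - lambda) * r
  diag(rs) <- 1
  omega <- tryCatch(chol2inv(chol(rs)), error = function(e) {
    # cannot occur for lambda > 0; guard against numerically singular input
    chol2inv(chol(rs + diag(1e-8, nrow(rs))))
  })
  d <- sqrt(diag(omega))
  pc <- -omega / tcrossprod(d)
  diag(pc) <- 1
  dimnames(pc) <- dimnames(r)
  list(pcor = .clamp(pc), lambda = lambda)
}

.bhAdjust <- function(p) {
  q <- p
  off <- upper.tri(p)
  q[off] <- stats::p.adjust(p[off], method = "BH")
  q[lower.tri(q)] <- t(q)[lower.tri(q)]
  q
}

.newNetwork <- function(r, p, kind, n, alpha, lambda = NA_real_,
                        confounders = character()) {
  q <- .bhAdjust(p)
  mask <- !is.na(q) & q <= alpha
  diag(mask) <- FALSE
  new("CorrelationNetwork", estimates = r, pvalues = p, qvalues = q,
      mask = mask, kind = kind, lambda = lambda, nSamples = as.integer(n),
      confounders = confounders, alpha = alpha)
}

#' Pearson correlation network
#'
#' Pairwise product-moment correlations with two-sided p-values from the
#' t-distribution transform, Benjamini-Hochberg correction over all tested
#' pairs, and a significance mask at the given FDR.
#'
#' @param x samples x glycoforms matrix (complete, >= 3 samples), or a
#'   \code{SummarizedExperiment}.
#' @param alpha FDR level (default 0.01).
#' @return A \code{\linkS4class{CorrelationNetwork}} of kind
#'   \code{"pearson"}.
#' @export
pearsonNetwork <- function(x, alpha = 0.01) {
  v <- glycoformValues(x)
  stopifnot(nrow(v) >= 3, !anyNA(v))
  fp <- .fastPearson(v)
  .newNetwork(fp$r, fp$p, "pearson", fp$n, alpha)
}

#' Shrinkage partial-correlation network
#'
#' Estimates partial correlations (pairwise dependencies conditioned on all
#' other glycoforms and the confounders) from the analytically shrunken
#' correlation matrix, with the shrinkage intensity lambda* chosen to
#' minimize the estimator's expected squared error (shrinkage toward the
#' identity target). Confounders are included in the
#' conditioning but dropped from the returned network, so coefficients
#' between glycoforms are corrected for, e.g., age and sex.
#'
#' @param x samples x glycoforms matrix, or a \code{SummarizedExperiment}
#'   (in which case \code{age} and \code{sex} from \code{colData} are used
#'   as confounders when present and \code{confounders} is NULL).
#' @param confounders optional numeric matrix/data.frame of per-sample
#'   confounder values.
#' @param alpha FDR level (default 0.01).
#' @param method p-value method, see \code{\link{pcorSignificance}}.
#' @return A \code{\linkS4class{CorrelationNetwork}} of kind
#'   \code{"partial"} with the shrinkage intensity recorded.
#' @export
partialCorrelation <- function(x, confounders = NULL, alpha = 0.01,
                               method = c("fisher", "empirical")) {
  method <- match.arg(method)
  if (is(x, "SummarizedExperiment") && is.null(confounders)) {
    cd <- SummarizedExperiment::colData(x)
    keep <- intersect(c("age", "sex"), colnames(cd))
    if (length(keep)) confounders <- as.data.frame(cd[, keep, drop = FALSE])
  }
  v <- glycoformValues(x)
  stopifnot(nrow(v) > 3, !anyNA(v))
  cf <- if (is.null(confounders)) NULL else as.matrix(confounders)
  if (!is.null(cf)) {
    stopifnot(nrow(cf) == nrow(v))
    if (is.null(colnames(cf)))
      colnames(cf) <- paste0("confounder", seq_len(ncol(cf)))
  }
  full <- cbind(v, cf)
  sp <- .shrinkPcor(full)
  keepIdx <- seq_len(ncol(v))
  pc <- sp$pcor[keepIdx, keepIdx, drop = FALSE]
  net <- new("CorrelationNetwork", estimates = pc,
             pvalues = matrix(NA_real_, ncol(v), ncol(v), dimnames = dimnames(pc)),
             qvalues = matrix(NA_real_, ncol(v), ncol(v), dimnames = dimnames(pc)),
             mask = matrix(FALSE, ncol(v), ncol(v), dimnames = dimnames(pc)),
             kind = "partial", lambda = sp$lambda,
             nSamples = nrow(v),
             confounders = if (is.null(cf)) character() else colnames(cf),
             alpha = alpha)
  pcorSignificance(net, alpha = alpha, method = method)
}

# two-sided p-values for partial correlations under the null density
# f0(r; kappa) proportional to (1 - r^2)^((kappa-3)/2)
.pcorNullP <- function(r, kappa) {
  r2 <- pmin(r^2, 1 - 1e-12)
  1 - stats::pbeta(r2, 1 / 2, (kappa - 1) / 2)
}

.fitNullKappa <- function(r) {
  r2 <- pmin(r^2, 1 - 1e-12)
  negll <- function(kappa) {
    -sum(lgamma(kappa / 2) - lgamma((kappa - 1) / 2) - 0.5 * log(pi) +
         (kappa - 3) / 2 * log1p(-r2))
  }
  stats::optimize(negll, c(3.5, 1e6))$minimum
}

#' Significance of partial correlations
#'
#' Default method \code{"fisher"}: Fisher z-transform with effective degrees
#' of freedom \code{n - k - 2 - c}, where \code{k} is the number of
#' conditioned glycoforms and \code{c} the number of confounders.
#' Method \code{"empirical"} fits the null distribution of partial
#' correlations, \code{f0(r) ~ (1 - r^2)^((kappa - 3)/2)}, to the observed
#' coefficients by maximum likelihood (assuming most are null) and derives
#' p-values from the fitted null; this mode mimics empirical-null fitting as
#' used by shrinkage GGM software and is intended for parity comparisons.
#' Benjamini-Hochberg q-values and the FDR mask are recomputed.
#'
#' @param network a partial \code{\linkS4class{CorrelationNetwork}}.
#' @param alpha FDR level.
#' @param method \code{"fisher"} (analytic) or \code{"empirical"}.
#' @return The network with \code{pvalues}, \code{qvalues} and \code{mask}
#'   filled in.
#' @export
pcorSignificance <- function(network, alpha = 0.01,
                             method = c("fisher", "empirical")) {
  stopifnot(is(network, "CorrelationNetwork"),
            network@kind == "partial")
  method <- match.arg(method)
  r <- network@estimates
  pGly <- nrow(r)
  n <- network@nSamples
  nConf <- length(network@confounders)
  if (method == "fisher") {
    df <- n - (pGly - 2) - 2 - nConf
    if (df < 1) stop("too few samples for the Fisher z test")
    z <- atanh(.clamp(r, -1 + 1e-15, 1 - 1e-15))
    p <- 2 * stats::pnorm(-abs(z) * sqrt(df))
  } else {
    off <- upper.tri(r)
    kappa <- .fitNullKappa(r[off])
    p <- .pcorNullP(r, kappa)
    p[lower.tri(p)] <- t(p)[lower.tri(p)]
  }
  diag(p) <- NA
  .newNetwork(r, p, "partial", n, alpha, lambda = network@lambda,
              confounders = network@confounders)
}

#' Gaussian graphical model from partial and Pearson networks
#'
#' The final GGM keeps a partial-correlation edge only if the corresponding
#' Pearson correlation is also significant; partial correlations whose
#' marginal correlation is not supported are masked out. Coefficients and
#' p-values are those of the partial network.
#'
#' @param pearson a \code{"pearson"} \code{\linkS4class{CorrelationNetwork}}.
#' @param partial a \code{"partial"} \code{\linkS4class{CorrelationNetwork}}
#'   over the same glycoforms.
#' @return A \code{\linkS4class{CorrelationNetwork}} of kind \code{"ggm"}.
#' @export
buildGGM <- function(pearson, partial) {
  stopifnot(is(pearson, "CorrelationNetwork"),
            is(partial, "CorrelationNetwork"),
            pearson@kind == "pearson", partial@kind == "partial")
  if (!identical(nodeLabels(pearson), nodeLabels(partial)))
    stop("networks are defined over different glycoform sets")
  out <- partial
  out@kind <- "ggm"
  out@mask <- partial@mask & pearson@mask
  validObject(out)
  out
}

#' Consensus of cohort networks
#'
#' Combines significance masks of two or more networks over a shared
#' glycoform universe into per-edge replication counts. An edge is
#' replicated when significant in every cohort.
#'
#' @param networks list of \code{\linkS4class{CorrelationNetwork}} objects.
#' @return A \code{\linkS4class{ConsensusNetwork}}.
#' @export
consensusNetwork <- function(networks) {
  stopifnot(is.list(networks), length(networks) >= 2)
  labs <- nodeLabels(networks[[1L]])
  for (net in networks)
    if (!identical(nodeLabels(net), labs))
      stop("networks are defined over different glycoform sets")
  counts <- Reduce(`+`, lapply(networks, function(net)
    1L * significanceMask(net)))
  new("ConsensusNetwork", counts = counts,
      nCohorts = length(networks))
}

#' Edge table of a network
#'
#' @param network a \code{\linkS4class{CorrelationNetwork}}.
#' @param significantOnly keep only edges in the significance mask.
#' @return data.frame with columns \code{node1}, \code{node2},
#'   \code{coefficient}, \code{p}, \code{q}, \code{significant}.
#' @export
networkEdges <- function(network, significantOnly = FALSE) {
  stopifnot(is(network, "CorrelationNetwork"))
  labs <- nodeLabels(network)
  idx <- which(upper.tri(network@estimates), arr.ind = TRUE)
  out <- data.frame(node1 = labs[idx[, 1L]], node2 = labs[idx[, 2L]],
                    coefficient = network@estimates[idx],
                    p = network@pvalues[idx], q = network@qvalues[idx],
                    significant = network@mask[idx],
                    stringsAsFactors = FALSE)
  if (significantOnly) out <- out[out$significant, ]
  rownames(out) <- NULL
  out
}
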