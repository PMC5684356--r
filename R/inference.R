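# Pathway-distance classification, Fisher overlap scoring, bootstrap model
# fitting and parsimony selection.

# two-sided 2x2 Fisher exact p (conditional on margins), vectorized over the
# hypergeometric support; equals stats::fisher.test(x)$p.value
.fisher2x2 <- function(a, b, c, d) {
  m <- a + b
  n <- c + d
  k <- a + c
  lo <- max(0L, k - n)
  hi <- min(k, m)
  support <- lo:hi
  dens <- stats::dhyper(support, m, n, k)
  pObs <- dens[support == a]
  sum(dens[dens <= pObs * (1 + 1e-7)])
}

# pair scaffold over a glycoform label set: indices, subclasses, structures
.pairScaffold <- function(labels) {
  info <- parseGlycoform(labels)
  idx <- which(upper.tri(diag(length(labels))), arr.ind = TRUE)
  i <- idx[, 1L]; j <- idx[, 2L]
  sameSub <- info$subclass[i] == info$subclass[j]
  sameStr <- info$structure[i] == info$structure[j]
  list(i = i, j = j, labels = labels, info = info,
       within = sameSub,
       cross = !sameSub & sameStr,      # "X" pairs
       excluded = !sameSub & !sameStr)
}

.pairDistances <- function(scaffold, model) {
  dm <- distanceMatrix(model)
  str1 <- scaffold$info$structure[scaffold$i]
  str2 <- scaffold$info$structure[scaffold$j]
  miss <- setdiff(unique(c(str1, str2)), rownames(dm))
  if (length(miss))
    stop("structure(s) not in the model panel: ",
         paste(miss, collapse = ", "))
  d <- dm[cbind(str1, str2)]
  d[!scaffold$within] <- NA_real_
  d
}

#' Classify glycoform pairs by pathway distance
#'
#' Pairs within an IgG subclass are assigned the pathway distance of their
#' structures on the model's reaction graph. Cross-subclass pairs of the
#' same structure are labeled \code{"X"} (uninterpretable in terms of
#' enzymatic reactions, as the glycans are bound to different proteins);
#' all other cross-subclass pairs are \code{"excluded"}.
#'
#' @param network a \code{\linkS4class{CorrelationNetwork}} whose node
#'   labels parse as glycoforms.
#' @param model a \code{\linkS4class{GlycanPathway}}.
#' @return data.frame with one row per unordered pair: \code{node1},
#'   \code{node2}, \code{category} (\code{"X"}, \code{"excluded"}, or the
#'   distance as character), \code{distance} (numeric, NA for
#'   cross-subclass), \code{significant} (network mask) and
#'   \code{sign} of the coefficient.
#' @export
classifyPairs <- function(network, model) {
  stopifnot(is(network, "CorrelationNetwork"), is(model, "GlycanPathway"))
  sc <- .pairScaffold(nodeLabels(network))
  d <- .pairDistances(sc, model)
  category <- ifelse(sc$cross, "X",
                     ifelse(sc$excluded, "excluded", as.character(d)))
  idx <- cbind(sc$i, sc$j)
  data.frame(node1 = sc$labels[sc$i], node2 = sc$labels[sc$j],
             category = category, distance = d,
             significant = significanceMask(network)[idx],
             sign = sign(estimates(network)[idx]),
             stringsAsFactors = FALSE)
}

#' Fisher exact test of network-pathway overlap
#'
#' Tests whether significant edges accumulate at pathway distance 1. The
#' 2x2 contingency table cross-classifies the within-subclass pairs
#' (\code{"X"} and excluded pairs are omitted) by distance (\code{== 1} vs
#' \code{> 1}) and significance; the p-value is the two-sided Fisher exact
#' test.
#'
#' @param classification output of \code{\link{classifyPairs}}.
#' @param includeNegative count significant edges with negative
#'   coefficients as significant (default TRUE; set FALSE to restrict the
#'   table to positive associations, whose biochemical interpretation is
#'   cleaner).
#' @return list with \code{table} (2x2 matrix) and \code{p}.
#' @export
fisherOverlap <- function(classification, includeNegative = TRUE) {
  cls <- classification[!is.na(classification$distance), ]
  if (!includeNegative) cls$significant <- cls$significant & cls$sign > 0
  d1 <- cls$distance == 1
  if (!any(d1) || all(d1))
    stop("empty row margin: need pairs both at distance 1 and at distance > 1")
  tab <- matrix(c(sum(d1 & cls$significant), sum(d1 & !cls$significant),
                  sum(!d1 & cls$significant), sum(!d1 & !cls$significant)),
                nrow = 2L, byrow = TRUE,
                dimnames = list(c("distance==1", "distance>1"),
                                c("significant", "not significant")))
  list(table = tab, p = .fisher2x2(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]))
}

# significance vector (upper-tri pair order) of the GGM built from a value
# matrix: partial mask AND pearson mask
.ggmSignificance <- function(values, confounders, alpha, method = "fisher",
                             strict = FALSE) {
  fp <- .fastPearson(values, strict = strict)
  qPearson <- stats::p.adjust(fp$p[upper.tri(fp$p)], "BH")
  full <- cbind(values, confounders)
  sp <- .shrinkPcor(full)
  keep <- seq_len(ncol(values))
  pc <- sp$pcor[keep, keep]
  nConf <- if (is.null(confounders)) 0L else ncol(confounders)
  if (method == "fisher") {
    df <- nrow(values) - (ncol(values) - 2) - 2 - nConf
    z <- atanh(.clamp(pc, -1 + 1e-15, 1 - 1e-15))
    pPartial <- 2 * stats::pnorm(-abs(z) * sqrt(df))
  } else {
    off <- upper.tri(pc)
    kappa <- .fitNullKappa(pc[off])
    pPartial <- .pcorNullP(pc, kappa)
  }
  qPartial <- stats::p.adjust(pPartial[upper.tri(pPartial)], "BH")
  sig <- !is.na(qPearson) & qPearson <= alpha &
         !is.na(qPartial) & qPartial <= alpha
  sig
}

#' Fit pathway models by bootstrap Fisher scoring
#'
#' Scores every candidate pathway model by the Fisher exact p-value of its
#' overlap with the data-driven GGM (lower p = better overlap; used here as
#' a variance-normalized effect size). Robustness is assessed by bootstrap:
#' each resample redraws samples with replacement and re-runs the entire
#' pipeline (Pearson network, shrinkage partial correlations, FDR masks,
#' pair classification, Fisher test), giving a percentile 95\% confidence
#' interval per model. A model is flagged \code{better} than the base
#' (known) pathway when its point p-value is lower and the confidence
#' intervals do not overlap.
#'
#' @param x preprocessed (log-scale, complete) samples x glycoforms matrix,
#'   or a \code{SummarizedExperiment} whose abundance assay is log-scale.
#' @param models named list of \code{\linkS4class{GlycanPathway}} models,
#'   including the base model (empty rule set); see
#'   \code{\link{enumerateModels}}.
#' @param confounders optional per-sample confounder matrix (for a
#'   \code{SummarizedExperiment}, age/sex are used automatically).
#' @param alpha FDR level for both networks (default 0.01).
#' @param B number of bootstrap resamples (default 10000).
#' @param seed optional RNG seed.
#' @param method partial-correlation p-value method
#'   (\code{\link{pcorSignificance}}).
#' @return data.frame with one row per model: \code{model} (rule-set
#'   label), \code{nRules}, \code{p} (full-data), \code{lower},
#'   \code{upper} (bootstrap 95\% CI), \code{better}. The bootstrap
#'   p-value matrix is attached as \code{attr(, "bootstrap")}.
#' @export
fitModels <- function(x, models, confounders = NULL, alpha = 0.01,
                      B = 10000, seed = NULL,
                      method = c("fisher", "empirical")) {
  method <- match.arg(method)
  if (is(x, "SummarizedExperiment") && is.null(confounders)) {
    cd <- SummarizedExperiment::colData(x)
    keep <- intersect(c("age", "sex"), colnames(cd))
    if (length(keep)) confounders <- as.matrix(as.data.frame(cd[, keep, drop = FALSE]))
  }
  values <- glycoformValues(x)
  cf <- if (is.null(confounders)) NULL else as.matrix(confounders)
  stopifnot(is.list(models), length(models) >= 2, B >= 2)
  baseIdx <- which(vapply(models, function(m) length(m@ruleIds) == 0L, TRUE))
  if (!length(baseIdx))
    stop("the base (known) pathway model must be among the fitted models")
  sc <- .pairScaffold(colnames(values))
  valid <- sc$within
  d1 <- lapply(models, function(m) {
    d <- .pairDistances(sc, m)
    d[valid] == 1
  })
  fisherFromSig <- function(sig) {
    sigv <- sig[valid]
    vapply(d1, function(dd)
      .fisher2x2(sum(dd & sigv), sum(dd & !sigv),
                 sum(!dd & sigv), sum(!dd & !sigv)), 0)
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  pFull <- fisherFromSig(.ggmSignificance(values, cf, alpha, method,
                                          strict = TRUE))
  n <- nrow(values)
  boot <- matrix(NA_real_, B, length(models),
                 dimnames = list(NULL, names(models)))
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    sig <- .ggmSignificance(values[idx, , drop = FALSE],
                            if (is.null(cf)) NULL else cf[idx, , drop = FALSE],
                            alpha, method)
    boot[b, ] <- fisherFromSig(sig)
  }
  ci <- apply(boot, 2L, stats::quantile, probs = c(0.025, 0.975))
  fits <- data.frame(
    model = names(models),
    nRules = vapply(models, function(m) length(m@ruleIds), 0L),
    p = pFull, lower = ci[1L, ], upper = ci[2L, ],
    stringsAsFactors = FALSE, row.names = NULL)
  kn <- fits[baseIdx[1L], ]
  fits$better <- fits$p < kn$p & fits$upper < kn$lower
  fits$better[baseIdx[1L]] <- FALSE
  attr(fits, "bootstrap") <- boot
  fits
}

#' Parsimony selection among fitted pathway models
#'
#' Among models that fit significantly better than the base pathway (lower
#' point p-value with non-overlapping bootstrap confidence intervals), the
#' one with the fewest rules is chosen; ties between equally simple models
#' are broken by the lowest point p-value. If no model is better, the base
#' pathway is returned.
#'
#' @param fits output of \code{\link{fitModels}}.
#' @return single-row data.frame: the selected model's fit.
#' @export
selectModel <- function(fits) {
  base <- fits[fits$nRules == 0L, ]
  if (!nrow(base))
    stop("the base (known) pathway is absent from the fits")
  cand <- fits[fits$better, ]
  if (!nrow(cand)) return(base[1L, ])
  cand <- cand[cand$nRules == min(cand$nRules), ]
  cand[order(cand$p)[1L], ]
}

#' Replication Fisher test on a consensus network
#'
#' Considers edges significant in at least one cohort and cross-classifies
#' them by replication status (significant in all cohorts) and pathway
#' distance (1 vs > 1); cross-subclass pairs are omitted as in
#' \code{\link{classifyPairs}}. A low p-value indicates that replicated
#' edges preferentially sit on single enzymatic reactions.
#'
#' @param consensus a \code{\linkS4class{ConsensusNetwork}}.
#' @param model a \code{\linkS4class{GlycanPathway}}.
#' @return list with \code{table} (2x2) and \code{p}.
#' @export
replicationFisher <- function(consensus, model) {
  stopifnot(is(consensus, "ConsensusNetwork"), is(model, "GlycanPathway"))
  sc <- .pairScaffold(nodeLabels(consensus))
  d <- .pairDistances(sc, model)
  counts <- replicationCounts(consensus)[cbind(sc$i, sc$j)]
  keep <- counts >= 1L & !is.na(d)
  if (!any(keep)) stop("no within-subclass edges significant in any cohort")
  repl <- counts[keep] == consensus@nCohorts
  d1 <- d[keep] == 1
  tab <- matrix(c(sum(repl & d1), sum(repl & !d1),
                  sum(!repl & d1), sum(!repl & !d1)),
                nrow = 2L, byrow = TRUE,
                dimnames = list(c("replicated", "not replicated"),
                                c("distance==1", "distance>1")))
  list(table = tab, p = .fisher2x2(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]))
}
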