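#' @import methods
NULL

#' GlycanPathway: a pathway model over a glycan structure panel
#'
#' A pathway model is a set of single-sugar-addition reactions over a fixed
#' panel of glycan structures. The shipped fixture encodes the known human
#' IgG Fc glycosylation pathway (see \code{\link{knownPathway}}); extended
#' models add the member reactions of one or more substrate-specificity
#' rules (see \code{\link{extendModel}}).
#'
#' @slot panel data.frame with columns \code{name}, \code{gal}, \code{fuc},
#'   \code{bis}, \code{sia}, \code{measured}. Unmeasured structures are part
#'   of the reaction graph but carry no data.
#' @slot reactions data.frame with columns \code{substrate}, \code{product},
#'   \code{enzyme}; every row is a valid single addition.
#' @slot rules named list of rule definitions (id, enzyme, description,
#'   predicate feature bounds).
#' @slot ruleIds character vector of rule ids included in this model beyond
#'   the base pathway (empty for the known pathway).
#' @slot subclasses named list mapping IgG subclass names to the structure
#'   names measured for that subclass.
#' @exportClass GlycanPathway
setClass("GlycanPathway",
  representation(panel = "data.frame", reactions = "data.frame",
                 rules = "list", ruleIds = "character",
                 subclasses = "list"))

setValidity("GlycanPathway", function(object) {
  p <- object@panel
  r <- object@reactions
  msg <- character()
  need <- c("name", "gal", "fuc", "bis", "sia", "measured")
  if (!all(need %in% names(p)))
    return("panel must have columns name, gal, fuc, bis, sia, measured")
  if (anyDuplicated(p$name)) msg <- c(msg, "duplicated panel structures")
  if (any(p$sia > p$gal)) msg <- c(msg, "panel violates sia <= gal")
  if (nrow(r)) {
    if (!all(c(r$substrate, r$product) %in% p$name))
      msg <- c(msg, "reaction endpoints outside the panel")
    else {
      enz <- singleAddition(r$substrate, r$product)
      bad <- is.na(enz) | enz != r$enzyme
      if (any(bad))
        msg <- c(msg, paste0("reaction(s) not a single matching addition: ",
          paste(r$substrate[bad], "->", r$product[bad], collapse = ", ")))
    }
    if (anyDuplicated(paste(r$substrate, r$product)))
      msg <- c(msg, "duplicated reactions")
  }
  for (sc in names(object@subclasses))
    if (!all(object@subclasses[[sc]] %in% p$name))
      msg <- c(msg, paste0("subclass ", sc, " lists unknown structures"))
  if (length(msg)) msg else TRUE
})

setMethod("show", "GlycanPathway", function(object) {
  cat("GlycanPathway model\n")
  cat("  panel:    ", nrow(object@panel), " structures (",
      sum(object@panel$measured), " measured)\n", sep = "")
  cat("  reactions:", nrow(object@reactions), "\n")
  cat("  rules:    ", if (length(object@ruleIds))
        paste(object@ruleIds, collapse = "+") else "(base pathway)", "\n")
  cat("  subclasses:", paste(sprintf("%s[%d]", names(object@subclasses),
      lengths(object@subclasses)), collapse = " "), "\n")
})

#' CorrelationNetwork: coefficients, p-values and significance mask
#'
#' Holds a symmetric coefficient matrix over glycoforms together with
#' two-sided p-values, Benjamini-Hochberg q-values and the significance mask
#' at the chosen false discovery rate. \code{kind} distinguishes Pearson
#' networks, shrinkage partial-correlation networks and the masked Gaussian
#' graphical model (\code{"ggm"}).
#'
#' @slot estimates,pvalues,qvalues,mask symmetric glycoform x glycoform
#'   matrices; \code{mask} is logical.
#' @slot kind one of \code{"pearson"}, \code{"partial"}, \code{"ggm"}.
#' @slot lambda shrinkage intensity (partial networks; \code{NA} otherwise).
#' @slot nSamples number of samples the network was estimated from.
#' @slot confounders names of confounder variables conditioned on.
#' @slot alpha FDR level of the significance mask.
#' @exportClass CorrelationNetwork
setClass("CorrelationNetwork",
  representation(estimates = "matrix", pvalues = "matrix",
                 qvalues = "matrix", mask = "matrix", kind = "character",
                 lambda = "numeric", nSamples = "integer",
                 confounders = "character", alpha = "numeric"))

setValidity("CorrelationNetwork", function(object) {
  e <- object@estimates
  msg <- character()
  if (nrow(e) != ncol(e)) msg <- c(msg, "estimates must be square")
  if (is.null(rownames(e))) msg <- c(msg, "estimates must carry labels")
  if (max(abs(e), na.rm = TRUE) > 1 + 1e-8)
    msg <- c(msg, "coefficients outside [-1, 1]")
  if (any(abs(e - t(e)) > 1e-8, na.rm = TRUE))
    msg <- c(msg, "estimates not symmetric")
  if (any(abs(diag(e) - 1) > 1e-8))
    msg <- c(msg, "diagonal of estimates must be 1")
  for (s in c("pvalues", "qvalues", "mask"))
    if (!identical(dim(slot(object, s)), dim(e)))
      msg <- c(msg, paste(s, "dimensions differ from estimates"))
  if (!object@kind %in% c("pearson", "partial", "ggm"))
    msg <- c(msg, "kind must be pearson, partial or ggm")
  if (any(object@mask & !(object@qvalues <= object@alpha), na.rm = TRUE))
    msg <- c(msg, "mask must be contained in {q <= alpha}")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CorrelationNetwork", function(object) {
  ns <- sum(object@mask[upper.tri(object@mask)], na.rm = TRUE)
  cat(sprintf("CorrelationNetwork (%s)\n", object@kind))
  cat("  nodes:      ", nrow(object@estimates), "\n")
  cat("  n samples:  ", object@nSamples, "\n")
  cat(sprintf("  significant: %d edges at FDR %.3g\n", ns, object@alpha))
  if (!is.na(object@lambda))
    cat(sprintf("  shrinkage lambda*: %.4f\n", object@lambda))
  if (length(object@confounders))
    cat("  confounders:", paste(object@confounders, collapse = ", "), "\n")
})

#' ConsensusNetwork: per-edge replication counts across cohorts
#'
#' @slot counts symmetric matrix of the number of cohorts in which each edge
#'   was significant.
#' @slot nCohorts number of cohort networks combined.
#' @exportClass ConsensusNetwork
setClass("ConsensusNetwork",
  representation(counts = "matrix", nCohorts = "integer"))

setValidity("ConsensusNetwork", function(object) {
  cm <- object@counts
  if (nrow(cm) != ncol(cm)) return("counts must be square")
  if (any(cm < 0) || any(cm > object@nCohorts))
    return("counts outside [0, nCohorts]")
  TRUE
})

setMethod("show", "ConsensusNetwork", function(object) {
  ut <- upper.tri(object@counts)
  cat("ConsensusNetwork over", object@nCohorts, "cohorts\n")
  cat("  edges significant in >=1 cohort:", sum(object@counts[ut] >= 1), "\n")
  cat("  replicated in all cohorts:      ",
      sum(object@counts[ut] == object@nCohorts), "\n")
})
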