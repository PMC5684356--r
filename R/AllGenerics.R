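#' Accessors for network and pathway objects
#'
#' @param object a \code{\linkS4class{CorrelationNetwork}},
#'   \code{\linkS4class{ConsensusNetwork}} or
#'   \code{\linkS4class{GlycanPathway}}.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("estimates", function(object) standardGeneric("estimates"))
#' @rdname accessors
#' @export
setGeneric("pvalues", function(object) standardGeneric("pvalues"))
#' @rdname accessors
#' @export
setGeneric("qvalues", function(object) standardGeneric("qvalues"))
#' @rdname accessors
#' @export
setGeneric("significanceMask", function(object)
  standardGeneric("significanceMask"))
#' @rdname accessors
#' @export
setGeneric("networkKind", function(object) standardGeneric("networkKind"))
#' @rdname accessors
#' @export
setGeneric("shrinkageLambda", function(object)
  standardGeneric("shrinkageLambda"))
#' @rdname accessors
#' @export
setGeneric("nodeLabels", function(object) standardGeneric("nodeLabels"))
#' @rdname accessors
#' @export
setGeneric("reactions", function(object) standardGeneric("reactions"))
#' @rdname accessors
#' @export
setGeneric("panelStructures", function(object)
  standardGeneric("panelStructures"))
#' @rdname accessors
#' @export
setGeneric("pathwayRules", function(object) standardGeneric("pathwayRules"))
#' @rdname accessors
#' @export
setGeneric("ruleIds", function(object) standardGeneric("ruleIds"))
#' @rdname accessors
#' @export
setGeneric("subclassPanels", function(object)
  standardGeneric("subclassPanels"))
#' @rdname accessors
#' @export
setGeneric("replicationCounts", function(object)
  standardGeneric("replicationCounts"))

#' @rdname accessors
#' @export
setMethod("estimates", "CorrelationNetwork", function(object)
  object@estimates)
#' @rdname accessors
#' @export
setMethod("pvalues", "CorrelationNetwork", function(object) object@pvalues)
#' @rdname accessors
#' @export
setMethod("qvalues", "CorrelationNetwork", function(object) object@qvalues)
#' @rdname accessors
#' @export
setMethod("significanceMask", "CorrelationNetwork", function(object)
  object@mask)
#' @rdname accessors
#' @export
setMethod("networkKind", "CorrelationNetwork", function(object) object@kind)
#' @rdname accessors
#' @export
setMethod("shrinkageLambda", "CorrelationNetwork", function(object)
  object@lambda)
#' @rdname accessors
#' @export
setMethod("nodeLabels", "CorrelationNetwork", function(object)
  rownames(object@estimates))
#' @rdname accessors
#' @export
setMethod("nodeLabels", "ConsensusNetwork", function(object)
  rownames(object@counts))
#' @rdname accessors
#' @export
setMethod("replicationCounts", "ConsensusNetwork", function(object)
  object@counts)
#' @rdname accessors
#' @export
setMethod("reactions", "GlycanPathway", function(object) object@reactions)
#' @rdname accessors
#' @export
setMethod("panelStructures", "GlycanPathway", function(object) object@panel)
#' @rdname accessors
#' @export
setMethod("pathwayRules", "GlycanPathway", function(object) object@rules)
#' @rdname accessors
#' @export
setMethod("ruleIds", "GlycanPathway", function(object) object@ruleIds)
#' @rdname accessors
#' @export
setMethod("subclassPanels", "GlycanPathway", function(object)
  object@subclasses)
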