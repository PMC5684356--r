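#' Load a pathway model from a JSON definition file
#'
#' The definition file lists the structure panel (with measurement flags),
#' the reaction edges \code{[substrate, product, enzyme]}, the
#' substrate-specificity rules, and the per-subclass glycoform panels. Every
#' reaction is validated as a single sugar addition catalysed by the stated
#' enzyme.
#'
#' @param file path to a JSON pathway definition.
#' @return A validated \code{\linkS4class{GlycanPathway}}.
#' @seealso \code{\link{knownPathway}} for the shipped IgG pathway.
#' @export
loadPathway <- function(file) {
  def <- jsonlite::read_json(file, simplifyVector = FALSE)
  if (is.null(def$panel) || is.null(def$reactions))
    stop("pathway definition must contain 'panel' and 'reactions'")
  panel <- parseGlycanName(vapply(def$panel, `[[`, "", "name"))
  panel$measured <- vapply(def$panel, function(p)
    is.null(p$measured) || isTRUE(p$measured), TRUE)
  rx <- data.frame(
    substrate = vapply(def$reactions, `[[`, "", 1L),
    product = vapply(def$reactions, `[[`, "", 2L),
    enzyme = vapply(def$reactions, `[[`, "", 3L),
    rule = NA_character_,
    stringsAsFactors = FALSE)
  rules <- lapply(def$rules, function(r)
    list(id = r$id, enzyme = r$enzyme, description = r$description,
         predicate = r$predicate))
  names(rules) <- vapply(rules, `[[`, "", "id")
  subclasses <- lapply(def$subclasses, function(v)
    vapply(v, `[[`, "", 1L))
  model <- new("GlycanPathway", panel = panel, reactions = rx,
               rules = rules, ruleIds = character(), subclasses = subclasses)
  validObject(model)
  model
}

#' The known IgG Fc glycosylation pathway
#'
#' Loads the shipped transcription of the canonical IgG glycosylation
#' pathway: 22 biantennary complex-type structures (20 of them measured by
#' the LC-ESI-MS glycopeptide panel) and 21 single-addition reactions
#' catalysed by FUT8 (core fucosylation of the agalactosylated core),
#' MGAT3 (bisection of agalactosylated structures), B4GalT1 (galactosylation
#' of asialylated structures) and ST6Gal1 (sialylation of galactosylated
#' structures), together with the six candidate-reaction rules F1-F3, G1,
#' N1, N2.
#'
#' @return A \code{\linkS4class{GlycanPathway}}.
#' @examples
#' kp <- knownPathway()
#' pathwayDistance(kp, "G0", "G2S1")  # 3 enzymatic steps
#' @export
knownPathway <- function() {
  loadPathway(system.file("extdata", "igg_pathway.json",
                          package = "glyconet", mustWork = TRUE))
}

.reactionKey <- function(rx) paste(rx$substrate, rx$product, sep = ">")

#' Candidate reactions not present in a pathway model
#'
#' Enumerates all ordered panel structure pairs that differ by exactly one
#' sugar addition and are not reactions of the model. These are the
#' candidate novel reactions from which rules are built.
#'
#' @param model a \code{\linkS4class{GlycanPathway}}.
#' @return data.frame with columns \code{substrate}, \code{product},
#'   \code{enzyme}.
#' @export
candidateReactions <- function(model) {
  stopifnot(is(model, "GlycanPathway"))
  p <- model@panel
  idx <- expand.grid(i = seq_len(nrow(p)), j = seq_len(nrow(p)))
  idx <- idx[idx$i != idx$j, ]
  enz <- singleAddition(p$name[idx$i], p$name[idx$j])
  keep <- !is.na(enz)
  out <- data.frame(substrate = p$name[idx$i][keep],
                    product = p$name[idx$j][keep],
                    enzyme = enz[keep], stringsAsFactors = FALSE)
  out <- out[!(.reactionKey(out) %in% .reactionKey(model@reactions)), ]
  rownames(out) <- NULL
  out
}

.predicateHolds <- function(predicate, s) {
  ok <- rep(TRUE, nrow(s))
  if (!is.null(predicate$gal_min)) ok <- ok & s$gal >= predicate$gal_min
  if (!is.null(predicate$gal_max)) ok <- ok & s$gal <= predicate$gal_max
  if (!is.null(predicate$sia_min)) ok <- ok & s$sia >= predicate$sia_min
  if (!is.null(predicate$sia_max)) ok <- ok & s$sia <= predicate$sia_max
  if (!is.null(predicate$fuc)) ok <- ok & s$fuc == predicate$fuc
  if (!is.null(predicate$bis)) ok <- ok & s$bis == predicate$bis
  ok
}

#' Member reactions of a substrate-specificity rule
#'
#' A rule groups candidate reactions sharing an enzyme and a feature
#' predicate on the substrate (e.g. G1 = galactosylation of sialylated
#' glycans). Members are evaluated against the candidate set of the model's
#' base reactions, so they are, by construction, not part of the model.
#'
#' @param model a \code{\linkS4class{GlycanPathway}}.
#' @param rule a rule id (one of the ids carried by the model).
#' @return data.frame of member reactions.
#' @export
ruleMembers <- function(model, rule) {
  stopifnot(is(model, "GlycanPathway"))
  if (!rule %in% names(model@rules))
    stop("unknown rule id: ", rule, " (known: ",
         paste(names(model@rules), collapse = ", "), ")")
  r <- model@rules[[rule]]
  cand <- candidateReactions(model)
  sub <- model@panel[match(cand$substrate, model@panel$name), ]
  out <- cand[cand$enzyme == r$enzyme & .predicateHolds(r$predicate, sub), ]
  if (nrow(out)) out$rule <- rule
  else out$rule <- character()
  rownames(out) <- NULL
  out
}

#' Extend a pathway model with rule reactions
#'
#' Adds the member reactions of the given rules to the model. Extension is
#' idempotent and monotone: the base reactions are always retained.
#'
#' @param model a \code{\linkS4class{GlycanPathway}}.
#' @param rules character vector of rule ids (may be empty).
#' @return An extended \code{\linkS4class{GlycanPathway}} whose
#'   \code{ruleIds} records the applied rules.
#' @examples
#' kp <- knownPathway()
#' ext <- extendModel(kp, c("G1", "N2"))
#' nrow(reactions(ext)) - nrow(reactions(kp))  # 8 new reactions
#' @export
extendModel <- function(model, rules = character()) {
  stopifnot(is(model, "GlycanPathway"))
  rules <- unique(as.character(rules))
  unknown <- setdiff(rules, names(model@rules))
  if (length(unknown))
    stop("unknown rule id(s): ", paste(unknown, collapse = ", "))
  add <- lapply(rules, function(r) ruleMembers(model, r))
  rx <- rbind(model@reactions, do.call(rbind, add))
  rx <- rx[!duplicated(.reactionKey(rx)), ]
  rownames(rx) <- NULL
  out <- model
  out@reactions <- rx
  out@ruleIds <- sort(unique(c(model@ruleIds, rules)))
  validObject(out)
  out
}

#' Enumerate all rule-combination pathway models
#'
#' Builds the power set of the given rules applied to the base model: with
#' the six IgG rules this yields all 64 (2^6) pathway models, including the
#' unextended base pathway.
#'
#' @param model the base \code{\linkS4class{GlycanPathway}}.
#' @param rules character vector of rule ids (default: all rules carried by
#'   the model).
#' @return Named list of \code{\linkS4class{GlycanPathway}} objects; names
#'   are rule ids concatenated (\code{""} for the base model).
#' @export
enumerateModels <- function(model, rules = names(model@rules)) {
  stopifnot(is(model, "GlycanPathway"))
  k <- length(rules)
  subsets <- lapply(seq_len(2^k) - 1L, function(m)
    rules[bitwAnd(m, 2^(seq_len(k) - 1L)) > 0])
  models <- lapply(subsets, function(rs) extendModel(model, rs))
  names(models) <- vapply(subsets, paste, "", collapse = "")
  models
}

.pathwayGraph <- function(model) {
  igraph::graph_from_data_frame(model@reactions[, c("substrate", "product")],
                                directed = FALSE,
                                vertices = model@panel$name)
}

#' Pathway distance between glycan structures
#'
#' The pathway distance between two structures is the minimum number of
#' enzymatic steps separating them on the model's reaction graph. Reactions
#' are treated as undirected edges, so the distance is also defined for
#' structure pairs that do not lie on a common synthesis route (e.g.
#' siblings such as G0F and G0N). The distance is 0 only for a structure
#' and itself, and infinite for disconnected pairs.
#'
#' @param model a \code{\linkS4class{GlycanPathway}}.
#' @param a,b structure names; both must be in the model panel.
#' @return numeric: the number of steps (possibly \code{Inf}).
#' @examples
#' pathwayDistance(knownPathway(), "G0", "G2S1")  # 3
#' @export
pathwayDistance <- function(model, a, b) {
  stopifnot(is(model, "GlycanPathway"))
  miss <- setdiff(c(a, b), model@panel$name)
  if (length(miss))
    stop("structure(s) not in panel: ", paste(miss, collapse = ", "))
  d <- igraph::distances(.pathwayGraph(model), v = a, to = b)
  as.numeric(d)
}

#' All pairwise pathway distances
#'
#' @param model a \code{\linkS4class{GlycanPathway}}.
#' @return symmetric numeric matrix of distances over the panel.
#' @export
distanceMatrix <- function(model) {
  stopifnot(is(model, "GlycanPathway"))
  igraph::distances(.pathwayGraph(model))
}
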