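# Readers and writers for the plain-text interchange formats.

#' Read a glycomics abundance table
#'
#' Expects a CSV/TSV with a header row of glycoform labels
#' (\code{"<subclass>_<structure>"}) and the sample id in the first column.
#' An optional covariates table (columns \code{id}, \code{age}, \code{sex})
#' is matched by sample id.
#'
#' @param file abundance table path.
#' @param covariates optional covariates table path.
#' @param sep field separator (default: inferred from the extension,
#'   \code{"\t"} for .tsv, \code{","} otherwise).
#' @return A \code{SummarizedExperiment}
#'   (see \code{\link{glycomicsExperiment}}).
#' @export
readGlycomicsTable <- function(file, covariates = NULL, sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.tsv$", file)) "\t" else ","
  tab <- utils::read.table(file, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE)
  values <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(values) <- as.character(tab[[1L]])
  age <- sex <- NULL
  if (!is.null(covariates)) {
    cv <- utils::read.table(covariates, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE)
    m <- match(rownames(values), as.character(cv$id))
    if (anyNA(m)) stop("covariates missing for sample(s): ",
                       paste(rownames(values)[is.na(m)], collapse = ", "))
    age <- cv$age[m]
    sex <- cv$sex[m]
  }
  glycomicsExperiment(values, age = age, sex = sex)
}

#' Read a kinship matrix
#'
#' Accepts either a square matrix (first column and header = sample ids) or
#' a long-format triplet table with columns \code{id1}, \code{id2},
#' \code{kinship} (unlisted pairs are 0).
#'
#' @param file path to a CSV file.
#' @return symmetric kinship matrix.
#' @export
readKinshipTable <- function(file) {
  tab <- utils::read.table(file, header = TRUE, sep = ",",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) == 3L && all(c("id1", "id2", "kinship") %in% colnames(tab))) {
    ids <- sort(unique(c(as.character(tab$id1), as.character(tab$id2))))
    k <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    k[cbind(as.character(tab$id1), as.character(tab$id2))] <- tab$kinship
    k[cbind(as.character(tab$id2), as.character(tab$id1))] <- tab$kinship
    return(k)
  }
  ids <- as.character(tab[[1L]])
  k <- as.matrix(tab[, -1L, drop = FALSE])
  dimnames(k) <- list(ids, colnames(k))
  k
}

#' Write a network as a tab-separated edge list
#'
#' Columns: node1, node2, coefficient, p, q, significant.
#'
#' @param network a \code{\linkS4class{CorrelationNetwork}}.
#' @param file output path.
#' @param significantOnly write only significant edges (default FALSE).
#' @export
writeNetworkTSV <- function(network, file, significantOnly = FALSE) {
  utils::write.table(networkEdges(network, significantOnly), file,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read an edge-list TSV written by \code{writeNetworkTSV}
#'
#' @param file path.
#' @return data.frame of edges.
#' @export
readNetworkTSV <- function(file) {
  utils::read.table(file, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

.networkGraph <- function(network) {
  ed <- networkEdges(network, significantOnly = TRUE)
  igraph::graph_from_data_frame(ed, directed = FALSE,
                                vertices = nodeLabels(network))
}

#' Write a network in GraphML format
#'
#' Significant edges only, with the coefficient as an edge attribute.
#'
#' @param network a \code{\linkS4class{CorrelationNetwork}}.
#' @param file output path.
#' @export
writeNetworkGraphML <- function(network, file) {
  igraph::write_graph(.networkGraph(network), file, format = "graphml")
  invisible(file)
}

#' Write a pathway model as a tab-separated reaction list
#'
#' @param model a \code{\linkS4class{GlycanPathway}}.
#' @param file output path.
#' @export
writePathwayTSV <- function(model, file) {
  utils::write.table(reactions(model), file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
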