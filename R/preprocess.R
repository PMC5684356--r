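#' Assemble a glycomics experiment
#'
#' Wraps a samples x glycoforms abundance table and per-sample covariates in
#' a \code{\link[SummarizedExperiment]{SummarizedExperiment}} (glycoforms as
#' rows, samples as columns, assay \code{"abundance"}). Column labels of
#' \code{values} must parse as glycoforms (\code{"<subclass>_<structure>"}).
#'
#' @param values numeric matrix, samples in rows, glycoforms in columns.
#' @param age numeric vector of ages in years.
#' @param sex vector codeable as 0/1 (e.g. 0 = male, 1 = female).
#' @param cohort optional cohort id (scalar).
#' @return A \code{SummarizedExperiment} with rowData columns
#'   \code{subclass} and \code{structure}.
#' @export
glycomicsExperiment <- function(values, age = NULL, sex = NULL,
                                cohort = NA_character_) {
  stopifnot(is.matrix(values), !is.null(colnames(values)))
  info <- parseGlycoform(colnames(values))
  cd <- S4Vectors::DataFrame(row.names = rownames(values))
  if (!is.null(age)) cd$age <- as.numeric(age)
  if (!is.null(sex)) cd$sex <- as.numeric(sex)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(abundance = t(values)),
    rowData = S4Vectors::DataFrame(subclass = info$subclass,
                                   structure = info$structure),
    colData = cd,
    metadata = list(cohort = cohort))
}

#' Extract the samples x glycoforms value matrix
#'
#' @param x a \code{SummarizedExperiment} from
#'   \code{\link{glycomicsExperiment}} or a samples x glycoforms matrix.
#' @param assay assay name when \code{x} is a \code{SummarizedExperiment}.
#' @return numeric matrix, samples in rows.
#' @export
glycoformValues <- function(x, assay = "abundance") {
  if (is(x, "SummarizedExperiment"))
    t(SummarizedExperiment::assay(x, assay))
  else {
    stopifnot(is.matrix(x))
    x
  }
}

.subclassOf <- function(labels) parseGlycoform(labels)$subclass

#' Probabilistic quotient normalization
#'
#' Corrects per-sample dilution: the reference profile is the per-glycoform
#' median across samples; each sample's dilution factor is the median of its
#' per-glycoform quotients against the reference, and the sample is divided
#' by that factor. Applied separately within each IgG subclass (the
#' measurement is subclass-specific), unless \code{bySubclass = FALSE}.
#'
#' @param x samples x glycoforms matrix of strictly positive abundances, or
#'   a \code{SummarizedExperiment}.
#' @param bySubclass normalize within subclass blocks (default TRUE).
#' @param reference optional named per-glycoform reference profile (e.g.
#'   stored from a previous cohort); by default the per-glycoform median of
#'   the data itself.
#' @return Same type as \code{x}, normalized. For a matrix the dilution
#'   factors (samples x subclass) are attached as \code{attr(,
#'   "dilution")}; for a \code{SummarizedExperiment} they are added to
#'   \code{colData} as \code{dilution.<subclass>}.
#' @export
pqnNormalize <- function(x, bySubclass = TRUE, reference = NULL) {
  if (is(x, "SummarizedExperiment")) {
    v <- glycoformValues(x)
    nv <- pqnNormalize(v, bySubclass = bySubclass, reference = reference)
    SummarizedExperiment::assay(x, "abundance") <- t(nv)
    dil <- attr(nv, "dilution")
    for (j in colnames(dil))
      SummarizedExperiment::colData(x)[[paste0("dilution.", j)]] <- dil[, j]
    return(x)
  }
  stopifnot(is.matrix(x))
  groups <- if (bySubclass) .subclassOf(colnames(x))
            else rep("all", ncol(x))
  out <- x
  dil <- matrix(NA_real_, nrow(x), length(unique(groups)),
                dimnames = list(rownames(x), unique(groups)))
  for (g in unique(groups)) {
    block <- x[, groups == g, drop = FALSE]
    ref <- if (is.null(reference)) apply(block, 2L, stats::median, na.rm = TRUE)
           else reference[colnames(block)]
    bad <- !(ref > 0)
    if (any(bad))
      stop("non-positive PQN reference median for glycoform(s): ",
           paste(colnames(block)[bad], collapse = ", "))
    q <- sweep(block, 2L, ref, "/")
    f <- apply(q, 1L, stats::median, na.rm = TRUE)
    out[, groups == g] <- block / f
    dil[, g] <- f
  }
  attr(out, "dilution") <- dil
  out
}

#' Natural-log transform
#'
#' @param x samples x glycoforms matrix of strictly positive values, or a
#'   \code{SummarizedExperiment}.
#' @return Same type, with values replaced by their natural logarithm.
#' @export
logTransform <- function(x) {
  if (is(x, "SummarizedExperiment")) {
    v <- glycoformValues(x)
    SummarizedExperiment::assay(x, "abundance") <- t(logTransform(v))
    return(x)
  }
  stopifnot(is.matrix(x))
  bad <- which(!is.na(x) & x <= 0, arr.ind = TRUE)
  if (nrow(bad))
    stop("non-positive value(s) at: ",
         paste(sprintf("[%s, %s]",
                       if (is.null(rownames(x))) bad[, 1] else rownames(x)[bad[, 1]],
                       if (is.null(colnames(x))) bad[, 2] else colnames(x)[bad[, 2]]),
               collapse = ", "))
  log(x)
}

#' Drop samples with missing values
#'
#' @param x samples x glycoforms matrix, or a \code{SummarizedExperiment}.
#' @return Same type with incomplete samples removed; the dropped sample
#'   ids are attached as \code{attr(, "dropped")} (matrix) or
#'   \code{metadata(x)$dropped}.
#' @export
dropIncomplete <- function(x) {
  if (is(x, "SummarizedExperiment")) {
    v <- glycoformValues(x)
    keep <- stats::complete.cases(v)
    out <- x[, keep]
    S4Vectors::metadata(out)$dropped <- colnames(x)[!keep]
    return(out)
  }
  stopifnot(is.matrix(x))
  keep <- stats::complete.cases(x)
  out <- x[keep, , drop = FALSE]
  attr(out, "dropped") <- if (is.null(rownames(x))) which(!keep)
                          else rownames(x)[!keep]
  out
}

#' Select unrelated samples from a kinship matrix
#'
#' Removes close relatives so that no retained pair has a kinship
#' coefficient above the threshold (the default 0.0312 removes first-degree
#' cousins or closer). Removal is greedy by relatedness degree: the sample
#' implicated in the most above-threshold pairs is dropped first, ties
#' broken by the lowest sample id, until no violating pair remains.
#'
#' @param kinship symmetric samples x samples matrix of kinship
#'   coefficients; the diagonal is ignored.
#' @param threshold maximum allowed pairwise kinship (default 0.0312).
#' @return character (or integer) vector of retained sample ids.
#' @export
selectUnrelated <- function(kinship, threshold = 0.0312) {
  stopifnot(is.matrix(kinship), nrow(kinship) == ncol(kinship))
  if (any(abs(kinship - t(kinship)) > 1e-8))
    stop("kinship matrix must be symmetric")
  ids <- rownames(kinship)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(kinship)))
  adj <- kinship > threshold
  diag(adj) <- FALSE
  dimnames(adj) <- list(ids, ids)
  keep <- ids
  repeat {
    deg <- rowSums(adj[keep, keep, drop = FALSE])
    if (!length(deg) || max(deg) == 0L) break
    worst <- keep[deg == max(deg)]
    keep <- setdiff(keep, sort(worst)[1L])
  }
  keep
}

#' Per-batch location/scale adjustment
#'
#' A simple batch adjuster for log-scale values: within each batch, each
#' glycoform is centred to the overall median and rescaled from the batch
#' median absolute deviation to the overall one. This is a deliberately
#' plain location/scale correction, not an empirical-Bayes method.
#'
#' @param x samples x glycoforms matrix on the log scale.
#' @param batch factor-like vector of batch labels, one per sample.
#' @return Adjusted matrix.
#' @export
adjustBatches <- function(x, batch) {
  stopifnot(is.matrix(x), length(batch) == nrow(x))
  batch <- as.factor(batch)
  out <- x
  for (j in seq_len(ncol(x))) {
    med <- stats::median(x[, j], na.rm = TRUE)
    s <- stats::mad(x[, j], na.rm = TRUE)
    for (b in levels(batch)) {
      i <- batch == b
      mb <- stats::median(x[i, j], na.rm = TRUE)
      sb <- stats::mad(x[i, j], na.rm = TRUE)
      scale <- if (sb > 0 && s > 0) s / sb else 1
      out[i, j] <- (x[i, j] - mb) * scale + med
    }
  }
  out
}
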