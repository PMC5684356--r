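# Product-substrate ratio traits and the p-gain statistic.

#' Rank-based inverse normal transform
#'
#' Maps values to standard-normal quantiles of their mid-ranks,
#' \code{qnorm((rank - 0.5)/n)}.
#'
#' @param x numeric vector.
#' @return transformed vector (mean ~ 0, variance ~ 1).
#' @export
inverseNormal <- function(x) {
  stats::qnorm((rank(x, ties.method = "average") - 0.5) / length(x))
}

#' Product-substrate ratio traits
#'
#' For every reaction of the model and every IgG subclass in which both the
#' substrate and the product glycoform are measured, forms the quantitative
#' trait \code{log(product / substrate)}, regresses it on age and sex, and
#' applies the rank-based inverse normal transform to the residuals.
#' Reactions with an unmeasured endpoint in a subclass are skipped.
#'
#' @param x a \code{SummarizedExperiment} of raw (positive) abundances with
#'   \code{age} and \code{sex} in \code{colData}, or a samples x glycoforms
#'   matrix (then \code{covariates} must be supplied).
#' @param model a \code{\linkS4class{GlycanPathway}}; all of its reactions
#'   (base plus any applied rules) define the candidate ratios.
#' @param covariates optional data.frame with columns \code{age} and
#'   \code{sex}.
#' @return samples x traits matrix of transformed ratio traits; trait
#'   metadata (subclass, substrate, product, enzyme) is attached as
#'   \code{attr(, "traitInfo")}.
#' @export
ratioTraits <- function(x, model, covariates = NULL) {
  stopifnot(is(model, "GlycanPathway"))
  if (is(x, "SummarizedExperiment") && is.null(covariates)) {
    cd <- SummarizedExperiment::colData(x)
    covariates <- as.data.frame(cd[, intersect(c("age", "sex"),
                                               colnames(cd)), drop = FALSE])
  }
  values <- glycoformValues(x)
  if (any(values <= 0, na.rm = TRUE))
    stop("abundances must be strictly positive to form log ratios")
  info <- parseGlycoform(colnames(values))
  rx <- reactions(model)
  traits <- list()
  meta <- list()
  for (sc in unique(info$subclass)) {
    have <- info$structure[info$subclass == sc]
    ok <- rx$substrate %in% have & rx$product %in% have
    for (r in which(ok)) {
      subCol <- glycoformLabel(sc, rx$substrate[r])
      prodCol <- glycoformLabel(sc, rx$product[r])
      raw <- log(values[, prodCol] / values[, subCol])
      resid <- if (length(covariates)) {
        stats::residuals(stats::lm(raw ~ ., data = covariates))
      } else raw
      id <- paste0(sc, "_", rx$product[r], "/", rx$substrate[r])
      traits[[id]] <- inverseNormal(resid)
      meta[[id]] <- data.frame(trait = id, subclass = sc,
                               substrate = rx$substrate[r],
                               product = rx$product[r],
                               enzyme = rx$enzyme[r],
                               stringsAsFactors = FALSE)
    }
  }
  out <- do.call(cbind, traits)
  rownames(out) <- rownames(values)
  attr(out, "traitInfo") <- do.call(rbind, c(meta, list(make.row.names = FALSE)))
  out
}

#' P-gain of a ratio association
#'
#' The p-gain quantifies how much stronger a ratio's association is than
#' that of its component glycans: \code{min(p_substrate, p_product) /
#' p_ratio}. A p-gain of at least 10 (one order of magnitude) is considered
#' significant.
#'
#' @param pRatio,pSubstrate,pProduct association p-values in (0, 1].
#' @param threshold significance threshold for the gain (default 10).
#' @return list with \code{pgain} and logical \code{significant}.
#' @export
pGain <- function(pRatio, pSubstrate, pProduct, threshold = 10) {
  ps <- c(pRatio, pSubstrate, pProduct)
  if (any(ps <= 0 | ps > 1))
    stop("p-values must lie in (0, 1]")
  g <- pmin(pSubstrate, pProduct) / pRatio
  list(pgain = g, significant = g >= threshold)
}

#' Additive genetic association of a trait
#'
#' Slope test of a simple linear regression of the trait on allele dosage
#' (the additive model). This is deliberately minimal plumbing so that
#' ratio traits and p-gains can be exercised on synthetic genotypes; it is
#' not a GWAS engine.
#'
#' @param trait numeric vector.
#' @param dosage numeric vector of allele dosages in [0, 2].
#' @return two-sided p-value of the dosage coefficient.
#' @export
additiveAssociation <- function(trait, dosage) {
  stopifnot(length(trait) == length(dosage),
            all(dosage >= 0 & dosage <= 2))
  if (stats::sd(dosage) == 0) stop("constant dosage: association undefined")
  fit <- stats::lm(trait ~ dosage)
  summary(fit)$coefficients["dosage", "Pr(>|t|)"]
}

#' Genome-wide significance threshold for ratio traits
#'
#' Bonferroni correction of the conventional genome-wide level for the
#' number of ratio traits tested: \code{base / nTraits}.
#'
#' @param nTraits number of ratio traits generated (see
#'   \code{\link{ratioTraits}}).
#' @param base uncorrected genome-wide level (default 5e-8).
#' @return corrected threshold.
#' @examples
#' genomewideThreshold(95)  # 5.26e-10
#' @export
genomewideThreshold <- function(nTraits, base = 5e-8) {
  stopifnot(nTraits >= 1)
  base / nTraits
}
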