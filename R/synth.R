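# Synthetic glycomics cohorts whose conditional-independence structure
# matches a chosen pathway model.

#' Configure a synthetic glycomics cohort
#'
#' The generator emulates the statistical structure of IgG Fc glycopeptide
#' panels: log-normal abundances whose conditional-dependence graph equals
#' the reaction graph of a pathway model (positive partial correlation
#' \code{rho} along each within-subclass reaction edge), coupling
#' \code{rhoX} between the same structure measured in different subclasses,
#' linear age and sex effects on the latent log scale, per-sample dilution,
#' and optional missingness.
#'
#' @param model a \code{\linkS4class{GlycanPathway}}; its per-subclass
#'   measured panels define the glycoforms and its reactions the
#'   conditional dependencies.
#' @param nSamples cohort size (default 700).
#' @param rho target partial correlation per reaction edge, in (-1, 1)
#'   (default 0.35).
#' @param ruleRho optional weaker strength for reactions that were added to
#'   the model by rules (default: equal to \code{rho}). Cohort data show
#'   candidate-reaction correlations near the detection boundary while
#'   known-pathway correlations are strong; setting \code{ruleRho < rho}
#'   emulates that regime.
#' @param rhoX cross-subclass same-structure partial correlation
#'   (default 0.25).
#' @param latentSd marginal biological standard deviation of each
#'   glycoform on the log scale (default 0.15, i.e. ~15\% coefficient of
#'   variation, typical for relative glycan abundances).
#' @param ageEffect,sexEffect standard deviations of the per-glycoform
#'   age (per year of age) and sex effects on the latent log scale; the
#'   defaults give age an average ~7% variance share per glycoform, with
#'   tails around 20% for the most age-dependent glycoforms.
#' @param dilutionSd standard deviation of the log dilution factor
#'   (default 0.5: severalfold technical dilution spread, the regime
#'   probabilistic quotient normalization is designed for).
#' @param missingRate probability that an individual measurement is missing.
#' @param seed RNG seed used by the generator.
#' @return A \code{SimulationConfig} (list) for
#'   \code{\link{buildPrecision}} and \code{\link{simulateCohort}}.
#' @export
simulationConfig <- function(model, nSamples = 700, rho = 0.35,
                             ruleRho = NULL, rhoX = 0.25, latentSd = 0.15,
                             ageEffect = 0.002,
                             sexEffect = 0.05, dilutionSd = 0.5,
                             missingRate = 0, seed = 1) {
  stopifnot(is(model, "GlycanPathway"), length(model@subclasses) >= 1,
            abs(rho) < 1, abs(rhoX) < 1, nSamples >= 2, latentSd > 0,
            missingRate >= 0, missingRate < 1)
  if (is.null(ruleRho)) ruleRho <- rho
  stopifnot(abs(ruleRho) < 1)
  structure(list(model = model, nSamples = as.integer(nSamples),
                 rho = rho, ruleRho = ruleRho, rhoX = rhoX,
                 latentSd = latentSd,
                 ageEffect = ageEffect,
                 sexEffect = sexEffect, dilutionSd = dilutionSd,
                 missingRate = missingRate, seed = seed),
            class = "SimulationConfig")
}

.configLabels <- function(config) {
  panels <- subclassPanels(config$model)
  measured <- panelStructures(config$model)
  measured <- measured$name[measured$measured]
  unlist(lapply(names(panels), function(sc)
    glycoformLabel(sc, intersect(panels[[sc]], measured))),
    use.names = FALSE)
}

#' Precision matrix implied by a simulation configuration
#'
#' Builds the (standardized, unit-diagonal) precision matrix over all
#' measured glycoforms: entry \code{-rho} for each within-subclass reaction
#' edge of the model and \code{-rhoX} for each same-structure
#' cross-subclass pair, zero elsewhere. If the requested strengths are not
#' jointly realisable (the implied matrix would not be positive definite),
#' all off-diagonal entries are scaled down by a common factor so that the
#' smallest eigenvalue stays at 0.05; the realized edge strength is then
#' \code{rho} times that factor and is reported in the attached truth
#' table.
#'
#' @param config a \code{SimulationConfig}.
#' @return precision matrix with glycoform dimnames; the true edge list
#'   (with realized partial correlations) is attached as
#'   \code{attr(, "edges")} and the scaling factor as
#'   \code{attr(, "scale")}.
#' @export
buildPrecision <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  labels <- .configLabels(config)
  p <- length(labels)
  info <- parseGlycoform(labels)
  M <- matrix(0, p, p, dimnames = list(labels, labels))
  rx <- reactions(config$model)
  strength <- if (is.null(rx$rule)) rep(config$rho, nrow(rx))
              else ifelse(is.na(rx$rule), config$rho, config$ruleRho)
  for (sc in unique(info$subclass)) {
    have <- info$structure[info$subclass == sc]
    ok <- rx$substrate %in% have & rx$product %in% have
    i <- match(glycoformLabel(sc, rx$substrate[ok]), labels)
    j <- match(glycoformLabel(sc, rx$product[ok]), labels)
    M[cbind(i, j)] <- strength[ok]
    M[cbind(j, i)] <- strength[ok]
  }
  sameStr <- outer(info$structure, info$structure, "==") &
             outer(info$subclass, info$subclass, "!=")
  M[sameStr & M == 0] <- config$rhoX
  scale <- 1
  if (any(M != 0)) {
    lmax <- max(eigen(M, symmetric = TRUE, only.values = TRUE)$values)
    if (lmax >= 0.95) scale <- 0.95 / lmax
  }
  omega <- diag(p) - M * scale
  dimnames(omega) <- list(labels, labels)
  ev <- eigen(omega, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("precision matrix not positive definite; use a smaller rho/rhoX")
  idx <- which(M != 0 & upper.tri(M), arr.ind = TRUE)
  attr(omega, "edges") <- data.frame(
    node1 = labels[idx[, 1L]], node2 = labels[idx[, 2L]],
    pcor = M[idx] * scale, stringsAsFactors = FALSE)
  attr(omega, "scale") <- scale
  omega
}

.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  expr
}

.simulate <- function(config, variant = NULL) {
  omega <- buildPrecision(config)
  labels <- colnames(omega)
  p <- length(labels)
  n <- config$nSamples
  .withSeed(config$seed, {
    baseline <- stats::runif(p, 1, 3)
    betaAge <- stats::rnorm(p, 0, config$ageEffect)
    betaSex <- stats::rnorm(p, 0, config$sexEffect)
    sigma <- chol2inv(chol(omega))
    # standardize to the configured marginal log-scale biological sd;
    # rescaling leaves the partial-correlation structure untouched
    sigma <- config$latentSd^2 * stats::cov2cor(sigma)
    latent <- matrix(stats::rnorm(n * p), n, p) %*% chol(sigma)
    age <- stats::runif(n, 18, 88)
    sex <- stats::rbinom(n, 1L, 0.6)
    dilution <- exp(stats::rnorm(n, 0, config$dilutionSd))
    missMask <- if (config$missingRate > 0)
      matrix(stats::runif(n * p) < config$missingRate, n, p)
    else NULL
    dosage <- if (!is.null(variant)) stats::rbinom(n, 2L, variant$maf)
    logAbund <- sweep(latent, 2L, baseline, "+") +
      outer(age - 50, betaAge) + outer(sex, betaSex)
    if (!is.null(variant)) {
      shift <- outer(dosage, rep(0, p))
      shift[, match(variant$productCols, labels)] <-
        dosage * variant$beta / 2
      shift[, match(variant$substrateCols, labels)] <-
        shift[, match(variant$substrateCols, labels)] - dosage * variant$beta / 2
      logAbund <- logAbund + shift
    }
    values <- exp(logAbund) * dilution
    if (!is.null(missMask)) values[missMask] <- NA
    dimnames(values) <- list(sprintf("S%04d", seq_len(n)), labels)
    se <- glycomicsExperiment(values, age = age, sex = sex,
                              cohort = "synthetic")
    S4Vectors::metadata(se)$truth <- list(
      edges = attr(omega, "edges"), precision = omega,
      dilution = dilution, baseline = baseline,
      betaAge = betaAge, betaSex = betaSex,
      dosage = dosage, config = config)
    se
  })
}

#' Simulate a synthetic glycomics cohort
#'
#' Draws a latent multivariate normal sample with the precision matrix of
#' \code{\link{buildPrecision}}, adds age and sex effects on the latent log
#' scale, exponentiates to log-normal abundances, multiplies each sample by
#' a random dilution factor and applies optional missingness. The ground
#' truth (edge list, precision matrix, dilution factors, effect sizes) is
#' stored in \code{metadata(x)$truth}.
#'
#' @param config a \code{SimulationConfig}.
#' @return A \code{SummarizedExperiment} (see
#'   \code{\link{glycomicsExperiment}}).
#' @export
simulateCohort <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  .simulate(config)
}

#' Simulate a cohort with a genetic variant acting on one reaction
#'
#' Adds a biallelic variant with binomial dosages that shifts the
#' reaction's product up and its substrate down by \code{beta/2} per allele
#' on the latent log scale, in every subclass where both endpoints are
#' measured -- the signature expected for a cis variant of the catalysing
#' enzyme. All other randomness is identical to
#' \code{\link{simulateCohort}} with the same config, so \code{beta = 0}
#' reproduces the unmodified cohort.
#'
#' @param config a \code{SimulationConfig}.
#' @param substrate,product structure names of a reaction of the model.
#' @param beta allelic effect on the log scale.
#' @param maf minor allele frequency (default 0.3).
#' @return list with \code{dosage} (length-n vector) and \code{experiment}
#'   (the modified cohort).
#' @export
simulateVariant <- function(config, substrate, product, beta, maf = 0.3) {
  stopifnot(inherits(config, "SimulationConfig"))
  rx <- reactions(config$model)
  if (!any(rx$substrate == substrate & rx$product == product))
    stop("reaction ", substrate, " -> ", product, " is not in the model")
  labels <- .configLabels(config)
  info <- parseGlycoform(labels)
  inPanel <- function(str) labels[info$structure == str]
  bySub <- split(labels, info$subclass)
  subCols <- prodCols <- character()
  for (sc in names(bySub)) {
    s <- glycoformLabel(sc, substrate); pr <- glycoformLabel(sc, product)
    if (s %in% labels && pr %in% labels) {
      subCols <- c(subCols, s); prodCols <- c(prodCols, pr)
    }
  }
  se <- .simulate(config, variant = list(substrateCols = subCols,
                                         productCols = prodCols,
                                         beta = beta, maf = maf))
  list(dosage = S4Vectors::metadata(se)$truth$dosage, experiment = se)
}
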