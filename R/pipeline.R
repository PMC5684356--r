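# End-to-end analysis pipeline: preprocess -> networks -> modularity ->
# model inference -> (optional) ratio traits.

.readRunConfig <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("reading YAML configs requires the yaml package")
      yaml::read_yaml(config)
    } else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  defaults <- list(fdr = 0.01, bootstrap = 10000, nulls = 1e5,
                   swapsFactor = 10, seed = 1,
                   kinshipThreshold = 0.0312,
                   pcorMethod = "fisher", ratios = FALSE,
                   pathway = NULL, outDir = "glyconet_out")
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  config
}

#' Run the full glycomics pathway-inference pipeline
#'
#' Executes preprocessing (missing-value and relatedness filtering, PQN,
#' log transform), network estimation (Pearson, shrinkage partial
#' correlations, GGM), subclass modularity with rewiring null, rule-based
#' pathway model fitting with bootstrap, parsimony model selection and,
#' optionally, ratio-trait construction. All artifacts are written to the
#' output directory as plain-text tables plus a JSON provenance log
#' (configuration, package version, seed, stage summaries).
#'
#' @param config a named list, or the path of a JSON/YAML file, with
#'   entries: \code{input} (abundance table path) or \code{experiment} (a
#'   \code{SummarizedExperiment}), optional \code{covariates} and
#'   \code{kinship} paths, \code{pathway} (pathway JSON; default: shipped
#'   known pathway), \code{fdr} (0.01), \code{bootstrap} (10000),
#'   \code{nulls} (1e5), \code{seed}, \code{ratios} (logical),
#'   \code{outDir}.
#' @return Invisibly, a list with the fitted objects (experiment, networks,
#'   modularity, fits, selected model) and the artifact paths.
#' @export
runPipeline <- function(config) {
  cfg <- .readRunConfig(config)
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  logLines <- list(package = "glyconet",
                   version = as.character(utils::packageVersion("glyconet")),
                   config = cfg[setdiff(names(cfg), "experiment")],
                   stages = list())
  stage <- function(name, value) {
    logLines$stages[[name]] <<- value
  }

  se <- if (!is.null(cfg[["experiment"]])) cfg[["experiment"]]
        else readGlycomicsTable(cfg[["input"]], cfg[["covariates"]])
  nStart <- ncol(se)
  se <- dropIncomplete(se)
  stage("dropIncomplete", list(before = nStart, after = ncol(se)))
  if (!is.null(cfg[["kinship"]])) {
    kin <- readKinshipTable(cfg[["kinship"]])
    keep <- selectUnrelated(kin, cfg$kinshipThreshold)
    se <- se[, colnames(se) %in% keep]
    stage("selectUnrelated", list(threshold = cfg$kinshipThreshold,
                                  retained = ncol(se)))
  }
  se <- pqnNormalize(se)
  raw <- se              # positive scale, for ratio traits
  se <- logTransform(se)
  stage("preprocess", list(order = "dropIncomplete -> selectUnrelated -> PQN (per subclass) -> log",
                           samples = ncol(se)))

  model <- if (is.null(cfg[["pathway"]])) knownPathway()
           else loadPathway(cfg[["pathway"]])

  pearson <- pearsonNetwork(se, alpha = cfg$fdr)
  partial <- partialCorrelation(se, alpha = cfg$fdr,
                                method = cfg$pcorMethod)
  ggm <- buildGGM(pearson, partial)
  for (obj in list(list(pearson, "pearson"), list(partial, "partial"),
                   list(ggm, "ggm"))) {
    writeNetworkTSV(obj[[1L]], file.path(cfg$outDir,
                                         paste0(obj[[2L]], "_edges.tsv")))
    writeNetworkGraphML(obj[[1L]], file.path(cfg$outDir,
                                             paste0(obj[[2L]], ".graphml")))
  }
  stage("networks", list(
    pearsonSignificant = sum(significanceMask(pearson)[upper.tri(significanceMask(pearson))]),
    partialSignificant = sum(significanceMask(partial)[upper.tri(significanceMask(partial))]),
    ggmEdges = sum(significanceMask(ggm)[upper.tri(significanceMask(ggm))]),
    lambda = shrinkageLambda(partial)))

  nPos <- sum(significanceMask(ggm)[upper.tri(significanceMask(ggm))] &
              estimates(ggm)[upper.tri(estimates(ggm))] > 0)
  if (nPos >= 2) {
    mod <- subclassModularity(ggm)
    nullRes <- rewireNull(ggm, nNull = cfg$nulls,
                          swapsFactor = cfg$swapsFactor, seed = cfg$seed)
    stage("modularity", list(Q = mod$Q, p = nullRes$p, nulls = cfg$nulls))
  } else {
    mod <- nullRes <- NULL
    stage("modularity", list(
      skipped = "fewer than 2 significantly positive edges"))
  }

  models <- enumerateModels(model)
  fits <- fitModels(se, models, alpha = cfg$fdr, B = cfg$bootstrap,
                    seed = cfg$seed, method = cfg$pcorMethod)
  sel <- selectModel(fits)
  utils::write.table(fits, file.path(cfg$outDir, "model_fits.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(as.list(sel), file.path(cfg$outDir,
                                               "selected_model.json"),
                       auto_unbox = TRUE, digits = NA)
  stage("inference", list(selected = sel$model, p = sel$p))

  ratios <- NULL
  if (isTRUE(cfg$ratios)) {
    fullModel <- extendModel(model, names(pathwayRules(model)))
    ratios <- ratioTraits(raw, fullModel)
    info <- attr(ratios, "traitInfo")
    utils::write.table(cbind(info,
                             threshold = genomewideThreshold(nrow(info))),
                       file.path(cfg$outDir, "ratio_traits.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(id = rownames(ratios), ratios, check.names = FALSE),
      file.path(cfg$outDir, "ratio_values.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    stage("ratios", list(nTraits = nrow(info),
                         threshold = genomewideThreshold(nrow(info))))
  }

  jsonlite::write_json(logLines, file.path(cfg$outDir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(list(experiment = se, pearson = pearson, partial = partial,
                 ggm = ggm, modularity = mod, modularityNull = nullRes,
                 fits = fits, selected = sel, ratios = ratios,
                 outDir = cfg$outDir))
}
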