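#' Default pipeline run configuration
#'
#' A flat named list controlling every pipeline stage: input table paths,
#' path-score settings, classifier backend and CV shape, prediction
#' threshold, feature-subset and path-type ablation switches, and all
#' seeds (no wall-clock seeding anywhere). Unknown keys in \code{...} are
#' rejected.
#'
#' @param ... overrides of the defaults.
#' @return a named list.
#' @export
runConfig <- function(...) {
  cfg <- list(
    network = NULL, drugs = NULL, diseases = NULL, associations = NULL,
    fingerprints = NULL, validation = NULL, pairs = NULL,
    outDir = ".", mode = "fixed", allowedLengths = "0,1,2",
    combineWeights = "0.5,0.5", sourceTags = NULL,
    backend = "forest", folds = 10L, repeats = 10L, seed = 1,
    threshold = 0.5, strictCV = FALSE, pooled = FALSE,
    featureSubset = "all",
    nNodes = 500L, edgeModel = "preferential_attachment",
    medianDegree = 6, nDrugs = 60L, nDiseases = 20L, nPositives = 200L,
    signal = 0.8)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  cfg
}

#' Read a key=value configuration file
#'
#' One \code{key = value} pair per line; \code{#} comments and blank lines
#' ignored. Values are kept as strings and coerced where the pipeline needs
#' numbers.
#'
#' @param path configuration file path.
#' @return a config list as from [runConfig()].
#' @export
readRunConfig <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  if (any(lengths(kv) < 2L)) stop("malformed config line")
  keys <- trimws(vapply(kv, `[[`, character(1L), 1L))
  vals <- trimws(vapply(kv, function(x) paste(x[-1L], collapse = "="),
                        character(1L)))
  do.call(runConfig, setNames(as.list(vals), keys))
}

parseIntVec <- function(s) sort(unique(as.integer(
  strsplit(as.character(s), ",", fixed = TRUE)[[1L]])))

configPathScore <- function(cfg, net = NULL) {
  pathScoreConfig(mode = cfg$mode, net = net,
                  allowedLengths = parseIntVec(cfg$allowedLengths),
                  combineWeights = as.numeric(
                    strsplit(as.character(cfg$combineWeights), ",")[[1L]]))
}

featureSubsetNames <- function(which) {
  fn <- featureNames()
  switch(which,
         all = fn,
         adjacency = fn[1:3],
         module = fn[4:30],
         stop("unknown feature subset: ", which))
}

loadPipelineInputs <- function(cfg) {
  for (key in c("network", "drugs", "diseases", "associations")) {
    if (is.null(cfg[[key]])) stop("config key '", key, "' is required")
    if (!file.exists(cfg[[key]])) stop("missing file: ", cfg[[key]])
  }
  net <- loadNetwork(cfg$network)
  if (!is.null(cfg$sourceTags)) {   # network-source ablation: filter tags
    keepTags <- strsplit(as.character(cfg$sourceTags), ",")[[1L]]
    tab <- edgeTable(net)
    keep <- vapply(strsplit(tab$type, ","), function(tg)
      any(tg %in% keepTags), logical(1L))
    if (!any(keep)) stop("no edges carry the requested source tags")
    net <- loadNetwork(tab[keep, , drop = FALSE])
  }
  cats <- loadCatalogs(cfg$drugs, cfg$diseases, cfg$associations, net,
                       reportPath = file.path(cfg$outDir,
                                              "filter_report.json"))
  list(net = net, cats = cats, pcfg = configPathScore(cfg, net))
}

#' Run a pipeline stage
#'
#' Orchestrates the full workflow from the command line or a script:
#' \describe{
#'   \item{simulate}{generate a synthetic benchmark into \code{outDir}.}
#'   \item{build-features}{compute the labeled feature matrix (CSV + ARFF).}
#'   \item{train-eval}{repeated cross-validation; writes CVResult JSON and
#'     the information-gain ranking TSV.}
#'   \item{predict}{train on the full matrix and rank candidate pairs.}
#'   \item{validate}{coverage enrichment of predictions against an external
#'     association list, plus the fingerprint Tanimoto screen.}
#'   \item{ablate}{train-eval for the all/adjacency-only/module-only
#'     feature subsets.}
#' }
#' Every artifact lands under \code{cfg$outDir} together with a run log
#' echoing the configuration and its hash.
#'
#' @param cfg configuration list from [runConfig()] or [readRunConfig()].
#' @param command one of the stage names above.
#' @return a list of produced artifact paths (and key results), invisibly.
#' @export
runPipeline <- function(cfg, command = c("simulate", "build-features",
                                         "train-eval", "predict",
                                         "validate", "ablate")) {
  command <- match.arg(command)
  if (!dir.exists(cfg$outDir)) dir.create(cfg$outDir, recursive = TRUE)
  logPath <- file.path(cfg$outDir, paste0("run_", command, ".log"))
  echo <- cfg[!vapply(cfg, is.null, logical(1L))]
  cfgHash <- substr(digestConfig(echo), 1L, 12L)
  writeLines(c(sprintf("command: %s", command),
               sprintf("config_hash: %s", cfgHash),
               sprintf("%s = %s", names(echo),
                       vapply(echo, function(v)
                         paste(format(v), collapse = ","), character(1L)))),
             logPath)

  out <- switch(command,
    "simulate" = {
      spec <- benchmarkSpec(
        nNodes = as.integer(cfg$nNodes), edgeModel = cfg$edgeModel,
        medianDegree = as.numeric(cfg$medianDegree),
        nDrugs = as.integer(cfg$nDrugs),
        nDiseases = as.integer(cfg$nDiseases),
        nPositives = as.integer(cfg$nPositives),
        signal = as.numeric(cfg$signal), seed = as.numeric(cfg$seed))
      paths <- generateBenchmark(spec, cfg$outDir)
      attr(paths, "benchmark") <- NULL
      as.list(paths)
    },
    "build-features" = {
      inp <- loadPipelineInputs(cfg)
      tm <- if (!is.null(cfg$pairs)) {
        pr <- readTsv(cfg$pairs, "pair")
        pairs <- data.frame(drug = pr$V1, disease = pr$V2,
                            stringsAsFactors = FALSE)
        fm <- featureTable(pairs, inp$cats$drugs, inp$cats$diseases,
                           inp$cats$assoc, inp$net, inp$pcfg,
                           excludeSelf = TRUE)
        lab <- ifelse(pairKey(pairs$drug, pairs$disease) %in%
                        pairKey(associationPairs(inp$cats$assoc)$drug,
                                associationPairs(inp$cats$assoc)$disease),
                      "positive", "negative")
        newDrugDiseaseFeatures(t(fm), pairs, lab, NA)
      } else buildTrainingMatrix(inp$cats$drugs, inp$cats$diseases,
                                 inp$cats$assoc, inp$net, inp$pcfg,
                                 seed = as.numeric(cfg$seed))
      csv <- file.path(cfg$outDir, "features.csv")
      arff <- file.path(cfg$outDir, "features.arff")
      writeFeatureCSV(tm, csv)
      writeFeatureARFF(tm, arff)
      list(features_csv = csv, features_arff = arff)
    },
    "train-eval" = {
      inp <- loadPipelineInputs(cfg)
      cv <- repeatedCV(inp$cats$drugs, inp$cats$diseases, inp$cats$assoc,
                       inp$net, inp$pcfg, backend = cfg$backend,
                       folds = as.integer(cfg$folds),
                       repeats = as.integer(cfg$repeats),
                       seed = as.numeric(cfg$seed),
                       features = featureSubsetNames(cfg$featureSubset),
                       strictCV = isTRUE(as.logical(cfg$strictCV)),
                       pooled = isTRUE(as.logical(cfg$pooled)))
      cvPath <- file.path(cfg$outDir, "cv_result.json")
      writeCVResult(cv, cvPath)
      igPath <- file.path(cfg$outDir, "info_gain.tsv")
      writeTsvFile(cv@infoGain, igPath, col.names = TRUE)
      list(cv_result = cvPath, info_gain = igPath, grand_mean = meanAUC(cv))
    },
    "predict" = {
      inp <- loadPipelineInputs(cfg)
      tm <- buildTrainingMatrix(inp$cats$drugs, inp$cats$diseases,
                                inp$cats$assoc, inp$net, inp$pcfg,
                                seed = as.numeric(cfg$seed))
      model <- trainModel(classifierBackend(cfg$backend,
                                            seed = as.numeric(cfg$seed)),
                          tm, featureSubsetNames(cfg$featureSubset))
      pt <- predictCandidates(model, inp$cats$drugs, inp$cats$diseases,
                              inp$cats$assoc, inp$net, inp$pcfg,
                              threshold = as.numeric(cfg$threshold))
      path <- file.path(cfg$outDir, "predictions.tsv")
      writeTsvFile(pt, path, col.names = TRUE)
      list(predictions = path, n_predicted = sum(pt$predicted == "yes"))
    },
    "validate" = {
      inp <- loadPipelineInputs(cfg)
      predPath <- file.path(cfg$outDir, "predictions.tsv")
      if (!file.exists(predPath))
        stop("run the 'predict' stage first: missing ", predPath)
      pt <- read.delim(predPath, stringsAsFactors = FALSE)
      universe <- expand.grid(drug = entityIds(inp$cats$drugs),
                              disease = entityIds(inp$cats$diseases),
                              KEEP.OUT.ATTRS = FALSE,
                              stringsAsFactors = FALSE)
      pos <- associationPairs(inp$cats$assoc)
      universe <- universe[!pairKey(universe$drug, universe$disease) %in%
                             pairKey(pos$drug, pos$disease), , drop = FALSE]
      res <- list()
      if (!is.null(cfg$validation)) {
        vdf <- readTsv(cfg$validation, "validation")
        val <- data.frame(drug = vdf$V1, disease = vdf$V2,
                          stringsAsFactors = FALSE)
        val <- val[pairKey(val$drug, val$disease) %in%
                     pairKey(universe$drug, universe$disease), ,
                   drop = FALSE]
        covPath <- file.path(cfg$outDir, "coverage_report.json")
        res$coverage <- coverageReport(
          pt[pt$predicted == "yes", c("drug", "disease")], val, universe,
          path = covPath)
        res$coverage_report <- covPath
      }
      if (!is.null(cfg$fingerprints)) {
        fps <- readFingerprints(cfg$fingerprints)
        hits <- pt[pt$predicted == "yes", , drop = FALSE]
        res$fractionSimilar <- if (nrow(hits) >= 2L) {
          dd <- t(utils::combn(unique(hits$drug), 2L))
          fractionSimilar(data.frame(a = dd[, 1L], b = dd[, 2L]), fps,
                          threshold = 0.7)
        } else NA_real_
      }
      res
    },
    "ablate" = {
      inp <- loadPipelineInputs(cfg)
      res <- lapply(c(all = "all", adjacency = "adjacency",
                      module = "module"), function(sub)
        meanAUC(repeatedCV(inp$cats$drugs, inp$cats$diseases,
                           inp$cats$assoc, inp$net, inp$pcfg,
                           backend = cfg$backend,
                           folds = as.integer(cfg$folds),
                           repeats = as.integer(cfg$repeats),
                           seed = as.numeric(cfg$seed),
                           features = featureSubsetNames(sub))))
      path <- file.path(cfg$outDir, "ablation.json")
      jsonlite::write_json(res, path, auto_unbox = TRUE, digits = NA)
      c(res, list(ablation = path))
    })
  invisible(out)
}

# Stable hash of a config list (name-sorted, formatted, md5).
digestConfig <- function(cfg) {
  cfg <- cfg[order(names(cfg))]
  txt <- paste(names(cfg),
               vapply(cfg, function(v) paste(format(v), collapse = ","),
                      character(1L)),
               sep = "=", collapse = ";")
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(txt, tmp)
  unname(tools::md5sum(tmp))
}
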