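#' GeneNetwork: an undirected integrative gene/protein interaction network
#'
#' Wraps an undirected simple \pkg{igraph} graph whose vertices are opaque
#' gene/protein identifiers. Each edge carries the set of evidence sources it
#' was observed in (e.g. \code{ppi}, \code{regulation_activation},
#' \code{regulation_inhibition}, \code{complex_inferred}). Regulation edges
#' are directed in typical source data but all scoring here is undirected, so
#' direction is discarded at load time and only the tags are kept.
#'
#' Depth-limited reachability (distances 1 and 2) is precomputed per node at
#' construction, so bounded-distance and neighborhood queries never traverse
#' the graph beyond two steps.
#'
#' @slot graph an undirected simple \code{igraph} object with vertex
#'   \code{name} attributes and an edge attribute \code{sources}
#'   (comma-joined tags).
#' @slot adj list, per vertex, of integer indices at distance exactly 1.
#' @slot reach2 list, per vertex, of integer indices at distance exactly 2.
#'
#' @seealso [loadNetwork()], [boundedDistance()], [nodeNeighborhood()],
#'   [medianDegree()]
#' @exportClass GeneNetwork
setClass("GeneNetwork",
  representation(graph = "ANY", adj = "list", reach2 = "list"))

setValidity("GeneNetwork", function(object) {
  g <- object@graph
  if (!igraph::is_igraph(g)) return("'graph' must be an igraph object")
  if (igraph::is_directed(g)) return("network must be undirected")
  if (igraph::any_loop(g)) return("network must not contain self-loops")
  if (igraph::any_multiple(g)) return("network must not contain duplicate edges")
  if (is.null(igraph::V(g)$name)) return("vertices must be named")
  if (anyDuplicated(igraph::V(g)$name)) return("vertex names must be unique")
  n <- igraph::vcount(g)
  if (length(object@adj) != n || length(object@reach2) != n)
    return("reachability caches out of sync with graph")
  TRUE
})

#' PathScoreConfig: scoring weights for bounded shortest paths
#'
#' Paths between two genes are classified by length: R0 (identical genes,
#' length 0), R1 (direct edge), R2 (one intermediate gene). An R0 path scores
#' \code{base}, R1 scores \code{base^2}, R2 scores \code{base^3}; longer or
#' absent paths score 0. The default fixed base is 1/6, the reciprocal of the
#' median degree of the integrative network the method was developed on;
#' \code{mode = "auto"} instead takes 1/medianDegree of the loaded network.
#'
#' @slot base numeric in (0, 1], the R0 path score.
#' @slot mode either \code{"fixed"} or \code{"auto"}.
#' @slot maxPathLen integer, always 2.
#' @slot allowedLengths integer subset of \code{0:2}; path lengths outside
#'   this set contribute 0 (used for single-path-type ablation).
#' @slot combineWeights numeric length-2 weights (summing to 1) for the
#'   weighted geometric mean that merges drug-side and disease-side scores.
#'
#' @seealso [pathScoreConfig()], [pathScore()]
#' @exportClass PathScoreConfig
setClass("PathScoreConfig",
  representation(base = "numeric", mode = "character",
                 maxPathLen = "integer", allowedLengths = "integer",
                 combineWeights = "numeric"),
  prototype(base = 1 / 6, mode = "fixed", maxPathLen = 2L,
            allowedLengths = 0:2, combineWeights = c(0.5, 0.5)))

setValidity("PathScoreConfig", function(object) {
  if (length(object@base) != 1L || is.na(object@base) ||
      object@base <= 0 || object@base > 1)
    return("'base' must be a single value in (0, 1]")
  if (!object@mode %in% c("fixed", "auto"))
    return("'mode' must be 'fixed' or 'auto'")
  if (!identical(object@maxPathLen, 2L))
    return("'maxPathLen' is fixed at 2")
  if (!all(object@allowedLengths %in% 0:2) ||
      length(object@allowedLengths) < 1L)
    return("'allowedLengths' must be a non-empty subset of 0:2")
  w <- object@combineWeights
  if (length(w) != 2L || any(w < 0) || abs(sum(w) - 1) > 1e-9)
    return("'combineWeights' must be two non-negative weights summing to 1")
  TRUE
})

#' EntityCatalog: drug target sets or disease susceptibility gene sets
#'
#' Maps entity identifiers (drugs or diseases) to their sets of network node
#' identifiers. After in-network filtering every retained entity has at least
#' two nodes, all of which are network vertices.
#'
#' @slot sets named list of character vectors (entity id -> node ids).
#' @slot kind \code{"drug"} or \code{"disease"}.
#'
#' @seealso [loadCatalogs()], [nodeSets()], [entityIds()]
#' @exportClass EntityCatalog
setClass("EntityCatalog",
  representation(sets = "list", kind = "character"))

setValidity("EntityCatalog", function(object) {
  if (!object@kind %in% c("drug", "disease"))
    return("'kind' must be 'drug' or 'disease'")
  if (length(object@sets) &&
      (is.null(names(object@sets)) || anyDuplicated(names(object@sets))))
    return("entity ids must be unique names of 'sets'")
  sizes <- lengths(object@sets)
  if (any(sizes < 2L))
    return("every retained entity must map to at least 2 network nodes")
  TRUE
})

#' AssociationSet: known drug-disease associations
#'
#' The curated positive pairs, with per-entity indexes supporting lookup of
#' the known drugs of a disease and the known diseases of a drug (the anchor
#' sets over which best-known adjacency and module-distance maxima are taken).
#'
#' @slot pairs data.frame with character columns \code{drug}, \code{disease};
#'   no duplicated pairs.
#' @slot drugsByDisease named list: disease id -> character vector of drugs.
#' @slot diseasesByDrug named list: drug id -> character vector of diseases.
#'
#' @seealso [loadCatalogs()], [knownDrugs()], [knownDiseases()]
#' @exportClass AssociationSet
setClass("AssociationSet",
  representation(pairs = "data.frame", drugsByDisease = "list",
                 diseasesByDrug = "list"))

setValidity("AssociationSet", function(object) {
  p <- object@pairs
  if (!all(c("drug", "disease") %in% names(p)))
    return("'pairs' needs 'drug' and 'disease' columns")
  if (anyDuplicated(pairKey(p$drug, p$disease)))
    return("duplicate associations are not allowed")
  TRUE
})

#' DrugDiseaseFeatures: labeled feature matrix of drug-disease pairs
#'
#' A \linkS4class{SummarizedExperiment} whose single assay \code{"features"}
#' holds the 30 named pair features as rows and drug-disease pairs as
#' columns. \code{colData} carries \code{drug}, \code{disease} and
#' \code{label} (\code{"positive"}/\code{"negative"}); \code{rowData} records
#' each feature's inference method and its (v, k) grid position. Metadata
#' records the feature schema version and the negative-sampling seed.
#'
#' @seealso [buildTrainingMatrix()], [pairFeatures()], [featureMatrix()],
#'   [pairLabels()]
#' @exportClass DrugDiseaseFeatures
setClass("DrugDiseaseFeatures",
  contains = "SummarizedExperiment")

setValidity("DrugDiseaseFeatures", function(object) {
  if (!"features" %in% SummarizedExperiment::assayNames(object))
    return("assay 'features' is required")
  if (!identical(rownames(object), featureNames()))
    return("rows must be the 30 canonical features in canonical order")
  cd <- SummarizedExperiment::colData(object)
  need <- c("drug", "disease", "label")
  if (!all(need %in% names(cd)))
    return("colData needs columns drug, disease, label")
  if (!all(cd$label %in% c("positive", "negative")))
    return("labels must be 'positive' or 'negative'")
  a <- SummarizedExperiment::assay(object, "features")
  if (any(a < 0)) return("feature values must be non-negative")
  TRUE
})

#' CVResult: repeated cross-validation outcome for one classifier backend
#'
#' Stores the per-repeat, per-fold AUCs of repeated stratified k-fold
#' cross-validation in which every repeat draws a fresh random negative set,
#' together with the grand mean AUC, all seeds, a configuration echo and a
#' feature information-gain ranking (diagnostic only).
#'
#' @slot backend backend name.
#' @slot foldAUCs numeric matrix, repeats x folds.
#' @slot repeatAUCs numeric vector, mean AUC per repeat.
#' @slot foldSeed seed governing fold assignment.
#' @slot negativeSeeds one negative-sampling seed per repeat.
#' @slot config configuration echo (list).
#' @slot infoGain data.frame ranking features by information gain.
#'
#' @seealso [repeatedCV()], [meanAUC()]
#' @exportClass CVResult
setClass("CVResult",
  representation(backend = "character", foldAUCs = "matrix",
                 repeatAUCs = "numeric", foldSeed = "numeric",
                 negativeSeeds = "numeric", config = "list",
                 infoGain = "data.frame"))

setValidity("CVResult", function(object) {
  if (length(object@repeatAUCs) != nrow(object@foldAUCs))
    return("one repeat AUC per foldAUCs row required")
  aucs <- c(object@foldAUCs, object@repeatAUCs)
  if (any(aucs < 0 | aucs > 1, na.rm = TRUE))
    return("AUCs must lie in [0, 1]")
  TRUE
})

#' BenchmarkSpec: parameters of the synthetic benchmark generator
#'
#' Describes a self-contained synthetic data set: a sparse scale-free (or
#' Erdos-Renyi) gene network, drug target catalogs, disease gene catalogs,
#' known associations with planted network-proximity signal, and random drug
#' fingerprints. Defaults emulate the structure of curated pharmacological
#' networks at desk scale: median degree about 6, entities with at least two
#' nodes, and positive pairs whose target sets lie near the disease module.
#'
#' @slot nNodes number of network nodes.
#' @slot edgeModel \code{"preferential_attachment"} or \code{"erdos_renyi"}.
#' @slot medianDegree target median degree of the generated network.
#' @slot nDrugs,nDiseases catalog sizes.
#' @slot targetsPerDrug,genesPerDisease inclusive size ranges (min 2).
#' @slot nPositives number of known associations to plant.
#' @slot signal probability, per target of a positive drug, of sampling the
#'   target within distance 1 of its disease's gene module.
#' @slot nBits,bitsPerDrug fingerprint length and set-bit count.
#' @slot seed master seed.
#'
#' @seealso [benchmarkSpec()], [simulateBenchmark()], [generateBenchmark()]
#' @exportClass BenchmarkSpec
setClass("BenchmarkSpec",
  representation(nNodes = "integer", edgeModel = "character",
                 medianDegree = "numeric", nDrugs = "integer",
                 nDiseases = "integer", targetsPerDrug = "integer",
                 genesPerDisease = "integer", nPositives = "integer",
                 signal = "numeric", nBits = "integer",
                 bitsPerDrug = "integer", seed = "numeric"))

setValidity("BenchmarkSpec", function(object) {
  if (object@nNodes < 10L) return("'nNodes' must be >= 10")
  if (!object@edgeModel %in% c("preferential_attachment", "erdos_renyi"))
    return("unknown edge model")
  if (object@nDrugs < 1L || object@nDiseases < 1L || object@nPositives < 1L)
    return("counts must be positive")
  if (object@nPositives > object@nDrugs * object@nDiseases)
    return("more positives requested than distinct drug-disease pairs")
  rng <- c(object@targetsPerDrug, object@genesPerDisease)
  if (length(object@targetsPerDrug) != 2L || length(object@genesPerDisease) != 2L ||
      any(rng < 2L))
    return("set-size ranges must be length-2 with minimum >= 2")
  if (object@targetsPerDrug[1] > object@targetsPerDrug[2] ||
      object@genesPerDisease[1] > object@genesPerDisease[2])
    return("set-size ranges must be non-decreasing")
  if (object@signal < 0 || object@signal > 1)
    return("'signal' must lie in [0, 1]")
  if (object@bitsPerDrug > object@nBits)
    return("'bitsPerDrug' cannot exceed 'nBits'")
  TRUE
})
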