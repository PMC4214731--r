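#' Load drug/disease catalogs and known associations with in-network filtering
#'
#' Reads the drug-target table, disease-gene table and known drug-disease
#' association table (each two tab-separated columns, \code{#} comments
#' allowed, or equivalent data.frames) and applies the in-network filtering
#' rules: node identifiers absent from the network are dropped first, then
#' entities left with fewer than two nodes, then associations referencing a
#' dropped entity. Duplicate (entity, node) and duplicate association rows
#' are removed silently. Filtering is order-independent: it reaches the same
#' fixpoint regardless of interleaving, because association pruning never
#' feeds back into catalog membership.
#'
#' @param drugTable,diseaseTable two-column (entity_id, node_id) TSV paths or
#'   data.frames.
#' @param assocTable two-column (drug_id, disease_id) TSV path or data.frame.
#' @param net a \linkS4class{GeneNetwork}.
#' @param reportPath optional path; when given, the filter report is written
#'   there as JSON.
#' @return a list with elements \code{drugs} and \code{diseases}
#'   (\linkS4class{EntityCatalog}), \code{assoc}
#'   (\linkS4class{AssociationSet}) and \code{report} (named counts dropped
#'   at each step). An empty post-filter association set triggers a warning,
#'   not an error.
#' @export
loadCatalogs <- function(drugTable, diseaseTable, assocTable, net,
                         reportPath = NULL) {
  nodes <- networkNodes(net)
  drugs <- filterCatalog(readTsv(drugTable, "drug"), nodes, "drug")
  diseases <- filterCatalog(readTsv(diseaseTable, "disease"), nodes, "disease")

  adf <- readTsv(assocTable, "association")
  apairs <- unique(data.frame(drug = trimws(adf$V1), disease = trimws(adf$V2),
                              stringsAsFactors = FALSE))
  nAssocIn <- nrow(apairs)
  keep <- apairs$drug %in% names(drugs$sets) &
    apairs$disease %in% names(diseases$sets)
  apairs <- apairs[keep, , drop = FALSE]
  if (nrow(apairs) == 0L)
    warning("no known associations remain after filtering")

  report <- list(
    drugs_in = drugs$nIn, drug_nodes_dropped = drugs$nodesDropped,
    drugs_dropped = drugs$entitiesDropped, drugs_retained = length(drugs$sets),
    diseases_in = diseases$nIn, disease_nodes_dropped = diseases$nodesDropped,
    diseases_dropped = diseases$entitiesDropped,
    diseases_retained = length(diseases$sets),
    associations_in = nAssocIn,
    associations_dropped = nAssocIn - nrow(apairs),
    associations_retained = nrow(apairs))
  if (!is.null(reportPath))
    jsonlite::write_json(report, reportPath, auto_unbox = TRUE, digits = NA)

  list(drugs = new("EntityCatalog", sets = drugs$sets, kind = "drug"),
       diseases = new("EntityCatalog", sets = diseases$sets,
                      kind = "disease"),
       assoc = newAssociationSet(apairs),
       report = report)
}

# In-network filtering of one (entity, node) table.
filterCatalog <- function(df, nodes, kind) {
  ent <- trimws(df$V1); node <- trimws(df$V2)
  keep <- !duplicated(paste(ent, node, sep = "\t"))
  ent <- ent[keep]; node <- node[keep]
  nIn <- length(unique(ent))
  inNet <- node %in% nodes
  nodesDropped <- sum(!inNet)
  ent <- ent[inNet]; node <- node[inNet]
  sets <- split(node, ent)
  sets <- lapply(sets, function(s) sort(unique(s)))
  big <- lengths(sets) >= 2L
  list(sets = sets[big], nIn = nIn, nodesDropped = nodesDropped,
       entitiesDropped = nIn - sum(big))
}

newAssociationSet <- function(pairs) {
  new("AssociationSet", pairs = pairs,
      drugsByDisease = split(pairs$drug, pairs$disease),
      diseasesByDrug = split(pairs$disease, pairs$drug))
}

#' @describeIn EntityCatalog retained entity identifiers.
#' @param x an \linkS4class{EntityCatalog}.
#' @export
setMethod("entityIds", "EntityCatalog", function(x) names(x@sets))

#' @describeIn EntityCatalog named list of node sets.
#' @export
setMethod("nodeSets", "EntityCatalog", function(x) x@sets)

setMethod("show", "EntityCatalog", function(object) {
  sz <- lengths(object@sets)
  cat(sprintf("EntityCatalog (%s): %d entities, node-set sizes %s-%s\n",
              object@kind, length(object@sets),
              if (length(sz)) min(sz) else 0, if (length(sz)) max(sz) else 0))
})

#' @describeIn AssociationSet drugs known to be associated with a disease
#'   (empty character vector if none).
#' @param assoc an \linkS4class{AssociationSet}.
#' @param disease a disease identifier.
#' @export
setMethod("knownDrugs", "AssociationSet", function(assoc, disease) {
  out <- assoc@drugsByDisease[[disease]]
  if (is.null(out)) character() else out
})

#' @describeIn AssociationSet diseases known to be associated with a drug.
#' @param drug a drug identifier.
#' @export
setMethod("knownDiseases", "AssociationSet", function(assoc, drug) {
  out <- assoc@diseasesByDrug[[drug]]
  if (is.null(out)) character() else out
})

#' @describeIn AssociationSet the pair table (drug, disease).
#' @export
setMethod("associationPairs", "AssociationSet", function(assoc) assoc@pairs)

setMethod("show", "AssociationSet", function(object) {
  cat(sprintf("AssociationSet: %d pairs (%d drugs, %d diseases)\n",
              nrow(object@pairs), length(unique(object@pairs$drug)),
              length(unique(object@pairs$disease))))
})
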