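# Intersection of two v-step neighborhoods, on vertex indices.
commonModuleIdx <- function(net, i1, i2, v) {
  n1 <- neighborhoodIdx(net, i1, v)
  n2 <- neighborhoodIdx(net, i2, v)
  n1[n1 %in% n2]
}

#' Common topological module of two entity node sets
#'
#' The topological gene module shared by two drugs (d-module) or two
#' diseases (p-module) at expansion level \code{v}: each node set is grown
#' to its v-step network neighborhood and the two neighborhoods are
#' intersected. At \code{v = 0} this is simply the shared targets (genes);
#' the module grows monotonically with \code{v} and may be empty.
#'
#' @param S1,S2 non-empty character vectors of network node identifiers.
#' @param v expansion level in \code{0:2}.
#' @param net a \linkS4class{GeneNetwork}.
#' @return sorted character vector of module member identifiers (possibly
#'   empty).
#' @export
commonModule <- function(S1, S2, v, net) {
  if (length(S1) == 0L || length(S2) == 0L)
    stop("node sets must be non-empty")
  if (length(v) != 1L || !v %in% 0:2)
    stop("level parameter 'v' must be one of 0, 1, 2")
  idx <- commonModuleIdx(net, nodeIndex(net, S1), nodeIndex(net, S2),
                         as.integer(v))
  igraph::V(net@graph)$name[idx]
}

#' Distance score between a topological module and an entity node set
#'
#' For path-length parameter \code{k}, every (module member, entity node)
#' pair whose bounded shortest-path distance is exactly \code{k} contributes
#' \code{base^(k+1)}; the sum is scaled by \code{|module| * |G|}. At
#' \code{k = 0} only exact intersections score, at \code{k = 1} only
#' directly connected pairs, at \code{k = 2} only pairs one intermediate
#' apart. An empty module scores 0.
#'
#' @param members character vector of module members (may be empty).
#' @param G non-empty character vector of entity node identifiers.
#' @param k path-length parameter in \code{0:2}.
#' @param net,cfg network and path-score configuration.
#' @return a single number in \code{[0, base^(k+1)]}.
#' @export
moduleEntityDistance <- function(members, G, k, net, cfg) {
  if (length(G) == 0L) stop("entity node set must be non-empty")
  if (length(k) != 1L || !k %in% 0:2)
    stop("distance parameter 'k' must be one of 0, 1, 2")
  if (length(members) == 0L) return(0)
  mi <- unique(nodeIndex(net, members)); gi <- unique(nodeIndex(net, G))
  counts <- bucketCountsIdx(net, mi, gi)
  counts[k + 1L] * pathScore(cfg, k) / (length(mi) * length(gi))
}

#' Best module-distance score against the known partners of an anchor
#'
#' For \code{kind = "d-module"} and a pair (drug d, disease p): for every
#' drug d' known to treat p (minus \code{exclude}), the common module of
#' T(d) and T(d') at level \code{v} is scored against the disease gene set
#' T(p) at path length \code{k}, and the maximum is returned. For
#' \code{kind = "p-module"} the roles flip: the query is the disease, the
#' anchor the drug, candidates its known diseases, and the p-module is
#' scored against the drug target set. Empty candidate sets score 0.
#'
#' @param query entity id whose node set seeds the module (drug for
#'   d-module, disease for p-module).
#' @param anchor the partner entity anchoring the known-association lookup
#'   (disease for d-module, drug for p-module).
#' @param kind \code{"d-module"} or \code{"p-module"}.
#' @param v,k module level and path-length parameters, each in \code{0:2}.
#' @param drugs,diseases \linkS4class{EntityCatalog}s.
#' @param assoc an \linkS4class{AssociationSet}.
#' @param net,cfg network and path-score configuration.
#' @param exclude optional candidate entity id to drop (self-exclusion for
#'   known positive pairs).
#' @return a single non-negative number.
#' @export
bestKnownModuleDistance <- function(query, anchor,
                                    kind = c("d-module", "p-module"),
                                    v, k, drugs, diseases, assoc, net, cfg,
                                    exclude = NULL) {
  kind <- match.arg(kind)
  if (kind == "d-module") {
    cands <- knownDrugs(assoc, anchor)
    seedSets <- nodeSets(drugs)
    targetSet <- nodeSets(diseases)[[anchor]]
    querySet <- nodeSets(drugs)[[query]]
  } else {
    cands <- knownDiseases(assoc, anchor)
    seedSets <- nodeSets(diseases)
    targetSet <- nodeSets(drugs)[[anchor]]
    querySet <- nodeSets(diseases)[[query]]
  }
  if (is.null(querySet)) stop("unknown query entity: ", query)
  if (is.null(targetSet)) stop("unknown anchor entity: ", anchor)
  if (!is.null(exclude)) cands <- setdiff(cands, exclude)
  cands <- cands[cands %in% names(seedSets)]
  if (length(cands) == 0L) return(0)
  max(vapply(cands, function(e) {
    mod <- commonModule(querySet, seedSets[[e]], v, net)
    moduleEntityDistance(mod, targetSet, k, net, cfg)
  }, numeric(1L)))
}

#' Write module members to a one-node-per-line text file
#'
#' @param members character vector of node identifiers.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeModule <- function(members, path) {
  writeLines(sort(members), path)
  invisible(path)
}
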