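# Count (t, g) pairs at bounded distance exactly 0, 1 and 2 between two
# node-index sets, via a membership flag over the vertex set. O(|M| +
# sum over g of deg2(g)); never walks beyond two steps.
bucketCountsIdx <- function(net, M, G) {
  n <- length(net@adj)
  flag <- logical(n)
  flag[M] <- TRUE
  c0 <- 0L; c1 <- 0L; c2 <- 0L
  for (g in G) {
    if (flag[g]) c0 <- c0 + 1L
    a <- net@adj[[g]]
    if (length(a)) c1 <- c1 + sum(flag[a])
    r <- net@reach2[[g]]
    if (length(r)) c2 <- c2 + sum(flag[r])
  }
  c(c0, c1, c2)
}

#' Adjacency score between two node sets
#'
#' The drug-drug (or disease-disease) adjacency score: every cross pair
#' (x, y) with x in \code{S1}, y in \code{S2} contributes the score of the
#' bounded shortest path between x and y (R0 = base, R1 = base^2,
#' R2 = base^3, 0 beyond distance 2), and the sum is scaled by
#' \code{|S1| * |S2|}. Symmetric in its two sets; lies in
#' \code{[0, base]} since each pair contributes at most the base score.
#'
#' @param S1,S2 non-empty character vectors of network node identifiers.
#' @param net a \linkS4class{GeneNetwork}.
#' @param cfg a \linkS4class{PathScoreConfig}.
#' @return a single non-negative number.
#' @examples
#' net <- loadNetwork(data.frame(a = c("A", "B", "C"), b = c("B", "C", "D")))
#' cfg <- pathScoreConfig()
#' pairSetAdjacency("A", "C", net, cfg)  # one R2 pair: (1/6)^3
#' @export
pairSetAdjacency <- function(S1, S2, net, cfg) {
  if (length(S1) == 0L || length(S2) == 0L)
    stop("node sets must be non-empty")
  i1 <- unique(nodeIndex(net, S1)); i2 <- unique(nodeIndex(net, S2))
  counts <- bucketCountsIdx(net, i1, i2)
  sum(counts * pathScore(cfg, 0:2)) / (length(i1) * length(i2))
}

#' Best adjacency score against the known partners of an anchor entity
#'
#' For \code{side = "drug"} the anchor is a disease: the query node set
#' (a drug's targets) is scored against the target set of every drug known
#' to treat that disease, and the maximum is returned. For
#' \code{side = "disease"} the anchor is a drug and the candidates are its
#' known diseases' gene sets. \code{exclude} removes one candidate — the
#' queried entity itself when scoring a known positive pair, so its own
#' association never anchors its own score. An empty candidate set scores 0.
#'
#' @param querySet character vector of network node identifiers.
#' @param anchorEntity the anchoring entity (disease id for
#'   \code{side="drug"}, drug id for \code{side="disease"}).
#' @param side \code{"drug"} or \code{"disease"}: which kind of known
#'   partner is enumerated.
#' @param drugs,diseases \linkS4class{EntityCatalog}s.
#' @param assoc an \linkS4class{AssociationSet}.
#' @param net,cfg network and path-score configuration.
#' @param exclude optional candidate entity id to drop.
#' @return a single non-negative number.
#' @export
bestKnownAdjacency <- function(querySet, anchorEntity,
                               side = c("drug", "disease"),
                               drugs, diseases, assoc, net, cfg,
                               exclude = NULL) {
  side <- match.arg(side)
  if (side == "drug") {
    cands <- knownDrugs(assoc, anchorEntity)
    sets <- nodeSets(drugs)
  } else {
    cands <- knownDiseases(assoc, anchorEntity)
    sets <- nodeSets(diseases)
  }
  if (!is.null(exclude)) cands <- setdiff(cands, exclude)
  cands <- cands[cands %in% names(sets)]
  if (length(cands) == 0L) return(0)
  max(vapply(cands, function(e)
    pairSetAdjacency(querySet, sets[[e]], net, cfg), numeric(1L)))
}

#' Weighted geometric mean of two non-negative scores
#'
#' Combines a drug-side and a disease-side score into one:
#' \code{a^w1 * b^w2} with the configured weights (default equal, i.e. the
#' plain geometric mean \code{sqrt(a*b)}). Returns 0 whenever either input
#' is 0.
#'
#' @param a,b non-negative scores.
#' @param weights two non-negative weights summing to 1.
#' @return a single non-negative number.
#' @export
combineGeometric <- function(a, b, weights = c(0.5, 0.5)) {
  if (any(c(a, b) < 0)) stop("scores must be non-negative")
  if (a == 0 || b == 0) return(0)
  a^weights[1L] * b^weights[2L]
}
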