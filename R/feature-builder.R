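FEATURE_SCHEMA <- "netRepurpose-features/1"

#' Canonical names of the 30 pair features
#'
#' Three adjacency-based features (\code{adj_drug}, \code{adj_disease} and
#' their geometric-mean combination) followed by 27 module-distance features:
#' for every module level \code{v} in 0:2 and path-length parameter \code{k}
#' in 0:2, the best d-module score, the best p-module score and their
#' combination. The order is fixed and versioned
#' (schema \code{netRepurpose-features/1}).
#'
#' @return character vector of length 30.
#' @export
featureNames <- function() {
  grid <- expand.grid(k = 0:2, v = 0:2)    # v-major, k-minor
  mods <- unlist(lapply(seq_len(nrow(grid)), function(i)
    sprintf("%s_v%d_k%d", c("dmod", "pmod", "comb"),
            grid$v[i], grid$k[i])))
  c("adj_drug", "adj_disease", "adj_combined", mods)
}

# Precompute index sets, neighborhoods and per-pair caches once, then score
# many (drug, disease) pairs cheaply. Returns a closure environment.
featureScorer <- function(drugs, diseases, assoc, net, cfg) {
  vnames <- igraph::V(net@graph)$name
  dSets <- lapply(nodeSets(drugs), function(s) match(s, vnames))
  pSets <- lapply(nodeSets(diseases), function(s) match(s, vnames))
  if (anyNA(unlist(dSets)) || anyNA(unlist(pSets)))
    stop("catalog references nodes absent from the network")
  nbhds <- function(sets) lapply(0:2, function(v)
    lapply(sets, function(idx) neighborhoodIdx(net, idx, v)))
  dNb <- nbhds(dSets); pNb <- nbhds(pSets)
  omega <- pathScore(cfg, 0:2)
  w <- cfg@combineWeights
  adjCache <- new.env(hash = TRUE, parent = emptyenv())
  modCache <- new.env(hash = TRUE, parent = emptyenv())

  setAdj <- function(i1, i2, side) {
    # side-tagged cache key, unordered entity pair
    k <- paste(side, min(i1$id, i2$id), max(i1$id, i2$id))
    hit <- adjCache[[k]]
    if (!is.null(hit)) return(hit)
    counts <- bucketCountsIdx(net, i1$set, i2$set)
    val <- sum(counts * omega) / (length(i1$set) * length(i2$set))
    adjCache[[k]] <- val
    val
  }
  moduleCounts <- function(nbA, nbB, v, id1, id2, side, targetIdx, tkey) {
    mkey <- paste(side, v, min(id1, id2), max(id1, id2), tkey)
    hit <- modCache[[mkey]]
    if (!is.null(hit)) return(hit)
    M <- nbA[nbA %in% nbB]
    val <- if (length(M) == 0L) c(0, 0, 0) else
      bucketCountsIdx(net, M, targetIdx) * omega /
        (length(M) * length(targetIdx))
    modCache[[mkey]] <- val
    val
  }
  combine2 <- function(a, b) ifelse(a == 0 | b == 0, 0, a^w[1L] * b^w[2L])

  scoreOne <- function(d, p, excludeSelf = TRUE) {
    Td <- dSets[[d]]; Tp <- pSets[[p]]
    if (is.null(Td)) stop("unknown drug: ", d)
    if (is.null(Tp)) stop("unknown disease: ", p)
    candD <- knownDrugs(assoc, p)
    candP <- knownDiseases(assoc, d)
    if (excludeSelf) {            # drop the evaluated pair itself
      candD <- setdiff(candD, d)
      candP <- setdiff(candP, p)
    }
    candD <- candD[candD %in% names(dSets)]
    candP <- candP[candP %in% names(pSets)]

    di <- match(d, names(dSets)); pi <- match(p, names(pSets))
    adjD <- if (length(candD)) max(vapply(candD, function(e)
      setAdj(list(id = di, set = Td),
             list(id = match(e, names(dSets)), set = dSets[[e]]),
             "d"), numeric(1L))) else 0
    adjP <- if (length(candP)) max(vapply(candP, function(e)
      setAdj(list(id = pi, set = Tp),
             list(id = match(e, names(pSets)), set = pSets[[e]]),
             "p"), numeric(1L))) else 0

    modBlock <- numeric(27L)
    pos <- 1L
    for (v in 0:2) {
      dmax <- c(0, 0, 0); pmax <- c(0, 0, 0)
      for (e in candD) {
        ei <- match(e, names(dSets))
        val <- moduleCounts(dNb[[v + 1L]][[di]], dNb[[v + 1L]][[ei]], v,
                            di, ei, "d", Tp, pi)
        dmax <- pmax.int(dmax, val)
      }
      for (e in candP) {
        ei <- match(e, names(pSets))
        val <- moduleCounts(pNb[[v + 1L]][[pi]], pNb[[v + 1L]][[ei]], v,
                            pi, ei, "p", Td, di)
        pmax <- pmax.int(pmax, val)
      }
      for (k in 0:2) {
        modBlock[pos:(pos + 2L)] <-
          c(dmax[k + 1L], pmax[k + 1L],
            combine2(dmax[k + 1L], pmax[k + 1L]))
        pos <- pos + 3L
      }
    }
    setNames(c(adjD, adjP, combine2(adjD, adjP), modBlock), featureNames())
  }
  scoreOne
}

#' Compute the 30-feature vector of one drug-disease pair
#'
#' Three adjacency features (best drug-drug and disease-disease adjacency
#' against the pair's known partners, plus their geometric-mean combination)
#' and 27 module-distance features (best d-module, best p-module and their
#' combination over the 3x3 grid of module level v and path length k). With
#' \code{excludeSelf = TRUE} (the default, and what training positives use)
#' the pair itself is removed from the known-association indices before
#' scoring, so a known positive never anchors its own features.
#'
#' @param d,p drug and disease identifiers retained in the catalogs.
#' @param drugs,diseases \linkS4class{EntityCatalog}s.
#' @param assoc an \linkS4class{AssociationSet}.
#' @param net,cfg network and path-score configuration.
#' @param excludeSelf logical; see above.
#' @return named numeric vector of length 30, all entries >= 0.
#' @export
buildFeatureVector <- function(d, p, drugs, diseases, assoc, net, cfg,
                               excludeSelf = TRUE) {
  featureScorer(drugs, diseases, assoc, net, cfg)(d, p, excludeSelf)
}

# Bulk feature computation with a shared scorer; pairs is a data.frame with
# drug/disease columns. Returns an npairs x 30 matrix.
featureTable <- function(pairs, drugs, diseases, assoc, net, cfg,
                         excludeSelf = TRUE, scorer = NULL) {
  if (is.null(scorer)) scorer <- featureScorer(drugs, diseases, assoc, net, cfg)
  out <- matrix(0, nrow(pairs), 30L,
                dimnames = list(NULL, featureNames()))
  for (i in seq_len(nrow(pairs)))
    out[i, ] <- scorer(pairs$drug[i], pairs$disease[i], excludeSelf)
  out
}

#' Sample random negative drug-disease pairs
#'
#' Draws \code{n} pairs uniformly without replacement from the Cartesian
#' product of the drugs and diseases appearing in the positive set, minus
#' the positives themselves. Reproducible given \code{seed}; the caller's
#' RNG state is untouched.
#'
#' @param assoc the positive \linkS4class{AssociationSet}.
#' @param n number of negatives (default: the number of positives, giving a
#'   balanced set).
#' @param seed integer seed.
#' @return data.frame with columns \code{drug}, \code{disease}.
#' @export
sampleNegatives <- function(assoc, n = NULL, seed) {
  pos <- associationPairs(assoc)
  if (is.null(n)) n <- nrow(pos)
  if (n < 1L) stop("'n' must be >= 1")
  pool <- expand.grid(drug = sort(unique(pos$drug)),
                      disease = sort(unique(pos$disease)),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pool <- pool[!pairKey(pool$drug, pool$disease) %in%
                 pairKey(pos$drug, pos$disease), , drop = FALSE]
  if (nrow(pool) < n)
    stop("candidate pool (", nrow(pool), ") smaller than requested n = ", n)
  idx <- withSeed(seed, sample.int(nrow(pool), n))
  out <- pool[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a balanced labeled training matrix
#'
#' Computes the 30 features for every known positive association (with
#' self-exclusion on, so the evaluated pair never anchors its own score) and
#' for an equally sized random negative sample, and assembles them into a
#' \linkS4class{DrugDiseaseFeatures} object (features x pairs). Byte-level
#' reproducible given \code{seed}.
#'
#' @param drugs,diseases \linkS4class{EntityCatalog}s.
#' @param assoc the positive \linkS4class{AssociationSet}.
#' @param net,cfg network and path-score configuration.
#' @param seed integer seed for negative sampling.
#' @param negatives optional pre-drawn negative pair data.frame (overrides
#'   sampling).
#' @return a \linkS4class{DrugDiseaseFeatures}.
#' @export
buildTrainingMatrix <- function(drugs, diseases, assoc, net, cfg, seed = 1,
                                negatives = NULL) {
  pos <- associationPairs(assoc)
  if (nrow(pos) == 0L) stop("positive set is empty")
  if (is.null(negatives)) negatives <- sampleNegatives(assoc, seed = seed)
  scorer <- featureScorer(drugs, diseases, assoc, net, cfg)
  fpos <- featureTable(pos, drugs, diseases, assoc, net, cfg,
                       excludeSelf = TRUE, scorer = scorer)
  fneg <- featureTable(negatives, drugs, diseases, assoc, net, cfg,
                       excludeSelf = TRUE, scorer = scorer)
  pairs <- rbind(pos[, c("drug", "disease")],
                 negatives[, c("drug", "disease")])
  label <- rep(c("positive", "negative"), c(nrow(pos), nrow(negatives)))
  newDrugDiseaseFeatures(t(rbind(fpos, fneg)), pairs, label, seed)
}

newDrugDiseaseFeatures <- function(featMat, pairs, label, seed = NA) {
  colnames(featMat) <- pairKey(pairs$drug, pairs$disease)
  grid <- expand.grid(k = 0:2, v = 0:2)
  rd <- S4Vectors::DataFrame(
    method = c(rep("adjacency", 3L),
               rep(c("d-module", "p-module", "combined"), 9L)),
    v = c(rep(NA_integer_, 3L), rep(grid$v, each = 3L)),
    k = c(rep(NA_integer_, 3L), rep(grid$k, each = 3L)),
    row.names = featureNames())
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = featMat),
    rowData = rd,
    colData = S4Vectors::DataFrame(drug = pairs$drug, disease = pairs$disease,
                                   label = label,
                                   row.names = colnames(featMat)),
    metadata = list(schema = FEATURE_SCHEMA, negativeSeed = seed))
  new("DrugDiseaseFeatures", se)
}

#' @describeIn DrugDiseaseFeatures pairs-by-features numeric matrix (the
#'   classifier orientation).
#' @param x a \linkS4class{DrugDiseaseFeatures}.
#' @export
setMethod("featureMatrix", "DrugDiseaseFeatures", function(x)
  t(SummarizedExperiment::assay(x, "features")))

#' @describeIn DrugDiseaseFeatures pair labels as a factor with levels
#'   \code{negative}, \code{positive}.
#' @export
setMethod("pairLabels", "DrugDiseaseFeatures", function(x)
  factor(SummarizedExperiment::colData(x)$label,
         levels = c("negative", "positive")))

#' @describeIn DrugDiseaseFeatures data.frame of drug, disease, label.
#' @export
setMethod("pairInfo", "DrugDiseaseFeatures", function(x)
  as.data.frame(SummarizedExperiment::colData(x)))

#' Write a feature matrix as CSV
#'
#' One row per pair: drug, disease, the 30 named features, label. A comment
#' header records the schema version and negative-sampling seed.
#'
#' @param x a \linkS4class{DrugDiseaseFeatures}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeFeatureCSV <- function(x, path) {
  info <- pairInfo(x)
  df <- cbind(info[, c("drug", "disease")],
              as.data.frame(featureMatrix(x)), label = info$label)
  md <- S4Vectors::metadata(x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# schema=%s negative_seed=%s", md$schema,
                     format(md$negativeSeed)), con)
  write.table(format(df, digits = 15, trim = TRUE, scientific = FALSE),
              con, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a feature matrix in ARFF format
#'
#' Weka-compatible export with numeric feature attributes and a nominal
#' \code{class \{positive,negative\}} attribute.
#'
#' @param x a \linkS4class{DrugDiseaseFeatures}.
#' @param path output path.
#' @param relation ARFF relation name.
#' @return the path, invisibly.
#' @export
writeFeatureARFF <- function(x, path, relation = "drug_disease_features") {
  m <- featureMatrix(x)
  lab <- as.character(pairLabels(x))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("@relation", relation), con)
  writeLines(sprintf("@attribute %s numeric", colnames(m)), con)
  writeLines("@attribute class {positive,negative}", con)
  writeLines("@data", con)
  writeLines(paste(apply(m, 1L, function(r)
    paste(format(r, digits = 15, trim = TRUE, scientific = FALSE),
          collapse = ",")), lab, sep = ","), con)
  invisible(path)
}
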