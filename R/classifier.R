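#' Area under the ROC curve via the Mann-Whitney statistic
#'
#' The probability that a randomly chosen positive outscores a randomly
#' chosen negative, with ties counted one half — computed from midranks, so
#' it equals trapezoidal integration of the ROC curve exactly.
#'
#' @param scores numeric classifier scores.
#' @param labels logical, 0/1, or factor/character with \code{"positive"}
#'   marking positives.
#' @return AUC in \code{[0, 1]}.
#' @examples
#' computeAUC(c(0.9, 0.4, 0.5, 0.1), c(1, 1, 0, 0))  # 0.75
#' @export
computeAUC <- function(scores, labels) {
  pos <- if (is.logical(labels)) labels
         else if (is.numeric(labels)) labels > 0
         else as.character(labels) == "positive"
  nPos <- sum(pos); nNeg <- sum(!pos)
  if (nPos == 0L || nNeg == 0L)
    stop("both classes must be present to compute an AUC")
  r <- rank(scores)              # midranks handle ties as 0.5 wins
  (sum(r[pos]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Classifier backends behind a common fit/score contract
#'
#' Returns a backend object with \code{fit(x, y)} (numeric matrix, factor
#' with levels negative/positive) returning a model, and
#' \code{score(model, x)} returning the positive-class score per row.
#' Available backends: \code{"tree"} (a C4.5-style decision tree via
#' \pkg{rpart}), \code{"forest"} (\pkg{randomForest}), \code{"mlp"}
#' (single-hidden-layer perceptron via \pkg{nnet}; size 8, decay 5e-4),
#' \code{"constant"} (uninformative baseline scoring 0.5 everywhere) and
#' \code{"oracle"} (diagnostic backend that outputs the true label as the
#' score; only usable inside [repeatedCV()], which attaches held-out labels
#' for backends flagged \code{usesTruth}).
#'
#' @param name backend name.
#' @param seed integer seed for stochastic learners.
#' @return a list with elements \code{name}, \code{fit}, \code{score},
#'   \code{usesTruth}.
#' @export
classifierBackend <- function(name = c("forest", "tree", "mlp", "constant",
                                       "oracle"), seed = 1) {
  name <- match.arg(name)
  backend <- switch(name,
    tree = list(
      fit = function(x, y) {
        df <- data.frame(x, .label = y, check.names = FALSE)
        rpart::rpart(.label ~ ., data = df, method = "class")
      },
      score = function(model, x)
        predict(model, data.frame(x, check.names = FALSE))[, "positive"]),
    forest = list(
      fit = function(x, y) withSeed(seed,
        randomForest::randomForest(x, y, ntree = 500L)),
      score = function(model, x)
        predict(model, x, type = "prob")[, "positive"]),
    mlp = list(
      fit = function(x, y) withSeed(seed,
        nnet::nnet(x, as.numeric(y == "positive"), size = 8L,
                   decay = 5e-4, maxit = 200L, trace = FALSE)),
      score = function(model, x) as.numeric(predict(model, x))),
    constant = list(
      fit = function(x, y) NULL,
      score = function(model, x) rep(0.5, nrow(x))),
    oracle = list(
      fit = function(x, y) NULL,
      score = function(model, x) {
        truth <- attr(x, "truth")
        if (is.null(truth)) stop("oracle backend needs attached truth")
        as.numeric(truth == "positive")
      }))
  backend$name <- name
  backend$usesTruth <- name == "oracle"
  backend
}

#' Train a backend on a labeled feature matrix
#'
#' @param backend a backend from [classifierBackend()].
#' @param training a \linkS4class{DrugDiseaseFeatures}.
#' @param features optional character subset of [featureNames()] to train on.
#' @return a fitted model wrapper usable with [predictCandidates()].
#' @export
trainModel <- function(backend, training, features = featureNames()) {
  x <- featureMatrix(training)[, features, drop = FALSE]
  y <- pairLabels(training)
  list(backend = backend, model = backend$fit(x, y), features = features)
}

# Stratified fold ids: labels shuffled within each class, folds balanced.
stratifiedFolds <- function(labels, folds, seed) {
  ids <- integer(length(labels))
  withSeed(seed, for (cl in unique(labels)) {
    i <- which(labels == cl)
    ids[i] <- sample(rep_len(seq_len(folds), length(i)))
  })
  ids
}

#' Repeated stratified cross-validation with fresh negative sets
#'
#' Runs k-fold cross-validation \code{repeats} times. Each repeat draws a
#' fresh random negative sample (same size as the positive set), computes
#' the feature matrix, partitions it into label-stratified folds, trains on
#' k-1 folds and scores the held-out fold; the repeat AUC is the mean of its
#' fold AUCs (or the AUC of the pooled held-out scores with
#' \code{pooled = TRUE}) and the grand mean averages the repeat AUCs.
#' Fully reproducible given \code{seed}.
#'
#' With \code{strictCV = TRUE} the features of each fold's pairs are
#' recomputed with all of that fold's positives removed from the
#' known-association indexes, so no test positive anchors any training or
#' test feature. The default (\code{FALSE}) excludes only the evaluated pair
#' itself, the most literal reading of the training protocol.
#'
#' @param drugs,diseases \linkS4class{EntityCatalog}s.
#' @param assoc the positive \linkS4class{AssociationSet}.
#' @param net,cfg network and path-score configuration.
#' @param backend a backend from [classifierBackend()] or a backend name.
#' @param folds,repeats cross-validation shape (default 10 x 10).
#' @param seed master seed; negative-sampling and fold seeds derive from it.
#' @param features optional feature-name subset (ablation runs).
#' @param strictCV logical, see above.
#' @param pooled logical; pool held-out scores per repeat instead of
#'   averaging fold AUCs.
#' @return a \linkS4class{CVResult}.
#' @export
repeatedCV <- function(drugs, diseases, assoc, net, cfg,
                       backend = "forest", folds = 10L, repeats = 10L,
                       seed = 1, features = featureNames(),
                       strictCV = FALSE, pooled = FALSE) {
  if (is.character(backend)) backend <- classifierBackend(backend, seed = seed)
  pos <- associationPairs(assoc)
  if (nrow(pos) < folds) stop("need at least ", folds, " positive pairs")
  scorer <- featureScorer(drugs, diseases, assoc, net, cfg)
  fpos <- featureTable(pos, drugs, diseases, assoc, net, cfg,
                       excludeSelf = TRUE, scorer = scorer)
  foldAUCs <- matrix(NA_real_, repeats, folds)
  repAUCs <- numeric(repeats)
  negSeeds <- vapply(seq_len(repeats), function(r) deriveSeed(seed, r),
                     numeric(1L))
  foldSeed <- deriveSeed(seed, 0L)
  igAccum <- NULL

  for (r in seq_len(repeats)) {
    neg <- sampleNegatives(assoc, seed = negSeeds[r])
    fneg <- featureTable(neg, drugs, diseases, assoc, net, cfg,
                         excludeSelf = TRUE, scorer = scorer)
    x <- rbind(fpos, fneg)[, features, drop = FALSE]
    y <- factor(rep(c("positive", "negative"), c(nrow(fpos), nrow(fneg))),
                levels = c("negative", "positive"))
    fid <- stratifiedFolds(y, folds, deriveSeed(foldSeed, r))
    if (is.null(igAccum)) igAccum <- informationGain(x, y)

    pooledScores <- numeric(0); pooledTruth <- character(0)
    for (f in seq_len(folds)) {
      test <- fid == f
      xtr <- x[!test, , drop = FALSE]; xte <- x[test, , drop = FALSE]
      if (strictCV) {
        # rebuild held-out features with this fold's positives unknown
        foldPos <- pos[test[seq_len(nrow(pos))], , drop = FALSE]
        keep <- !pairKey(pos$drug, pos$disease) %in%
          pairKey(foldPos$drug, foldPos$disease)
        redAssoc <- newAssociationSet(pos[keep, , drop = FALSE])
        allPairs <- rbind(pos, neg[, c("drug", "disease")])
        xs <- featureTable(allPairs, drugs, diseases, redAssoc, net, cfg,
                           excludeSelf = TRUE)[, features, drop = FALSE]
        xtr <- xs[!test, , drop = FALSE]; xte <- xs[test, , drop = FALSE]
      }
      fit <- tryCatch(backend$fit(xtr, y[!test]), error = function(e)
        stop("backend '", backend$name, "' failed in repeat ", r,
             ", fold ", f, ": ", conditionMessage(e)))
      if (backend$usesTruth) attr(xte, "truth") <- as.character(y[test])
      s <- backend$score(fit, xte)
      foldAUCs[r, f] <- computeAUC(s, y[test])
      pooledScores <- c(pooledScores, s)
      pooledTruth <- c(pooledTruth, as.character(y[test]))
    }
    repAUCs[r] <- if (pooled) computeAUC(pooledScores, pooledTruth)
                  else mean(foldAUCs[r, ])
  }

  new("CVResult", backend = backend$name, foldAUCs = foldAUCs,
      repeatAUCs = repAUCs, foldSeed = foldSeed, negativeSeeds = negSeeds,
      config = list(folds = folds, repeats = repeats, seed = seed,
                    features = features, strictCV = strictCV,
                    pooled = pooled, base = cfg@base, mode = cfg@mode,
                    allowedLengths = cfg@allowedLengths),
      infoGain = igAccum)
}

# Information gain of each feature for the class label, after
# equal-frequency discretization into at most `bins` bins. Diagnostic only.
informationGain <- function(x, y, bins = 10L) {
  H <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  base <- H(table(y) / length(y))
  ig <- vapply(seq_len(ncol(x)), function(j) {
    v <- x[, j]
    br <- unique(stats::quantile(v, probs = seq(0, 1, length.out = bins + 1L)))
    b <- if (length(br) < 2L) factor(rep(1L, length(v)))
         else cut(v, breaks = br, include.lowest = TRUE)
    cond <- sum(vapply(levels(b), function(l) {
      i <- b == l
      sum(i) / length(v) * H(table(y[i]) / sum(i))
    }, numeric(1L)))
    base - cond
  }, numeric(1L))
  out <- data.frame(feature = colnames(x), infoGain = ig,
                    stringsAsFactors = FALSE)
  out[order(-out$infoGain), , drop = FALSE]
}

#' @describeIn CVResult grand mean AUC over the repeats.
#' @param x a \linkS4class{CVResult}.
#' @export
setMethod("meanAUC", "CVResult", function(x) mean(x@repeatAUCs))

#' @describeIn CVResult per-repeat AUC vector.
#' @export
setMethod("repeatAUCs", "CVResult", function(x) x@repeatAUCs)

setMethod("show", "CVResult", function(object) {
  cat(sprintf("CVResult: %s backend, %d x %d-fold CV\n", object@backend,
              nrow(object@foldAUCs), ncol(object@foldAUCs)))
  cat(sprintf("  grand mean AUC: %.4f (repeat range %.4f-%.4f)\n",
              meanAUC(object), min(object@repeatAUCs),
              max(object@repeatAUCs)))
})

#' Serialize a CVResult as JSON
#'
#' Writes all repeat and fold AUCs, the seeds and a configuration echo.
#'
#' @param x a \linkS4class{CVResult}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeCVResult <- function(x, path) {
  jsonlite::write_json(list(
    backend = x@backend, grand_mean_auc = meanAUC(x),
    repeat_aucs = x@repeatAUCs,
    fold_aucs = apply(x@foldAUCs, 1L, identity, simplify = FALSE),
    fold_seed = x@foldSeed, negative_seeds = x@negativeSeeds,
    config = x@config,
    info_gain = x@infoGain), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Score and rank candidate drug-disease pairs
#'
#' Scores every candidate pair with a trained model and returns them sorted
#' by decreasing score with a thresholded prediction flag. Known positives
#' are always excluded from the candidate rows; by default the candidate
#' set is all catalog drugs x diseases minus the known positives.
#'
#' @param model a fitted model from [trainModel()].
#' @param drugs,diseases \linkS4class{EntityCatalog}s.
#' @param assoc the known \linkS4class{AssociationSet}.
#' @param net,cfg network and path-score configuration.
#' @param candidates optional data.frame (drug, disease) restricting the
#'   candidate set.
#' @param threshold score at or above which \code{predicted} is
#'   \code{"yes"}.
#' @return data.frame (drug, disease, score, predicted) sorted by score
#'   descending.
#' @export
predictCandidates <- function(model, drugs, diseases, assoc, net, cfg,
                              candidates = NULL, threshold = 0.5) {
  if (is.null(candidates))
    candidates <- expand.grid(drug = entityIds(drugs),
                              disease = entityIds(diseases),
                              KEEP.OUT.ATTRS = FALSE,
                              stringsAsFactors = FALSE)
  pos <- associationPairs(assoc)
  keep <- !pairKey(candidates$drug, candidates$disease) %in%
    pairKey(pos$drug, pos$disease)
  candidates <- candidates[keep, , drop = FALSE]
  if (nrow(candidates) == 0L)
    return(data.frame(drug = character(), disease = character(),
                      score = numeric(), predicted = character(),
                      stringsAsFactors = FALSE))
  x <- featureTable(candidates, drugs, diseases, assoc, net, cfg,
                    excludeSelf = FALSE)
  if (!all(model$features %in% colnames(x)))
    stop("feature schema mismatch between model and candidates")
  x <- x[, model$features, drop = FALSE]
  s <- model$backend$score(model$model, x)
  out <- data.frame(drug = candidates$drug, disease = candidates$disease,
                    score = s,
                    predicted = ifelse(s >= threshold, "yes", "no"),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$drug, out$disease), , drop = FALSE]
  rownames(out) <- NULL
  out
}
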