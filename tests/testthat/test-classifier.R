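test_that("AUC follows the Mann-Whitney statistic with tied midranks", {
  expect_equal(computeAUC(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(computeAUC(rep(0.3, 6), c(1, 1, 1, 0, 0, 0)), 0.5)
  expect_equal(computeAUC(c(0.9, 0.4, 0.5, 0.1), c(1, 1, 0, 0)), 0.75)
  expect_error(computeAUC(c(0.1, 0.2), c(1, 1)), "both classes")
})

test_that("AUC agrees with ROC-curve integration to 1e-12", {
  withr::with_seed(42, for (i in 1:40) {
    n <- sample(10:60, 1)
    lab <- sample(c(0, 1), n, replace = TRUE)
    if (length(unique(lab)) < 2) next
    s <- round(runif(n), sample(1:3, 1))   # force ties sometimes
    ref <- as.numeric(pROC::auc(pROC::roc(lab, s, quiet = TRUE,
                                          direction = "<")))
    expect_equal(computeAUC(s, lab), ref, tolerance = 1e-12)
  })
})

test_that("oracle and constant backends bracket the CV machinery", {
  bench <- simulateBenchmark(smallBenchSpec())
  cfg <- fixedCfg()
  cvO <- repeatedCV(bench$drugs, bench$diseases, bench$assoc, bench$net,
                    cfg, backend = "oracle", folds = 5, repeats = 2,
                    seed = 9)
  expect_equal(meanAUC(cvO), 1.0)
  cvC <- repeatedCV(bench$drugs, bench$diseases, bench$assoc, bench$net,
                    cfg, backend = "constant", folds = 5, repeats = 2,
                    seed = 9)
  expect_equal(meanAUC(cvC), 0.5)
  expect_equal(dim(cvC@foldAUCs), c(2L, 5L))
  expect_equal(meanAUC(cvC), mean(repeatAUCs(cvC)))
})

test_that("repeated CV is reproducible and stratification fills folds", {
  bench <- simulateBenchmark(smallBenchSpec())
  cfg <- fixedCfg()
  cv1 <- repeatedCV(bench$drugs, bench$diseases, bench$assoc, bench$net,
                    cfg, backend = "tree", folds = 5, repeats = 2, seed = 4)
  cv2 <- repeatedCV(bench$drugs, bench$diseases, bench$assoc, bench$net,
                    cfg, backend = "tree", folds = 5, repeats = 2, seed = 4)
  expect_identical(cv1@foldAUCs, cv2@foldAUCs)
  expect_identical(repeatAUCs(cv1), repeatAUCs(cv2))
  expect_true(all(is.finite(cv1@foldAUCs)))  # every fold had both classes
  expect_false(identical(cv1@negativeSeeds[1], cv1@negativeSeeds[2]))
})

test_that("tree, forest and mlp backends train and score in [0, 1]", {
  bench <- simulateBenchmark(smallBenchSpec())
  cfg <- fixedCfg()
  tm <- buildTrainingMatrix(bench$drugs, bench$diseases, bench$assoc,
                            bench$net, cfg, seed = 1)
  for (b in c("tree", "forest", "mlp")) {
    model <- trainModel(classifierBackend(b, seed = 1), tm)
    s <- model$backend$score(model$model, featureMatrix(tm))
    expect_length(s, nrow(featureMatrix(tm)))
    expect_true(all(s >= -1e-9 & s <= 1 + 1e-9))
  }
})

test_that("candidate prediction excludes known pairs and applies threshold", {
  net <- chainNet(c("A", "B", "C", "D", "E", "F"))
  drugTab <- data.frame(id = rep(sprintf("d%d", 1:5), each = 2),
                        n = c("A","B", "B","C", "C","D", "D","E", "E","F"))
  disTab <- data.frame(id = rep(sprintf("p%d", 1:4), each = 2),
                       n = c("A","C", "B","D", "C","E", "D","F"))
  assocTab <- data.frame(d = c("d1", "d2", "d3"), p = c("p1", "p2", "p3"))
  cats <- loadCatalogs(drugTab, disTab, assocTab, net)
  cfg <- fixedCfg()
  tm <- buildTrainingMatrix(cats$drugs, cats$diseases, cats$assoc, net,
                            cfg, seed = 1)
  model <- trainModel(classifierBackend("tree"), tm)
  pt <- predictCandidates(model, cats$drugs, cats$diseases, cats$assoc,
                          net, cfg)
  expect_equal(nrow(pt), 5L * 4L - 3L)                 # 20 pairs minus known
  expect_true(all(diff(pt$score) <= 1e-12))            # sorted descending
  expect_identical(pt$predicted, ifelse(pt$score >= 0.5, "yes", "no"))

  ptNone <- predictCandidates(model, cats$drugs, cats$diseases, cats$assoc,
                              net, cfg, threshold = 1.01)
  expect_equal(sum(ptNone$predicted == "yes"), 0L)

  ptKnown <- predictCandidates(model, cats$drugs, cats$diseases, cats$assoc,
                               net, cfg,
                               candidates = associationPairs(cats$assoc))
  expect_equal(nrow(ptKnown), 0L)
})

test_that("information gain ranks a label-aligned feature first", {
  withr::with_seed(8, {
    y <- factor(rep(c("negative", "positive"), each = 50))
    x <- cbind(signal = as.numeric(y == "positive") + rnorm(100, sd = 0.1),
               noise1 = rnorm(100), noise2 = rnorm(100))
  })
  ig <- netRepurpose:::informationGain(x, y)
  expect_equal(ig$feature[1L], "signal")
  expect_true(all(ig$infoGain >= -1e-9))
})
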