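test_that("every pair yields the 30-feature schema with 27 module scores", {
  tc <- tinyCatalogs()
  fv <- buildFeatureVector("d1", "p2", tc$drugs, tc$diseases, tc$assoc,
                           tc$net, tc$cfg)
  expect_length(fv, 30L)
  expect_identical(names(fv), featureNames())
  expect_true(all(fv >= 0))
  expect_length(grep("^(dmod|pmod|comb)_v[0-2]_k[0-2]$", names(fv)), 27L)
})

test_that("combined features are the geometric mean of their two sides", {
  bench <- simulateBenchmark(smallBenchSpec())
  cfg <- fixedCfg()
  pairs <- utils::head(associationPairs(bench$assoc), 5L)
  for (i in seq_len(nrow(pairs))) {
    fv <- buildFeatureVector(pairs$drug[i], pairs$disease[i], bench$drugs,
                             bench$diseases, bench$assoc, bench$net, cfg)
    expect_equal(fv[["adj_combined"]],
                 combineGeometric(fv[["adj_drug"]], fv[["adj_disease"]]))
    for (v in 0:2) for (k in 0:2) {
      expect_equal(fv[[sprintf("comb_v%d_k%d", v, k)]],
                   combineGeometric(fv[[sprintf("dmod_v%d_k%d", v, k)]],
                                    fv[[sprintf("pmod_v%d_k%d", v, k)]]))
    }
  }
})

test_that("pairs with no anchors and unreachable sets score all-zero", {
  # two disconnected components; the only association links the far pair
  net <- loadNetwork(data.frame(a = c("A", "B", "X", "Y"),
                                b = c("B", "C", "Y", "Z")))
  cats <- loadCatalogs(
    data.frame(id = c("d1", "d1"), n = c("A", "B")),
    data.frame(id = c("p1", "p1"), n = c("X", "Y")),
    data.frame(d = "d1", p = "p1"),
    net)
  fv <- buildFeatureVector("d1", "p1", cats$drugs, cats$diseases,
                           cats$assoc, net, fixedCfg(), excludeSelf = TRUE)
  expect_true(all(fv == 0))
})

test_that("negative sampling is seeded, disjoint from positives, balanced", {
  bench <- simulateBenchmark(smallBenchSpec())
  n1 <- sampleNegatives(bench$assoc, seed = 5)
  n2 <- sampleNegatives(bench$assoc, seed = 5)
  expect_identical(n1, n2)
  pos <- associationPairs(bench$assoc)
  expect_equal(nrow(n1), nrow(pos))
  expect_length(intersect(paste(n1$drug, n1$disease),
                          paste(pos$drug, pos$disease)), 0L)
  expect_false(anyDuplicated(paste(n1$drug, n1$disease)) > 0)
  expect_error(sampleNegatives(bench$assoc, n = 10000, seed = 1),
               "smaller than")
})

test_that("training matrices are balanced, labeled and reproducible", {
  bench <- simulateBenchmark(smallBenchSpec())
  cfg <- fixedCfg()
  tm <- buildTrainingMatrix(bench$drugs, bench$diseases, bench$assoc,
                            bench$net, cfg, seed = 2)
  expect_s4_class(tm, "DrugDiseaseFeatures")
  lab <- pairLabels(tm)
  expect_equal(sum(lab == "positive"), sum(lab == "negative"))
  expect_equal(nrow(featureMatrix(tm)),
               2L * nrow(associationPairs(bench$assoc)))
  expect_identical(colnames(featureMatrix(tm)), featureNames())

  tm2 <- buildTrainingMatrix(bench$drugs, bench$diseases, bench$assoc,
                             bench$net, cfg, seed = 2)
  f1 <- tempfile(); f2 <- tempfile()
  writeFeatureCSV(tm, f1); writeFeatureCSV(tm2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("feature values do not depend on input table row order", {
  bench <- simulateBenchmark(smallBenchSpec())
  tabs <- bench$tables
  shuffled <- loadCatalogs(
    withr::with_seed(1, tabs$drugs[sample.int(nrow(tabs$drugs)), ]),
    withr::with_seed(2, tabs$diseases[sample.int(nrow(tabs$diseases)), ]),
    withr::with_seed(3,
      tabs$associations[sample.int(nrow(tabs$associations)), ]),
    bench$net)
  cfg <- fixedCfg()
  pr <- utils::head(associationPairs(bench$assoc), 4L)
  for (i in seq_len(nrow(pr))) {
    a <- buildFeatureVector(pr$drug[i], pr$disease[i], bench$drugs,
                            bench$diseases, bench$assoc, bench$net, cfg)
    b <- buildFeatureVector(pr$drug[i], pr$disease[i], shuffled$drugs,
                            shuffled$diseases, shuffled$assoc, bench$net,
                            cfg)
    expect_equal(a, b)
  }
})

test_that("planted proximity separates drug-side scores of positives", {
  bench <- simulateBenchmark(benchmarkSpec())
  cfg <- fixedCfg()
  pos <- associationPairs(bench$assoc)
  neg <- sampleNegatives(bench$assoc, seed = 11)
  dS <- nodeSets(bench$drugs); pS <- nodeSets(bench$diseases)
  direct <- function(pr) vapply(seq_len(nrow(pr)), function(i)
    pairSetAdjacency(dS[[pr$drug[i]]], pS[[pr$disease[i]]], bench$net, cfg),
    numeric(1))
  # targets of positive pairs sit closer to their disease genes
  expect_lt(stats::wilcox.test(direct(pos), direct(neg),
                               alternative = "greater")$p.value, 0.01)
  tm <- buildTrainingMatrix(bench$drugs, bench$diseases, bench$assoc,
                            bench$net, cfg, seed = 1)
  fm <- featureMatrix(tm); lab <- pairLabels(tm)
  expect_gt(mean(fm[lab == "positive", "adj_drug"]),
            mean(fm[lab == "negative", "adj_drug"]))
  expect_gt(mean(fm[lab == "positive", "dmod_v1_k0"]),
            mean(fm[lab == "negative", "dmod_v1_k0"]))
})

test_that("ARFF export carries 30 numeric attributes and the class", {
  bench <- simulateBenchmark(smallBenchSpec())
  tm <- buildTrainingMatrix(bench$drugs, bench$diseases, bench$assoc,
                            bench$net, fixedCfg(), seed = 1)
  f <- tempfile(fileext = ".arff")
  writeFeatureARFF(tm, f)
  lines <- readLines(f)
  expect_length(grep("^@attribute .* numeric$", lines), 30L)
  expect_true("@attribute class {positive,negative}" %in% lines)
  expect_equal(sum(lines == "@data"), 1L)
  dataLines <- lines[(which(lines == "@data") + 1L):length(lines)]
  expect_length(dataLines, nrow(featureMatrix(tm)))
})
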