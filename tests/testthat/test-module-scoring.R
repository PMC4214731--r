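test_that("common modules are neighborhood intersections", {
  net <- chainNet(c("A", "B", "C"))
  expect_equal(commonModule("A", "A", 0, net), "A")
  expect_equal(commonModule("A", "C", 1, net), "B")
  expect_equal(commonModule("A", "C", 0, net), character())
  expect_error(commonModule("A", "C", 5, net), "v")
})

test_that("module growth is monotone in the level parameter", {
  for (seed in 1:5) {
    rn <- randomNet(60, 0.06, seed)
    nn <- networkNodes(rn$net)
    withr::with_seed(seed, {
      S1 <- sample(nn, 3); S2 <- sample(nn, 3)
    })
    m0 <- commonModule(S1, S2, 0, rn$net)
    m1 <- commonModule(S1, S2, 1, rn$net)
    m2 <- commonModule(S1, S2, 2, rn$net)
    expect_true(all(m0 %in% m1) && all(m1 %in% m2))
  }
})

test_that("module-entity distance reproduces hand-computed chain scores", {
  net <- chainNet(c("A", "B", "C"))
  cfg <- fixedCfg()
  expect_equal(moduleEntityDistance("B", "B", 0, net, cfg), 1 / 6)
  expect_equal(moduleEntityDistance("B", "C", 1, net, cfg), 1 / 36)
  expect_equal(moduleEntityDistance("B", "C", 0, net, cfg), 0)
  expect_equal(moduleEntityDistance(character(), "B", 1, net, cfg), 0)
  expect_equal(moduleEntityDistance(c("A", "B"), "B", 0, net, cfg), 1 / 12)
})

test_that("module-entity distance matches exact-distance enumeration", {
  for (seed in 1:10) {
    rn <- randomNet(50, 0.07, seed)
    D <- igraph::distances(rn$graph)
    nn <- networkNodes(rn$net)
    withr::with_seed(seed * 13, {
      M <- sample(nn, sample(1:6, 1)); G <- sample(nn, sample(2:4, 1))
      k <- sample(0:2, 1)
    })
    oracle <- mean(outer(M, G, function(a, b)
      (D[cbind(a, b)] == k) * (1 / 6)^(k + 1)))
    expect_equal(moduleEntityDistance(M, G, k, rn$net, fixedCfg()), oracle,
                 tolerance = 1e-14)
  }
})

test_that("exact-distance buckets partition pairs across k", {
  cfg <- fixedCfg()
  for (seed in 1:5) {
    rn <- randomNet(50, 0.07, seed)
    D <- igraph::distances(rn$graph)
    nn <- networkNodes(rn$net)
    withr::with_seed(seed, {
      M <- sample(nn, 5); G <- sample(nn, 3)
    })
    counts <- vapply(0:2, function(k)
      moduleEntityDistance(M, G, k, rn$net, cfg) *
        length(M) * length(G) / (1 / 6)^(k + 1), numeric(1))
    reachable <- sum(outer(M, G, function(a, b)
      as.numeric(is.finite(D[cbind(a, b)]) & D[cbind(a, b)] <= 2)))
    expect_equal(sum(counts), reachable)          # each pair counted once
    expect_lte(sum(counts), length(M) * length(G))
  }
})

test_that("best-known module distance handles empty anchors and modules", {
  tc <- tinyCatalogs()
  expect_equal(bestKnownModuleDistance("d1", "p1", "d-module", 1, 0,
                                       tc$drugs, tc$diseases, tc$assoc,
                                       tc$net, tc$cfg, exclude = "d1"), 0)
  # p-module side: d2 knows only p2; excluding it empties the maximum
  expect_equal(bestKnownModuleDistance("p2", "d2", "p-module", 1, 0,
                                       tc$drugs, tc$diseases, tc$assoc,
                                       tc$net, tc$cfg, exclude = "p2"), 0)
  # with the anchor available the score is the direct module computation
  got <- bestKnownModuleDistance("d2", "p1", "d-module", 1, 1,
                                 tc$drugs, tc$diseases, tc$assoc,
                                 tc$net, tc$cfg)
  mod <- commonModule(nodeSets(tc$drugs)$d2, nodeSets(tc$drugs)$d1, 1,
                      tc$net)
  expect_equal(got, moduleEntityDistance(mod, nodeSets(tc$diseases)$p1, 1,
                                         tc$net, tc$cfg))
})
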