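test_that("loading dedups edges, drops self-loops and unions tags", {
  net <- loadNetwork(data.frame(a = c("A", "B", "A"), b = c("B", "A", "B")))
  expect_equal(length(networkNodes(net)), 2L)
  expect_equal(numEdges(net), 1L)

  net2 <- loadNetwork(data.frame(a = c("A", "A"), b = c("A", "B")))
  expect_equal(sort(networkNodes(net2)), c("A", "B"))
  expect_equal(numEdges(net2), 1L)

  net3 <- loadNetwork(data.frame(a = c("A", "A"), b = c("B", "B"),
                                 t = c("regulation_activation", "ppi")))
  expect_equal(numEdges(net3), 1L)
  expect_equal(edgeTable(net3)$type, "ppi,regulation_activation")
})

test_that("sif dialect and malformed rows are handled", {
  tsv <- tempfile(fileext = ".sif")
  writeLines(c("# comment", "A\tppi\tB", "B\tppi\tC"), tsv)
  net <- loadNetwork(tsv, sif = TRUE)
  expect_equal(numEdges(net), 2L)
  expect_equal(boundedDistance(net, "A", "C"), 2L)

  bad <- tempfile()
  writeLines(c("A\tB", "Conly"), bad)
  expect_error(loadNetwork(bad), "line 2")
})

test_that("bounded distance follows the R0/R1/R2 scheme and is symmetric", {
  net <- chainNet()
  expect_identical(boundedDistance(net, "A", "A"), 0L)
  expect_identical(boundedDistance(net, "A", "B"), 1L)
  expect_identical(boundedDistance(net, "A", "C"), 2L)
  expect_identical(boundedDistance(net, "A", "D"), NA_integer_)
  expect_identical(boundedDistance(net, "D", "A"), NA_integer_)
  expect_error(boundedDistance(net, "A", "Z"), "unknown node")
})

test_that("bounded distance matches a full breadth-first-search oracle", {
  for (seed in 1:5) {
    rn <- randomNet(60, 0.05, seed)
    D <- igraph::distances(rn$graph)   # independent full BFS
    nn <- networkNodes(rn$net)
    for (i in seq_along(nn)) for (j in seq_len(i)) {
      d <- boundedDistance(rn$net, nn[i], nn[j])
      want <- D[nn[i], nn[j]]
      if (is.finite(want) && want <= 2) expect_identical(d, as.integer(want))
      else expect_identical(d, NA_integer_)
      expect_identical(d, boundedDistance(rn$net, nn[j], nn[i]))
    }
  }
})

test_that("neighborhoods include seeds and grow monotonically in v", {
  net <- chainNet(c("A", "B", "C"))
  expect_equal(nodeNeighborhood(net, "A", 0), "A")
  expect_equal(sort(nodeNeighborhood(net, "A", 1)), c("A", "B"))
  expect_equal(sort(nodeNeighborhood(net, c("A", "C"), 1)), c("A", "B", "C"))
  expect_error(nodeNeighborhood(net, "A", 3), "v")

  for (seed in 1:5) {
    rn <- randomNet(50, 0.08, seed)
    seeds <- sample(networkNodes(rn$net), 3L)
    n0 <- nodeNeighborhood(rn$net, seeds, 0)
    n1 <- nodeNeighborhood(rn$net, seeds, 1)
    n2 <- nodeNeighborhood(rn$net, seeds, 2)
    expect_setequal(n0, seeds)
    expect_true(all(n0 %in% n1) && all(n1 %in% n2))
  }
})

test_that("median degree uses the lower middle value for even counts", {
  tri <- loadNetwork(data.frame(a = c("A", "B", "C"), b = c("B", "C", "A")))
  expect_equal(medianDegree(tri), 2)
  expect_equal(medianDegree(chainNet(c("A", "B", "C"))), 1)
  expect_equal(medianDegree(chainNet()), 1)  # degrees 1,1,2,2 -> lower mid
})

test_that("auto path-score mode takes the reciprocal median degree", {
  tri <- loadNetwork(data.frame(a = c("A", "B", "C"), b = c("B", "C", "A")))
  cfg <- pathScoreConfig(mode = "auto", net = tri)
  expect_equal(cfg@base, 1 / 2)
  expect_error(pathScoreConfig(mode = "auto"), "network")
})

test_that("serialization round-trips to an identical network", {
  bench <- simulateBenchmark(smallBenchSpec())
  f1 <- tempfile(); f2 <- tempfile()
  writeNetwork(bench$net, f1)
  reloaded <- loadNetwork(f1)
  writeNetwork(reloaded, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(edgeTable(reloaded), edgeTable(bench$net))
  expect_identical(networkNodes(reloaded), networkNodes(bench$net))
})
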