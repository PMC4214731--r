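# Shared in-code fixtures: tiny deterministic graphs and a small benchmark.

chainNet <- function(nodes = c("A", "B", "C", "D")) {
  n <- length(nodes)
  loadNetwork(data.frame(a = nodes[-n], b = nodes[-1L],
                         stringsAsFactors = FALSE))
}

fixedCfg <- function(...) pathScoreConfig(mode = "fixed", ...)

# Random simple graph as a GeneNetwork plus its igraph twin for oracles.
randomNet <- function(n, p, seed) {
  g <- withr::with_seed(seed, igraph::sample_gnp(n, p))
  # ensure at least one edge
  if (igraph::ecount(g) == 0L) g <- igraph::add_edges(g, c(1, 2))
  igraph::V(g)$name <- sprintf("N%03d", seq_len(n))
  el <- as.data.frame(igraph::as_edgelist(g), stringsAsFactors = FALSE)
  net <- loadNetwork(el)
  g2 <- igraph::induced_subgraph(g, networkNodes(net))
  list(net = net, graph = g2)
}

# Path score of a full-BFS distance matrix entry (independent oracle).
omegaOracle <- function(l, base = 1 / 6)
  ifelse(is.finite(l) & l <= 2, base^(l + 1), 0)

# A small planted-signal benchmark that keeps CV tests fast.
smallBenchSpec <- function(seed = 3, signal = 0.9)
  benchmarkSpec(nNodes = 150L, nDrugs = 18L, nDiseases = 6L,
                nPositives = 42L, signal = signal, seed = seed)

# Minimal hand-built catalogs on the chain network for anchored-score tests:
# drugs d1 {A,B}, d2 {C,D}; diseases p1 {A,B}, p2 {B,C}; known: (d1,p1), (d2,p2)
tinyCatalogs <- function() {
  net <- chainNet()
  cats <- loadCatalogs(
    data.frame(id = c("d1", "d1", "d2", "d2"), n = c("A", "B", "C", "D")),
    data.frame(id = c("p1", "p1", "p2", "p2"), n = c("A", "B", "B", "C")),
    data.frame(d = c("d1", "d2"), p = c("p1", "p2")),
    net)
  c(cats, list(net = net, cfg = fixedCfg()))
}
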