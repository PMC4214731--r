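#' Construct a synthetic benchmark specification
#'
#' Defaults describe the reference desk-scale benchmark: a 500-node
#' preferential-attachment network targeting median degree 6 (mimicking the
#' degree heterogeneity of protein interaction networks), 60 drugs with 2-5
#' targets, 20 diseases with 2-6 susceptibility genes, 200 known
#' associations, and planted signal 0.8 — each target of a positively
#' associated drug is drawn from within distance 1 of its disease's gene
#' module with that probability, uniformly otherwise.
#'
#' @param nNodes,edgeModel,medianDegree network shape.
#' @param nDrugs,nDiseases,targetsPerDrug,genesPerDisease catalog shape.
#' @param nPositives,signal association count and planted-signal strength.
#' @param nBits,bitsPerDrug fingerprint shape.
#' @param seed master seed.
#' @return a \linkS4class{BenchmarkSpec}.
#' @export
benchmarkSpec <- function(nNodes = 500L,
                          edgeModel = "preferential_attachment",
                          medianDegree = 6, nDrugs = 60L, nDiseases = 20L,
                          targetsPerDrug = c(2L, 5L),
                          genesPerDisease = c(2L, 6L),
                          nPositives = 200L, signal = 0.8,
                          nBits = 128L, bitsPerDrug = 20L, seed = 1) {
  new("BenchmarkSpec", nNodes = as.integer(nNodes), edgeModel = edgeModel,
      medianDegree = as.numeric(medianDegree), nDrugs = as.integer(nDrugs),
      nDiseases = as.integer(nDiseases),
      targetsPerDrug = as.integer(targetsPerDrug),
      genesPerDisease = as.integer(genesPerDisease),
      nPositives = as.integer(nPositives), signal = as.numeric(signal),
      nBits = as.integer(nBits), bitsPerDrug = as.integer(bitsPerDrug),
      seed = as.numeric(seed))
}

setMethod("show", "BenchmarkSpec", function(object) {
  cat(sprintf(paste0("BenchmarkSpec: %d nodes (%s, target median degree ",
                     "%g)\n  %d drugs, %d diseases, %d positives, ",
                     "signal %g, seed %g\n"),
              object@nNodes, object@edgeModel, object@medianDegree,
              object@nDrugs, object@nDiseases, object@nPositives,
              object@signal, object@seed))
})

specAsList <- function(spec) list(
  n_nodes = spec@nNodes, edge_model = spec@edgeModel,
  median_degree = spec@medianDegree, n_drugs = spec@nDrugs,
  n_diseases = spec@nDiseases, targets_per_drug = spec@targetsPerDrug,
  genes_per_disease = spec@genesPerDisease, n_positives = spec@nPositives,
  signal = spec@signal, n_bits = spec@nBits,
  bits_per_drug = spec@bitsPerDrug, seed = spec@seed)

# Generate the network graph; for preferential attachment the per-step edge
# count m is chosen by probing m = 1..target on the actual n and keeping the
# graph whose median degree is closest to the target (ties -> smaller m).
synthNetworkGraph <- function(spec, seed) {
  n <- spec@nNodes
  medOf <- function(g) {
    deg <- sort(igraph::degree(g))
    if (n %% 2L == 1L) deg[(n + 1L) %/% 2L] else deg[n %/% 2L]
  }
  g <- if (spec@edgeModel == "preferential_attachment") {
    cand <- lapply(seq_len(max(1L, ceiling(spec@medianDegree))), function(m)
      withSeed(deriveSeed(seed, m),
               igraph::sample_pa(n, m = m, directed = FALSE)))
    err <- vapply(cand, function(g) abs(medOf(g) - spec@medianDegree),
                  numeric(1L))
    cand[[which.min(err)]]
  } else {
    withSeed(deriveSeed(seed, 1L),
             igraph::sample_gnm(n, round(n * spec@medianDegree / 2)))
  }
  g <- igraph::simplify(g)
  igraph::V(g)$name <- sprintf("G%04d", seq_len(n))
  g
}

#' Simulate a synthetic benchmark in memory
#'
#' Generates the network, catalogs, known associations with planted
#' proximity signal, and random drug fingerprints described by the spec.
#' Disease gene sets are connected-ish neighborhoods (a random seed node
#' plus sampled network neighbors). Drugs involved in a positive
#' association draw each target from within distance 1 of their associated
#' diseases' gene sets with probability \code{signal}, uniformly otherwise;
#' all other structure is uniform. Fingerprints are independent random
#' bitsets, so synthetic predictions carry essentially no chemical
#' similarity. Deterministic given the spec's seed.
#'
#' @param spec a \linkS4class{BenchmarkSpec}.
#' @return a list with \code{net} (\linkS4class{GeneNetwork}),
#'   \code{drugs}, \code{diseases} (\linkS4class{EntityCatalog}),
#'   \code{assoc} (\linkS4class{AssociationSet}), \code{fps} (fingerprint
#'   list) and \code{tables} (the raw TSV-ready data.frames).
#' @export
simulateBenchmark <- function(spec) {
  stopifnot(is(spec, "BenchmarkSpec"))
  validObject(spec)
  seed <- spec@seed
  g <- synthNetworkGraph(spec, deriveSeed(seed, 11L))
  names <- igraph::V(g)$name
  adj <- lapply(igraph::adjacent_vertices(g, igraph::V(g)), as.integer)
  connected <- which(lengths(adj) > 0L)

  # edge source tags: mostly ppi with a sprinkling of the other evidence
  # kinds, supporting network-source ablation runs
  ne <- igraph::ecount(g)
  tags <- withSeed(deriveSeed(seed, 12L),
    sample(c("ppi", "regulation_activation", "regulation_inhibition",
             "complex_inferred"), ne, replace = TRUE,
           prob = c(0.7, 0.1, 0.1, 0.1)))

  # disease gene sets: seed node plus neighbors (2-ball fallback)
  diseases <- withSeed(deriveSeed(seed, 13L), {
    lapply(seq_len(spec@nDiseases), function(i) {
      size <- sample(seq(spec@genesPerDisease[1L], spec@genesPerDisease[2L]),
                     1L)
      s <- sample(connected, 1L)
      pool <- adj[[s]]
      if (length(pool) < size - 1L)
        pool <- unique(c(pool, unlist(adj[pool], use.names = FALSE)))
      pool <- setdiff(pool, s)
      extra <- sample(pool, min(size - 1L, length(pool)))
      genes <- unique(c(s, extra))
      while (length(genes) < size)
        genes <- unique(c(genes, sample(connected, size - length(genes))))
      sort(genes)
    })
  })
  names(diseases) <- sprintf("P%03d", seq_len(spec@nDiseases))

  # Positive associations: a quasi-regular random bipartite assignment —
  # every drug and every disease carries a near-equal number of known
  # associations. Keeping entity frequencies (nearly) constant means the
  # max-over-known-partners features cannot read the label off anchor
  # counts, so at signal = 0 positives are statistically indistinguishable
  # from sampled negatives.
  pairing <- withSeed(deriveSeed(seed, 14L), {
    posDrug <- sample(rep_len(seq_len(spec@nDrugs), spec@nPositives))
    posDis <- sample(rep_len(seq_len(spec@nDiseases), spec@nPositives))
    for (iter in 1:200) {
      dup <- which(duplicated(paste(posDrug, posDis)))
      if (length(dup) == 0L) break
      swap <- sample.int(spec@nPositives, length(dup))
      tmp <- posDis[dup]
      posDis[dup] <- posDis[swap]
      posDis[swap] <- tmp
    }
    if (anyDuplicated(paste(posDrug, posDis)))
      stop("could not construct distinct positive pairs; reduce nPositives")
    list(drug = posDrug, dis = posDis)
  })
  posDrug <- pairing$drug
  posDis <- pairing$dis

  # Drug target sets, proximity-biased for positively associated drugs:
  # targets cycle round-robin over the drug's positive diseases, so each
  # positive pair independently receives, with probability `signal`, at
  # least one target within distance 1 of its own disease module (rather
  # than a lottery over the union of the drug's diseases).
  drugs <- withSeed(deriveSeed(seed, 15L), {
    lapply(seq_len(spec@nDrugs), function(i) {
      myDis <- sort(posDis[posDrug == i])
      # a drug needs at least one target slot per treated disease (capped
      # at the range maximum) for every one of its positive pairs to carry
      # the per-pair planting probability
      size <- max(sample(seq(spec@targetsPerDrug[1L],
                             spec@targetsPerDrug[2L]), 1L),
                  min(length(myDis), spec@targetsPerDrug[2L]))
      targets <- integer()
      for (t in seq_len(size)) {
        pool <- if (length(myDis)) {
          q <- myDis[((t - 1L) %% length(myDis)) + 1L]
          genes <- diseases[[q]]
          unique(c(genes, unlist(adj[genes], use.names = FALSE)))
        } else integer()
        avail <- setdiff(pool, targets)
        pick <- if (length(avail) && runif(1L) < spec@signal)
          avail[sample.int(length(avail), 1L)]
        else {
          u <- setdiff(connected, targets)
          u[sample.int(length(u), 1L)]
        }
        targets <- c(targets, pick)
      }
      sort(targets)
    })
  })
  names(drugs) <- sprintf("D%03d", seq_len(spec@nDrugs))

  fps <- withSeed(deriveSeed(seed, 16L),
    lapply(seq_len(spec@nDrugs), function(i)
      sort(sample.int(spec@nBits, spec@bitsPerDrug))))
  names(fps) <- names(drugs)

  el <- igraph::as_edgelist(g)
  netTab <- data.frame(node1 = pmin(el[, 1L], el[, 2L]),
                       node2 = pmax(el[, 1L], el[, 2L]), type = tags,
                       stringsAsFactors = FALSE)
  netTab <- netTab[order(netTab$node1, netTab$node2), , drop = FALSE]
  drugTab <- data.frame(
    drug = rep(names(drugs), lengths(drugs)),
    node = names[unlist(drugs, use.names = FALSE)],
    stringsAsFactors = FALSE)
  disTab <- data.frame(
    disease = rep(names(diseases), lengths(diseases)),
    node = names[unlist(diseases, use.names = FALSE)],
    stringsAsFactors = FALSE)
  assocTab <- data.frame(drug = names(drugs)[posDrug],
                         disease = names(diseases)[posDis],
                         stringsAsFactors = FALSE)
  assocTab <- assocTab[order(assocTab$drug, assocTab$disease), , drop = FALSE]
  fpTab <- data.frame(drug = names(fps),
                      bits = vapply(fps, paste, character(1L),
                                    collapse = ","),
                      stringsAsFactors = FALSE)

  net <- loadNetwork(netTab)
  cats <- loadCatalogs(drugTab, disTab, assocTab, net)
  list(net = net, drugs = cats$drugs, diseases = cats$diseases,
       assoc = cats$assoc, fps = fps, report = cats$report,
       tables = list(network = netTab, drugs = drugTab, diseases = disTab,
                     associations = assocTab, fingerprints = fpTab))
}

#' Write a synthetic benchmark to TSV files
#'
#' Emits \code{network.tsv}, \code{drugs.tsv}, \code{diseases.tsv},
#' \code{associations.tsv} and \code{fingerprints.tsv} in exactly the
#' dialects the loaders consume, plus \code{spec.json} echoing the
#' generating parameters. Byte-identical across runs with the same spec.
#'
#' @param spec a \linkS4class{BenchmarkSpec}.
#' @param dir output directory (created if missing).
#' @return named character vector of the written paths, invisibly; the
#'   simulated objects are attached as attribute \code{"benchmark"}.
#' @export
generateBenchmark <- function(spec, dir) {
  bench <- simulateBenchmark(spec)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(network = file.path(dir, "network.tsv"),
             drugs = file.path(dir, "drugs.tsv"),
             diseases = file.path(dir, "diseases.tsv"),
             associations = file.path(dir, "associations.tsv"),
             fingerprints = file.path(dir, "fingerprints.tsv"),
             spec = file.path(dir, "spec.json"))
  writeTsvFile(bench$tables$network, paths[["network"]])
  writeTsvFile(bench$tables$drugs, paths[["drugs"]])
  writeTsvFile(bench$tables$diseases, paths[["diseases"]])
  writeTsvFile(bench$tables$associations, paths[["associations"]])
  writeTsvFile(bench$tables$fingerprints, paths[["fingerprints"]])
  jsonlite::write_json(specAsList(spec), paths[["spec"]],
                       auto_unbox = TRUE, digits = NA)
  attr(paths, "benchmark") <- bench
  invisible(paths)
}
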