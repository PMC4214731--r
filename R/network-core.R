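#' Load an integrative gene network from an edge list
#'
#' Reads a tab-separated edge list with columns \code{node1}, \code{node2}
#' and an optional interaction \code{type} (defaulting to \code{"ppi"}).
#' Lines starting with \code{#} are ignored. Self-loops are dropped,
#' duplicate edges are merged (keeping the union of their source tags), and
#' directed regulation rows collapse onto a single undirected edge. The
#' \code{.sif} dialect (\code{node1 TAB type TAB node2}) is accepted via
#' \code{sif = TRUE}. A \code{type} field may itself contain a comma-joined
#' tag set, so a network round-trips through [writeNetwork()] unchanged.
#'
#' @param edges path to a TSV file, or a data.frame with 2-3 character
#'   columns in the same order.
#' @param sif logical; interpret the three columns as source, type, target.
#' @return a \linkS4class{GeneNetwork}.
#' @examples
#' edges <- data.frame(a = c("A", "B", "A"), b = c("B", "A", "B"))
#' net <- loadNetwork(edges)
#' numEdges(net)  # 1: duplicates and reversals merge
#' @export
loadNetwork <- function(edges, sif = FALSE) {
  df <- readTsv(edges, what = "edge")
  if (nrow(df) == 0L) stop("edge table is empty")
  if (sif) {
    if (ncol(df) < 3L) stop("sif dialect requires 3 columns")
    df <- data.frame(V1 = df$V1, V2 = df$V3, V3 = df$V2,
                     stringsAsFactors = FALSE)
  }
  n1 <- trimws(df$V1); n2 <- trimws(df$V2)
  type <- if (ncol(df) >= 3L) trimws(df$V3) else rep("ppi", nrow(df))
  type[is.na(type) | !nzchar(type)] <- "ppi"
  if (any(!nzchar(n1) | !nzchar(n2)))
    stop("malformed edge row: empty node identifier")

  keep <- n1 != n2              # self-loops dropped
  n1 <- n1[keep]; n2 <- n2[keep]; type <- type[keep]
  if (length(n1) == 0L) stop("no edges remain after dropping self-loops")

  # canonical unordered orientation, then merge duplicates with tag union
  lo <- pmin(n1, n2); hi <- pmax(n1, n2)
  key <- paste(lo, hi, sep = "\t")
  tags <- strsplit(type, ",", fixed = TRUE)
  merged <- tapply(tags, key, function(x)
    paste(sort(unique(trimws(unlist(x)))), collapse = ","))
  ekeys <- names(merged)
  ends <- strsplit(ekeys, "\t", fixed = TRUE)
  elo <- vapply(ends, `[[`, character(1L), 1L)
  ehi <- vapply(ends, `[[`, character(1L), 2L)

  verts <- sort(unique(c(elo, ehi)))
  g <- igraph::graph_from_edgelist(cbind(elo, ehi), directed = FALSE)
  g <- g + igraph::vertices(setdiff(verts, igraph::V(g)$name))
  g <- igraph::permute(g, match(igraph::V(g)$name, verts))
  eidx <- igraph::get_edge_ids(g, rbind(match(elo, verts), match(ehi, verts)))
  src <- character(igraph::ecount(g))
  src[eidx] <- as.character(merged)
  igraph::E(g)$sources <- src
  newGeneNetwork(g)
}

# Build a GeneNetwork from a ready igraph graph, precomputing the
# distance-1 and exact-distance-2 node lists used by every scoring query.
newGeneNetwork <- function(g) {
  adj <- lapply(igraph::adjacent_vertices(g, igraph::V(g)), as.integer)
  r2 <- lapply(igraph::ego(g, order = 2L, mindist = 2L), as.integer)
  new("GeneNetwork", graph = g, adj = adj, reach2 = r2)
}

#' Serialize a network to its canonical sorted edge-list TSV
#'
#' Edges are written lexicographically (node1 < node2, rows sorted) with the
#' comma-joined source tags, so that serialization is canonical: reloading
#' the output with [loadNetwork()] reproduces an identical network.
#'
#' @param net a \linkS4class{GeneNetwork}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeNetwork <- function(net, path) {
  df <- edgeTable(net)
  writeTsvFile(df, path)
  invisible(path)
}

#' @describeIn GeneNetwork canonical edge table (node1, node2, type), sorted.
#' @param net a \linkS4class{GeneNetwork}.
#' @export
setMethod("edgeTable", "GeneNetwork", function(net) {
  el <- igraph::as_edgelist(net@graph)
  lo <- pmin(el[, 1L], el[, 2L]); hi <- pmax(el[, 1L], el[, 2L])
  df <- data.frame(node1 = lo, node2 = hi,
                   type = igraph::E(net@graph)$sources,
                   stringsAsFactors = FALSE)
  df[order(df$node1, df$node2), , drop = FALSE]
})

#' @describeIn GeneNetwork sorted vertex identifiers.
#' @param x a \linkS4class{GeneNetwork}.
#' @export
setMethod("networkNodes", "GeneNetwork", function(x)
  igraph::V(x@graph)$name)

#' @describeIn GeneNetwork number of (undirected, deduplicated) edges.
#' @export
setMethod("numEdges", "GeneNetwork", function(x) igraph::ecount(x@graph))

setMethod("show", "GeneNetwork", function(object) {
  cat("GeneNetwork with", igraph::vcount(object@graph), "nodes and",
      igraph::ecount(object@graph), "edges\n")
  cat("  median degree:", medianDegree(object), "\n")
  tags <- sort(unique(unlist(strsplit(igraph::E(object@graph)$sources, ","))))
  cat("  edge sources:", paste(tags, collapse = ", "), "\n")
})

# Map node names to vertex indices, erroring on unknown identifiers.
nodeIndex <- function(net, ids) {
  idx <- match(ids, igraph::V(net@graph)$name)
  if (anyNA(idx))
    stop("unknown node identifier(s): ",
         paste(head(ids[is.na(idx)], 5L), collapse = ", "))
  idx
}

# Bounded distance on vertex indices: 0, 1, 2 or NA (unreachable within 2).
boundedDistanceIdx <- function(net, i, j) {
  if (i == j) return(0L)
  if (j %in% net@adj[[i]]) return(1L)
  if (j %in% net@reach2[[i]]) return(2L)
  NA_integer_
}

#' Bounded shortest-path distance between two nodes
#'
#' Returns the shortest-path length between \code{a} and \code{b} if it is
#' at most \code{maxLen} (fixed at 2: the R0/R1/R2 path types), and
#' \code{NA_integer_} — the UNREACHABLE sentinel — otherwise. Symmetric in
#' its arguments.
#'
#' @param net a \linkS4class{GeneNetwork}.
#' @param a,b node identifiers present in the network.
#' @param maxLen maximum path length considered; only 2 is supported.
#' @return integer 0, 1, 2 or \code{NA_integer_}.
#' @export
setMethod("boundedDistance", "GeneNetwork", function(net, a, b, maxLen = 2L) {
  if (!identical(as.integer(maxLen), 2L))
    stop("'maxLen' is fixed at 2 (R0/R1/R2 path types)")
  boundedDistanceIdx(net, nodeIndex(net, a), nodeIndex(net, b))
})

# v-step neighborhood on vertex indices (v in 0:2), using the caches.
neighborhoodIdx <- function(net, seedIdx, v) {
  if (v == 0L) return(sort(unique(seedIdx)))
  out <- c(seedIdx, unlist(net@adj[seedIdx], use.names = FALSE))
  if (v == 2L)
    out <- c(out, unlist(net@reach2[seedIdx], use.names = FALSE))
  sort(unique(out))
}

#' v-step neighborhood of a seed node set
#'
#' All nodes at graph distance at most \code{v} from any seed. The level
#' parameter \code{v} sets the scope of a topological module; seeds are
#' always included and the result is monotone non-decreasing in \code{v}.
#'
#' @param net a \linkS4class{GeneNetwork}.
#' @param seeds character vector of node identifiers.
#' @param v integer level in \code{0:2}.
#' @return sorted character vector of node identifiers.
#' @export
setMethod("nodeNeighborhood", "GeneNetwork", function(net, seeds, v) {
  if (length(v) != 1L || !v %in% 0:2)
    stop("level parameter 'v' must be one of 0, 1, 2")
  idx <- nodeIndex(net, seeds)
  igraph::V(net@graph)$name[neighborhoodIdx(net, idx, as.integer(v))]
})

#' Median node degree of the network
#'
#' The median of the degree multiset; for an even node count the lower
#' middle value is taken, so that the automatic path base score
#' 1/medianDegree stays a unit fraction.
#'
#' @param net a non-empty \linkS4class{GeneNetwork}.
#' @return a single number.
#' @export
setMethod("medianDegree", "GeneNetwork", function(net) {
  deg <- sort(igraph::degree(net@graph))
  n <- length(deg)
  if (n == 0L) stop("network is empty")
  unname(if (n %% 2L == 1L) deg[(n + 1L) %/% 2L] else deg[n %/% 2L])
})
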