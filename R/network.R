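## Confidence-filtered interaction-network clustering and behavior overlay.

# internal: GeneNetwork -> igraph, preserving isolated nodes
.asIgraph <- function(network) {
  igraph::graph_from_data_frame(network@edges, directed = FALSE,
                                vertices = data.frame(name = network@nodes))
}

#' Filter network edges by confidence score
#'
#' Retains edges with `score >= min_score` (an interaction scored exactly at
#' the threshold is kept; only scores *below* it are excluded). Nodes that
#' become isolated are retained.
#'
#' @param network a [GeneNetwork-class].
#' @param min_score threshold in `[0, 1]` (default 0.7).
#' @return filtered [GeneNetwork-class] (same node set).
#' @export
filterEdges <- function(network, min_score = 0.7) {
  stopifnot(is(network, "GeneNetwork"))
  if (!is.numeric(min_score) || length(min_score) != 1 ||
      min_score < 0 || min_score > 1)
    stopf("filterEdges: min_score must lie in [0, 1]")
  out <- geneNetwork(network@edges[network@edges$score >= min_score, ,
                                   drop = FALSE],
                     nodes = network@nodes)
  iso <- sum(!out@nodes %in% c(out@edges$node_a, out@edges$node_b))
  if (iso > 0)
    message(sprintf("filterEdges: %d isolated node(s) retained", iso))
  out
}

#' Newman-Girvan modularity of a partition
#'
#' `Q = sum_c [ e_c / m - (d_c / 2m)^2 ]` over communities `c`, with `e_c`
#' the number of within-community edges, `d_c` the total degree of the
#' community and `m` the edge count. Unweighted by default; with
#' `weighted = TRUE` the confidence scores act as weights. An edgeless graph
#' has `Q = 0` by convention.
#'
#' @param network a [GeneNetwork-class].
#' @param partition named vector (node -> community id) covering all nodes.
#' @param weighted use edge scores as weights.
#' @return modularity value.
#' @examples
#' gn <- geneNetwork(data.frame(node_a = c("a", "b"), node_b = c("b", "c"),
#'                              score = 1))
#' networkModularity(gn, c(a = 1, b = 1, c = 1))  # single community: Q = 0
#' @export
networkModularity <- function(network, partition, weighted = FALSE) {
  stopifnot(is(network, "GeneNetwork"))
  miss <- setdiff(network@nodes, names(partition))
  if (length(miss))
    stopf("networkModularity: partition misses node(s) %s",
          paste(head(miss, 3), collapse = ", "))
  e <- network@edges
  w <- if (weighted) e$score else rep(1, nrow(e))
  m <- sum(w)
  if (m == 0) return(0)
  ca <- partition[e$node_a]; cb <- partition[e$node_b]
  deg <- setNames(numeric(length(network@nodes)), network@nodes)
  for (side in c("node_a", "node_b")) {
    agg <- tapply(w, e[[side]], sum)
    deg[names(agg)] <- deg[names(agg)] + agg
  }
  comm <- unique(partition[network@nodes])
  q <- 0
  for (cc in comm) {
    e_c <- sum(w[ca == cc & cb == cc])
    d_c <- sum(deg[names(partition)[partition == cc]])
    q <- q + e_c / m - (d_c / (2 * m))^2
  }
  q
}

#' Louvain clustering of a gene network
#'
#' Greedy modularity optimization (Louvain). The node visiting order is
#' randomized, so a seed fixes the result; the returned partition never has
#' lower modularity than the all-singletons partition. Cluster ids are
#' renumbered by descending cluster size (ties broken by smallest member id)
#' for stable reporting.
#'
#' @param network a [GeneNetwork-class].
#' @param seed integer seed.
#' @param weighted optimize weighted modularity using edge scores.
#' @return named integer vector node -> cluster id; empty network gives an
#'   empty partition. The achieved modularity is attached as attribute
#'   `"modularity"` (computed by [networkModularity()]).
#' @export
louvainCluster <- function(network, seed = 1, weighted = FALSE) {
  stopifnot(is(network, "GeneNetwork"))
  if (length(network@nodes) == 0) return(setNames(integer(0), character(0)))
  g <- .asIgraph(network)
  memb <- withSeed(facetSeed(seed, "louvain"), {
    cl <- igraph::cluster_louvain(
      g, weights = if (weighted) igraph::E(g)$score else NA)
    igraph::membership(cl)
  })
  memb <- setNames(as.integer(memb), igraph::V(g)$name)[network@nodes]
  # renumber by descending size, ties by smallest member id
  sizes <- table(memb)
  first <- tapply(names(memb), memb, min)
  ord <- order(-as.integer(sizes), first[names(sizes)])
  relabel <- setNames(seq_along(ord), names(sizes)[ord])
  out <- setNames(relabel[as.character(memb)], names(memb))
  attr(out, "modularity") <- networkModularity(network, out, weighted)
  out
}

#' Attach a clustering to a network
#'
#' @param network a [GeneNetwork-class].
#' @param partition named integer vector covering the nodes.
#' @return the network with its `clusters` slot set.
#' @export
setClusters <- function(network, partition) {
  miss <- setdiff(network@nodes, names(partition))
  if (length(miss)) stopf("setClusters: partition misses %d node(s)",
                          length(miss))
  network@clusters <- setNames(as.integer(partition[network@nodes]),
                               network@nodes)
  validObject(network)
  network
}

#' Functional annotation of network clusters
#'
#' Runs [enrich()] with each cluster (of size >= 2) as the test set against
#' the supplied reference and returns the top terms per cluster by FDR.
#' Singleton clusters yield no annotation.
#'
#' @param network a clustered [GeneNetwork-class] (see [setClusters()]), or a
#'   named partition vector.
#' @param annotation gene-level annotation table.
#' @param reference_genes reference gene universe (cluster members outside it
#'   are ignored).
#' @param top_n terms reported per cluster.
#' @param fdr_max enrichment threshold passed to [enrich()].
#' @return data.frame with `cluster` plus the [enrich()] columns, top
#'   `top_n` terms per cluster.
#' @export
annotateClusters <- function(network, annotation, reference_genes,
                             top_n = 5, fdr_max = 0.05) {
  partition <- if (is(network, "GeneNetwork")) network@clusters else network
  if (!length(partition))
    stopf("annotateClusters: no clustering available")
  out <- list()
  for (cl in sort(unique(partition))) {
    genes <- intersect(names(partition)[partition == cl], reference_genes)
    if (length(genes) < 2) next
    res <- enrich(genes, reference_genes, annotation, fdr_max = fdr_max)
    if (nrow(res) == 0) next
    res <- head(res, top_n)
    res$cluster <- cl
    out[[as.character(cl)]] <- res[, c("cluster", setdiff(names(res), "cluster"))]
  }
  if (!length(out))
    return(data.frame(cluster = integer(), term_id = character(),
                      k = integer(), n = integer(), K = integer(),
                      N = integer(), pvalue = numeric(), fdr = numeric(),
                      ic = numeric(), enriched = logical()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Overlay behavior categories onto network nodes
#'
#' Attaches double-behavior categories (from [doubleBehaviorOverlay()]) to
#' the nodes; nodes without a category become `"neutral"`.
#'
#' @param network a [GeneNetwork-class].
#' @param categories named character vector gene -> category.
#' @return the network with its `overlay` slot set.
#' @seealso [overlayCrossTab()]
#' @export
overlayBehavior <- function(network, categories) {
  stopifnot(is(network, "GeneNetwork"))
  cat <- categories[network@nodes]
  cat[is.na(cat)] <- "neutral"
  network@overlay <- setNames(unname(cat), network@nodes)
  network
}

#' Per-cluster overlay category counts
#'
#' @param network a [GeneNetwork-class] with clusters and overlay set.
#' @return contingency table cluster x category.
#' @export
overlayCrossTab <- function(network) {
  if (!length(network@clusters) || !length(network@overlay))
    stopf("overlayCrossTab: network needs both clusters and overlay")
  table(cluster = network@clusters[network@nodes],
        category = network@overlay[network@nodes])
}

#' Export a network to GraphML
#'
#' Writes the graph with `score` edge attributes plus `cluster` and
#' `overlay` node attributes (where set) for external viewers.
#'
#' @param network a [GeneNetwork-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeGraphML <- function(network, path) {
  g <- .asIgraph(network)
  if (length(network@clusters))
    igraph::V(g)$cluster <- as.integer(network@clusters[igraph::V(g)$name])
  if (length(network@overlay))
    igraph::V(g)$overlay <- unname(network@overlay[igraph::V(g)$name])
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
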