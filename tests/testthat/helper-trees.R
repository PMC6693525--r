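# Brute-force bipartition set of an unrooted tree via graph component
# decomposition: drop each internal edge in turn and read off the tip
# partition. Independent of the package's postorder traversal.
bruteforce_bipartitions <- function(tree) {
  n <- length(tree$tip.label)
  edges <- tree$edge
  g <- igraph::graph_from_edgelist(apply(edges, 2, as.character),
                                   directed = FALSE)
  taxa <- sort(tree$tip.label)
  anchor <- taxa[1]
  keys <- character()
  for (e in seq_len(nrow(edges))) {
    if (edges[e, 2] <= n) next  # pendant edge: trivial split
    g2 <- igraph::delete_edges(
      g, igraph::get_edge_ids(g, as.character(edges[e, ])))
    comp <- igraph::components(g2)$membership
    side_nodes <- as.integer(names(comp)[comp == comp[[
      as.character(edges[e, 2])]]])
    tips <- tree$tip.label[side_nodes[side_nodes <= n]]
    if (length(tips) < 2L || length(tips) > n - 2L) next
    side <- if (anchor %in% tips) setdiff(taxa, tips) else tips
    keys <- c(keys, paste(sort(side), collapse = "|"))
  }
  unique(keys)
}

bruteforce_rf <- function(t1, t2) {
  b1 <- bruteforce_bipartitions(t1)
  b2 <- bruteforce_bipartitions(t2)
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

random_unrooted_tree <- function(n) {
  tr <- ape::rtree(n, rooted = FALSE,
                   br = function(k) stats::runif(k, 0.05, 1))
  tr$tip.label <- sample(paste0("t", seq_len(n)))
  tr
}
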