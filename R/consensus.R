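#' Community detection on a weighted adjacency matrix
#'
#' Modularity-maximizing (Louvain) labels on the weighted undirected
#' graph.  Isolated nodes become singleton communities.  Deterministic
#' given the R random seed.
#'
#' @param adjacency symmetric matrix with nonnegative weights.
#' @return integer label vector (one entry per node).
#' @export
base_communities <- function(adjacency) {
  p <- nrow(adjacency)
  if (p == 0) return(integer(0))
  g <- igraph::graph_from_adjacency_matrix(adjacency, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  if (igraph::ecount(g) == 0) return(seq_len(p))
  cl <- igraph::cluster_louvain(g, weights = igraph::E(g)$weight)
  as.integer(igraph::membership(cl))
}

#' Consensus clustering of a joint network into stable subnetworks
#'
#' Operates on the union graph of the two condition networks (edges
#' present in either condition, weighted by the larger absolute partial
#' correlation), so differential edges cannot split a subnetwork by
#' construction.  Each run retains a random fraction of the union edges
#' and applies [base_communities()]; the consensus matrix `C` records
#' how often every node pair co-clusters.  The final partition refines
#' an average-linkage tree on `1 - C` (cut chosen to maximize the mean
#' within-cluster consensus) into connected components of the graph
#' `{C > consensus_threshold}`.  Components smaller than `min_size`
#' are left unassigned (id 0).  Subnetwork ids are ordered by
#' descending size.
#'
#' @param net a [joint_network()] (or a list with `R1`, `R2`, `nodes`).
#' @param n_runs number of perturbed runs.
#' @param edge_keep_frac fraction of union edges retained per run.
#' @param min_size minimum subnetwork size; smaller components are
#'   unassigned.
#' @param consensus_threshold co-clustering frequency defining the
#'   consensus graph.
#' @return object of class `SubnetworkPartition`: list with `labels`
#'   (named integer vector, 0 = unassigned), `members` (list of node
#'   vectors per subnetwork), and `consensus` (the matrix `C`).
#' @export
consensus_cluster <- function(net, n_runs = 50, edge_keep_frac = 0.8,
                              min_size = 5, consensus_threshold = 0.5) {
  W <- pmax(abs(net$R1), abs(net$R2))
  p <- nrow(W)
  nodes <- net$nodes %||% colnames(W) %||% paste0("V", seq_len(p))
  edges <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  labels <- setNames(integer(p), nodes)
  if (nrow(edges) == 0) {
    return(structure(list(labels = labels, members = list(),
                          consensus = diag(p)),
                     class = "SubnetworkPartition"))
  }
  C <- matrix(0, p, p)
  n_keep <- max(1L, round(edge_keep_frac * nrow(edges)))
  for (run in seq_len(n_runs)) {
    keep <- edges[sample.int(nrow(edges), n_keep), , drop = FALSE]
    A <- matrix(0, p, p)
    A[keep] <- W[keep]
    A <- A + t(A)
    lab <- base_communities(A)
    C <- C + outer(lab, lab, "==")
  }
  C <- C / n_runs
  diag(C) <- 1
  dimnames(C) <- list(nodes, nodes)

  cl <- refine_consensus(C, threshold = consensus_threshold)
  comp <- consensus_components(C, cl, consensus_threshold)

  sizes <- vapply(comp, length, 1L)
  comp <- comp[sizes >= min_size]
  if (length(comp)) {
    comp <- comp[order(-vapply(comp, length, 1L),
                       vapply(comp, min, 1L))]
    for (s in seq_along(comp)) labels[comp[[s]]] <- s
  }
  members <- lapply(comp, function(i) nodes[i])
  names(members) <- seq_along(members)
  structure(list(labels = labels, members = members, consensus = C),
            class = "SubnetworkPartition")
}

# average-linkage refinement: the shallowest cut of the 1 - C tree in
# which every cluster's mean internal consensus reaches the threshold
# (a raw "maximize mean within-cluster consensus" rule is degenerate --
# it always prefers shattering into tight pairs)
refine_consensus <- function(C, threshold = 0.5) {
  p <- nrow(C)
  if (p < 3) return(rep(1L, p))
  hc <- hclust(as.dist(1 - C), method = "average")
  for (k in seq_len(p)) {
    cl <- cutree(hc, k = k)
    ok <- vapply(unique(cl), function(g) {
      i <- which(cl == g)
      if (length(i) < 2) return(TRUE)
      sub <- C[i, i]
      mean(sub[upper.tri(sub)]) >= threshold
    }, logical(1))
    if (all(ok)) return(cl)
  }
  seq_len(p)
}

# split each refined cluster into connected components of {C > threshold}
consensus_components <- function(C, cl, threshold) {
  comp <- list()
  for (g in unique(cl)) {
    idx <- which(cl == g)
    A <- (C[idx, idx, drop = FALSE] > threshold) * 1
    diag(A) <- 0
    gph <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    mem <- igraph::components(gph)$membership
    for (cc in unique(mem)) comp <- c(comp, list(idx[mem == cc]))
  }
  comp
}

#' @export
print.SubnetworkPartition <- function(x, ...) {
  cat("SubnetworkPartition: ", length(x$members), " subnetworks; ",
      sum(x$labels == 0), " unassigned of ", length(x$labels),
      " nodes\n", sep = "")
  invisible(x)
}
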