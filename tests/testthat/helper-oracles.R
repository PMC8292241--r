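# Independent, deliberately naive oracles used to cross-check the package.
# None of these share code with the implementation under test.

# Prim's algorithm on the complete Euclidean graph. Returns the MST edge
# set as a sorted two-column matrix of vertex indices (i < j per row).
oracle_mst_edges <- function(x, y) {
  n <- length(x)
  if (n < 2) return(matrix(integer(), 0, 2))
  d <- as.matrix(stats::dist(cbind(x, y)))
  in_tree <- c(TRUE, rep(FALSE, n - 1))
  edges <- matrix(0L, 0, 2)
  while (sum(in_tree) < n) {
    bd <- Inf; best <- c(NA_integer_, NA_integer_)
    for (i in which(in_tree)) for (j in which(!in_tree)) {
      if (d[i, j] < bd) { bd <- d[i, j]; best <- c(i, j) }
    }
    in_tree[best[2]] <- TRUE
    edges <- rbind(edges, sort(best))
  }
  edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
}

# Edge set of an igraph graph in the same canonical form.
canonical_edges <- function(g) {
  el <- igraph::as_edgelist(g, names = FALSE)
  if (nrow(el) == 0) return(matrix(integer(), 0, 2))
  el <- t(apply(el, 1, sort))
  el[order(el[, 1], el[, 2]), , drop = FALSE]
}

# Average local clustering by explicit neighbour-pair enumeration;
# degree < 2 contributes 0.
oracle_avg_clustering <- function(adj) {
  n <- nrow(adj)
  cc <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    links <- 0
    for (a in 1:(k - 1)) for (b in (a + 1):k)
      links <- links + (adj[nb[a], nb[b]] > 0)
    cc[i] <- 2 * links / (k * (k - 1))
  }
  mean(cc)
}

# Hop-count diameter by Floyd-Warshall.
oracle_diameter <- function(adj) {
  n <- nrow(adj)
  dm <- ifelse(adj > 0, 1, Inf)
  diag(dm) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (dm[i, k] + dm[k, j] < dm[i, j]) dm[i, j] <- dm[i, k] + dm[k, j]
  max(dm)
}

# Newman modularity Q of a given membership, from the definition.
oracle_modularity_Q <- function(adj, membership) {
  m2 <- sum(adj)            # 2m
  deg <- rowSums(adj)
  q <- 0
  n <- nrow(adj)
  for (i in seq_len(n)) for (j in seq_len(n))
    if (membership[i] == membership[j])
      q <- q + adj[i, j] - deg[i] * deg[j] / m2
  q / m2
}

# Brute-force maximum of Q over all partitions into two labelled blocks
# (node 1 fixed to block 1 to halve the enumeration).
oracle_best_2block_Q <- function(adj) {
  n <- nrow(adj)
  best <- -Inf
  for (mask in 0:(2^(n - 1) - 1)) {
    mem <- c(1L, as.integer(intToBits(mask))[seq_len(n - 1)] + 1L)
    best <- max(best, oracle_modularity_Q(adj, mem))
  }
  best
}

# Random connected Erdos-Renyi-style graph for metric oracle checks.
random_connected_adj <- function(n, p = 0.4) {
  repeat {
    adj <- matrix(0L, n, n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      if (runif(1) < p) adj[i, j] <- adj[j, i] <- 1L
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    if (igraph::is_connected(g)) return(list(adj = adj, g = g))
  }
}

# Layout fixture helpers ----------------------------------------------------

square_land <- function() landscape(A = 25, L = 5)

complete_dists <- function(layout)
  as.numeric(stats::dist(cbind(layout$x, layout$y)))

fixed_layout <- function(n, seed, land = square_land()) {
  sample_layout(land, n, seed = seed)
}
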