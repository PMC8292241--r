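#' Structural metrics of habitat networks
#'
#' The three metrics used throughout the package to characterize the
#' pattern of potential connectivity. All are computed on the binarized
#' (unweighted) topology — weights, when present, are ignored — so they
#' are invariant to any rescaling of link weights.
#'
#' * `avg_clustering()`: mean local transitivity — the probability that two
#'   patches connected to a common patch are themselves connected;
#'   patches with fewer than two neighbours contribute 0.
#' * `graph_modularity()`: Newman modularity Q of the partition found by
#'   greedy agglomerative modularity maximization; high values mean
#'   clusters of patches more densely connected within than between.
#' * `graph_diameter()`: the longest shortest path, in link counts, between
#'   any two patches — a measure of the linearity of potential
#'   connectivity. Defined only on connected graphs.
#'
#' @param g an igraph habitat network.
#' @return `avg_clustering()`: a value in \[0, 1\]. `graph_modularity()`:
#'   Q in \[-0.5, 1\]. `graph_diameter()`: a non-negative integer.
#' @examples
#' tri <- igraph::make_full_graph(3)
#' avg_clustering(tri)   # 1
#' graph_diameter(tri)   # 1
#' @name network-metrics
NULL

#' @rdname network-metrics
#' @export
avg_clustering <- function(g) {
  stopifnot(igraph::is_igraph(g))
  if (igraph::vcount(g) == 0L) return(NaN)
  igraph::transitivity(g, type = "localaverage", isolates = "zero")
}

#' @rdname network-metrics
#' @export
graph_modularity <- function(g) {
  stopifnot(igraph::is_igraph(g))
  if (igraph::ecount(g) == 0L)
    stop("modularity is undefined on an edgeless graph", call. = FALSE)
  if ("weight" %in% igraph::edge_attr_names(g))
    g <- igraph::delete_edge_attr(g, "weight")  # metrics are topological
  comm <- igraph::cluster_fast_greedy(g)
  # Cut the merge dendrogram at maximum modularity ourselves: qs[i] is the
  # modularity with n - i + 1 communities; within numerical noise of the
  # maximum, prefer the fewest communities (coarsest partition).
  qs <- comm$modularity
  i <- max(which(qs >= max(qs) - 1e-12))
  n_comm <- igraph::vcount(g) - i + 1L
  mem <- if (n_comm <= 1L) rep(1L, igraph::vcount(g))
         else igraph::cut_at(comm, no = n_comm)
  igraph::modularity(g, mem)
}

#' @rdname network-metrics
#' @export
graph_diameter <- function(g) {
  stopifnot(igraph::is_igraph(g))
  if (igraph::vcount(g) > 1L && !igraph::is_connected(g))
    stop(paste("diameter is undefined on a disconnected graph;",
               "extract the largest component first (largest_component())"),
         call. = FALSE)
  as.integer(igraph::diameter(g, weights = NA))
}

#' Largest connected component
#'
#' Induced subgraph on the largest component; used to benchmark against
#' empirical networks whose giant component is the biologically meaningful
#' unit. Size ties are broken in favour of the component containing the
#' smallest vertex index.
#'
#' @param g an igraph habitat network.
#' @return The induced subgraph (the graph itself when already connected).
#' @export
largest_component <- function(g) {
  stopifnot(igraph::is_igraph(g))
  comp <- igraph::components(g)
  if (comp$no <= 1L) return(g)
  best <- which(comp$csize == max(comp$csize))
  if (length(best) > 1L) {
    first_idx <- vapply(best, function(cc) min(which(comp$membership == cc)),
                        integer(1))
    best <- best[which.min(first_idx)]
  }
  igraph::induced_subgraph(g, which(comp$membership == best))
}

#' Metric triple of a habitat network
#'
#' Convenience wrapper computing all three structural metrics at once.
#'
#' @param g an igraph habitat network (connected; diameter is otherwise
#'   undefined).
#' @return A one-row `data.frame` with columns `n_nodes`, `n_edges`,
#'   `clustering`, `modularity`, `diameter` and `community_algorithm` (the
#'   community-detection method behind the modularity value).
#' @examples
#' net <- generate_network(ahn_params(N = 20, seed = 7))
#' network_metrics(net)
#' @export
network_metrics <- function(g) {
  data.frame(n_nodes = igraph::vcount(g),
             n_edges = igraph::ecount(g),
             clustering = avg_clustering(g),
             modularity = graph_modularity(g),
             diameter = graph_diameter(g),
             community_algorithm = "fast_greedy",
             stringsAsFactors = FALSE)
}
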