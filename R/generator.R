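#' Generation parameters for habitat networks
#'
#' Bundles the landscape geometry and the link-formation parameters of the
#' generative model. The filtering function
#' \deqn{P(D) = [1 + \exp(-\lambda (D - \mu))]^{-1}}
#' gives the probability that the link between two patches at Euclidean
#' distance \eqn{D} is removed from the initial complete graph;
#' \eqn{\lambda > 0} sets its steepness and \eqn{\mu} the critical distance
#' at which removal probability crosses one half. `eta` rescales the
#' weights of rewiring links only (\eqn{D^{-\eta}}, default
#' \eqn{\eta = 1}, i.e. the same reciprocal kernel as within-component
#' links).
#'
#' @param A,L landscape area and side length (see [landscape()]).
#' @param N number of habitat patches (positive integer).
#' @param lambda steepness of the link filtering-out function
#'   (`lambda > 0`).
#' @param mu critical distance of the filtering function (any real).
#' @param eta scaler for the weights of rewiring links (`eta >= 1`).
#' @param connected if `TRUE`, rewire disconnected components into a single
#'   connected network.
#' @param weighted if `FALSE`, the returned network is stripped of weights.
#' @param deterministic if `TRUE`, links are removed deterministically
#'   whenever `P(D) > 0.5` (equivalently `D > mu`) instead of by Bernoulli
#'   draws.
#' @param seed optional master seed; sub-seeds are derived for coordinate
#'   sampling and link filtering so the full generation is reproducible.
#' @return An object of class `"ahn_params"`.
#' @examples
#' ahn_params(A = 25, L = 5, N = 30, lambda = 0.35, mu = 5, seed = 1)
#' @export
ahn_params <- function(A = 25, L = 5, N = 30, lambda = 0.35, mu = 5,
                       eta = 1, connected = TRUE, weighted = TRUE,
                       deterministic = FALSE, seed = NULL) {
  land <- landscape(A, L)
  if (!is.numeric(N) || length(N) != 1L || N < 1 || N != round(N))
    stop("'N' must be a positive integer", call. = FALSE)
  if (!is.numeric(lambda) || length(lambda) != 1L || !is.finite(lambda) ||
      lambda <= 0)
    stop("'lambda' must be a single positive number", call. = FALSE)
  if (!is.numeric(mu) || length(mu) != 1L || is.na(mu))
    stop("'mu' must be a single number", call. = FALSE)
  if (!is.numeric(eta) || length(eta) != 1L || !is.finite(eta) || eta < 1)
    stop("'eta' must be a single number >= 1", call. = FALSE)
  structure(list(landscape = land, N = as.integer(N), lambda = lambda,
                 mu = mu, eta = eta, connected = isTRUE(connected),
                 weighted = isTRUE(weighted),
                 deterministic = isTRUE(deterministic), seed = seed),
            class = "ahn_params")
}

#' @export
print.ahn_params <- function(x, ...) {
  cat(sprintf(paste0("Habitat-network parameters: A=%g, L=%g, N=%d, ",
                     "lambda=%g, mu=%g, eta=%g\n"),
              x$landscape$A, x$landscape$L, x$N, x$lambda, x$mu, x$eta)
  )
  cat(sprintf("  connected=%s, weighted=%s, deterministic=%s, seed=%s\n",
              x$connected, x$weighted, x$deterministic,
              if (is.null(x$seed)) "none" else x$seed))
  invisible(x)
}

#' Distance kernel for link weights
#'
#' The default weight of the link between two patches at Euclidean distance
#' `D` is the reciprocal `1/D`, expressing that closer patches are more
#' strongly connected. Alternative kernels (cost-distance, dispersal
#' kernels, attribute similarity) can be supplied wherever a `kernel`
#' argument is accepted; each must be a function of the distance vector.
#'
#' @param D vector of Euclidean distances, all `> 0`.
#' @return `1 / D`.
#' @examples
#' link_weight(c(1, 2, 0.1))  # 1, 0.5, 10
#' @export
link_weight <- function(D) {
  if (!is.numeric(D) || any(!is.finite(D)) || any(D <= 0))
    stop("distances must be positive and finite", call. = FALSE)
  1 / D
}

#' Sigmoidal link-removal probability
#'
#' Probability that the link between two patches at Euclidean distance `D`
#' is filtered out of the complete graph:
#' `P(D) = 1 / (1 + exp(-lambda * (D - mu)))`. It is strictly increasing in
#' `D` (distant patches are less likely to be directly connected), lies
#' strictly in (0, 1), and equals exactly 0.5 at `D = mu`.
#'
#' @param D vector of distances (any real values are admissible).
#' @param lambda steepness (`> 0`).
#' @param mu critical distance (midpoint of the sigmoid).
#' @return Removal probabilities in (0, 1).
#' @examples
#' removal_probability(5, lambda = 0.35, mu = 5)  # exactly 0.5
#' removal_probability(7, lambda = 0.35, mu = 5)  # 1/(1+exp(-0.7))
#' @export
removal_probability <- function(D, lambda, mu) {
  if (!is.numeric(lambda) || length(lambda) != 1L || !is.finite(lambda) ||
      lambda <= 0)
    stop("'lambda' must be a single positive number", call. = FALSE)
  if (!is.numeric(mu) || length(mu) != 1L || is.na(mu))
    stop("'mu' must be a single number", call. = FALSE)
  stats::plogis(lambda * (D - mu))
}

# Canonical edge table of the complete graph over a layout: one row per
# unordered pair (i < j) in lexicographic order, with distances.
complete_edge_table <- function(layout) {
  n <- nrow(layout)
  if (n < 2L)
    return(data.frame(i = integer(), j = integer(), d = numeric()))
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  # order by (i, j): upper.tri gives column-major; reorder explicitly
  o <- order(idx[, 1L], idx[, 2L])
  i <- idx[o, 1L]; j <- idx[o, 2L]
  d <- sqrt((layout$x[i] - layout$x[j])^2 + (layout$y[i] - layout$y[j])^2)
  data.frame(i = i, j = j, d = d)
}

# Assemble an igraph habitat network from a layout and an edge table.
make_habitat_graph <- function(layout, edges, weighted = TRUE) {
  g <- igraph::make_empty_graph(n = nrow(layout), directed = FALSE)
  igraph::V(g)$name <- as.character(layout$id)
  igraph::V(g)$x <- layout$x
  igraph::V(g)$y <- layout$y
  if (!is.null(layout$u)) igraph::V(g)$u <- layout$u
  if (!is.null(layout$v)) igraph::V(g)$v <- layout$v
  if (nrow(edges)) {
    g <- igraph::add_edges(g, rbind(edges$i, edges$j))
    if (weighted) igraph::E(g)$weight <- edges$w
    igraph::E(g)$rewired <- if (!is.null(edges$rewired)) edges$rewired
                            else rep(FALSE, nrow(edges))
  }
  land <- attr(layout, "landscape")
  if (!is.null(land)) {
    g <- igraph::set_graph_attr(g, "A", land$A)
    g <- igraph::set_graph_attr(g, "L", land$L)
  }
  g
}

#' Complete weighted graph over a patch layout
#'
#' First stage of network generation: every pair of patches is linked, with
#' weight given by the distance kernel (reciprocal Euclidean distance by
#' default).
#'
#' @param layout an `"ahn_layout"` (see [sample_layout()],
#'   [validate_layout()]).
#' @param kernel weight kernel, a function of the distance vector; defaults
#'   to [link_weight()].
#' @return An undirected [igraph][igraph::igraph-package] graph with vertex
#'   attributes `name`, `x`, `y` (and `u`, `v` when present), edge
#'   attributes `weight` and `rewired`, and graph attributes `A`, `L`.
#' @examples
#' lay <- sample_layout(landscape(25, 5), 4, seed = 1)
#' igraph::ecount(build_complete_graph(lay))  # choose(4, 2) = 6
#' @export
build_complete_graph <- function(layout, kernel = link_weight) {
  stopifnot(inherits(layout, "ahn_layout"))
  et <- complete_edge_table(layout)
  if (nrow(et) && any(et$d == 0))
    stop("duplicate coordinates: zero distances have undefined weights",
         call. = FALSE)
  et$w <- if (nrow(et)) kernel(et$d) else numeric()
  make_habitat_graph(layout, et)
}

#' Sigmoidal link filtering
#'
#' Second stage of network generation: each link of the complete graph is
#' removed independently with probability [removal_probability()] of its
#' length. In deterministic mode a link is removed whenever its removal
#' probability exceeds one half, i.e. whenever it is longer than `mu`
#' (links at exactly `D = mu` are retained). The result may be
#' disconnected.
#'
#' Removal draws are made in canonical edge order (sorted by the endpoint
#' index pair), so results are reproducible regardless of how the graph
#' stores its edges, and a fixed seed shares per-link uniforms across calls
#' (common random numbers): raising `mu` never removes a link that was
#' retained at a smaller `mu`.
#'
#' @param g a habitat network (typically from [build_complete_graph()]).
#' @param lambda,mu filtering parameters (see [removal_probability()]).
#' @param deterministic logical; threshold filtering instead of Bernoulli
#'   draws.
#' @param seed optional integer seed for the removal draws.
#' @return The filtered graph (possibly disconnected).
#' @export
filter_links <- function(g, lambda, mu, deterministic = FALSE, seed = NULL) {
  stopifnot(igraph::is_igraph(g))
  m <- igraph::ecount(g)
  if (m == 0L) return(g)
  ends <- igraph::ends(g, igraph::E(g), names = FALSE)
  i <- pmin(ends[, 1L], ends[, 2L]); j <- pmax(ends[, 1L], ends[, 2L])
  ord <- order(i, j)
  d <- sqrt((igraph::V(g)$x[i] - igraph::V(g)$x[j])^2 +
            (igraph::V(g)$y[i] - igraph::V(g)$y[j])^2)
  p <- removal_probability(d, lambda, mu)
  if (deterministic) {
    drop <- p > 0.5
  } else {
    u <- numeric(m)
    u[ord] <- with_seed(seed, runif(m))
    drop <- u < p
  }
  igraph::delete_edges(g, which(drop))
}

#' Rewire disconnected components into one connected network
#'
#' Third (optional) stage of network generation: while the network has more
#' than one component, the two spatially closest patches lying in different
#' components are linked. Adding the globally closest inter-component pair
#' each time uses the minimum number of links (exactly one fewer than the
#' number of components) and, starting from an edgeless graph, reproduces
#' the Euclidean minimum spanning tree. Distance ties are broken by the
#' lowest endpoint index pair.
#'
#' Rewired links receive weight `D^(-eta)`; with the default `eta = 1` this
#' is the same reciprocal kernel as within-component links. Larger `eta`
#' down-weights between-component movement. Rewired links are flagged in
#' the edge attribute `rewired`.
#'
#' @param g a habitat network (weighted or not).
#' @param eta rewiring-weight scaler (`>= 1`).
#' @return A connected graph; already-connected input is returned
#'   unchanged.
#' @export
rewire_components <- function(g, eta = 1) {
  stopifnot(igraph::is_igraph(g))
  if (!is.numeric(eta) || length(eta) != 1L || !is.finite(eta) || eta < 1)
    stop("'eta' must be a single number >= 1", call. = FALSE)
  comp <- igraph::components(g)$membership
  if (max(comp) == 1L || igraph::vcount(g) < 2L) return(g)
  x <- igraph::V(g)$x; y <- igraph::V(g)$y
  n <- igraph::vcount(g)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- idx[, 1L]; j <- idx[, 2L]
  d <- sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2)
  ord <- order(d, i, j)  # ties: lowest index pair
  weighted <- "weight" %in% igraph::edge_attr_names(g)
  for (k in ord) {
    if (comp[i[k]] == comp[j[k]]) next
    g <- igraph::add_edges(g, c(i[k], j[k]),
                           attr = c(if (weighted) list(weight = d[k]^(-eta)),
                                    list(rewired = TRUE)))
    comp[comp == comp[j[k]]] <- comp[i[k]]
    if (length(unique(comp)) == 1L) break
  }
  g
}

#' Generate a habitat network
#'
#' Full generation pipeline: sample (or accept) a patch layout, build the
#' complete distance-weighted graph, filter links with the sigmoidal
#' removal probability, optionally rewire components into one connected
#' network, and optionally strip weights. A fixed seed in `params`
#' reproduces the network exactly.
#'
#' @param params an [ahn_params()] object.
#' @param layout optional pre-defined `"ahn_layout"`; when supplied, `N`
#'   is taken from it and no coordinates are sampled.
#' @param kernel weight kernel passed to [build_complete_graph()].
#' @return An igraph habitat network. Graph attributes record the
#'   generation parameters.
#' @examples
#' net <- generate_network(ahn_params(A = 25, L = 5, N = 30, lambda = 0.35,
#'                                    mu = 5, seed = 42))
#' igraph::is_connected(net)
#' @export
generate_network <- function(params, layout = NULL, kernel = link_weight) {
  stopifnot(inherits(params, "ahn_params"))
  if (is.null(layout)) {
    lay_seed <- if (is.null(params$seed)) NULL
                else derive_seed(params$seed, "layout")
    layout <- sample_layout(params$landscape, params$N, seed = lay_seed)
  } else {
    stopifnot(inherits(layout, "ahn_layout"))
  }
  g <- build_complete_graph(layout, kernel = kernel)
  fil_seed <- if (is.null(params$seed)) NULL
              else derive_seed(params$seed, "filter")
  g <- filter_links(g, params$lambda, params$mu,
                    deterministic = params$deterministic, seed = fil_seed)
  if (params$connected) g <- rewire_components(g, eta = params$eta)
  if (!params$weighted && "weight" %in% igraph::edge_attr_names(g))
    g <- igraph::delete_edge_attr(g, "weight")
  for (a in c("lambda", "mu", "eta"))
    g <- igraph::set_graph_attr(g, a, params[[a]])
  g
}
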