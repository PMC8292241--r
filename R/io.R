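#' Read and write habitat networks
#'
#' GraphML is the canonical on-disk format (attribute-rich and portable):
#' vertex attributes `name`, `x`, `y` and optional `u`, `v`; edge
#' attributes `weight` (omitted for unweighted networks) and `rewired`.
#' The CSV format writes a pair of files for spreadsheet workflows: a node
#' table `<prefix>_nodes.csv` (`id, x, y[, u, v]`) and an edge list
#' `<prefix>_edges.csv` (`from, to[, weight], rewired`).
#'
#' A write followed by a read round-trips topology and attributes.
#'
#' @param g an igraph habitat network.
#' @param path output path; for `format = "csv"` this is a prefix, and
#'   `<prefix>_nodes.csv` / `<prefix>_edges.csv` are written.
#' @param format `"graphml"` or `"csv"`.
#' @return `write_habitat_graph()` returns the path(s) invisibly;
#'   `read_habitat_graph()` returns an igraph habitat network.
#' @export
write_habitat_graph <- function(g, path, format = c("graphml", "csv")) {
  stopifnot(igraph::is_igraph(g))
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
    return(invisible(path))
  }
  nodes <- data.frame(id = igraph::V(g)$name, x = igraph::V(g)$x,
                      y = igraph::V(g)$y)
  for (a in c("u", "v")) if (a %in% igraph::vertex_attr_names(g))
    nodes[[a]] <- igraph::vertex_attr(g, a)
  el <- igraph::ends(g, igraph::E(g), names = TRUE)
  edges <- data.frame(from = el[, 1L], to = el[, 2L])
  if ("weight" %in% igraph::edge_attr_names(g))
    edges$weight <- igraph::E(g)$weight
  edges$rewired <- if ("rewired" %in% igraph::edge_attr_names(g))
    igraph::E(g)$rewired else FALSE
  paths <- paste0(path, c("_nodes.csv", "_edges.csv"))
  utils::write.csv(nodes, paths[1L], row.names = FALSE)
  utils::write.csv(edges, paths[2L], row.names = FALSE)
  invisible(paths)
}

#' @rdname write_habitat_graph
#' @export
read_habitat_graph <- function(path, format = c("graphml", "csv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
  } else {
    nodes <- utils::read.csv(paste0(path, "_nodes.csv"),
                             colClasses = c(id = "character"))
    edges <- utils::read.csv(paste0(path, "_edges.csv"))
    unknown <- setdiff(unique(c(as.character(edges$from),
                                as.character(edges$to))), nodes$id)
    if (length(unknown))
      stop(sprintf("edge list references unknown node id(s): %s",
                   paste(unknown, collapse = ", ")), call. = FALSE)
    g <- igraph::graph_from_data_frame(
      transform(edges, from = as.character(from), to = as.character(to)),
      directed = FALSE, vertices = nodes)
  }
  if (!all(c("x", "y") %in% igraph::vertex_attr_names(g)))
    stop("graph file lacks x/y node coordinates", call. = FALSE)
  if ("weight" %in% igraph::edge_attr_names(g) &&
      igraph::ecount(g) > 0L && any(igraph::E(g)$weight <= 0))
    stop("graph file contains non-positive link weights", call. = FALSE)
  g
}

#' Run configurations
#'
#' A run configuration is a flat named list mirroring the command-line
#' flags of the bundled CLI script (`system.file("cli", "habnet.R",
#' package = "habnet")`), stored as YAML. Dumping the effective
#' configuration next to every output makes any artifact regenerable.
#'
#' @param path YAML file path.
#' @param overrides named list (e.g. parsed CLI flags) whose non-`NULL`
#'   entries take precedence over file values.
#' @return `load_run_config()` returns the merged named list;
#'   `dump_run_config()` returns `path` invisibly.
#' @export
load_run_config <- function(path = NULL, overrides = list()) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  valid <- c("command", "area", "side_length", "n_patches", "lambda", "mu",
             "eta", "connected", "weighted", "deterministic", "seed",
             "coords", "out", "n_individuals", "p_stay", "pi", "rho",
             "timesteps", "replicates", "side_lengths", "mus", "lambdas",
             "target_graph", "fixed_network", "graph", "format")
  unknown <- setdiff(names(cfg), valid)
  if (length(unknown))
    stop(sprintf("unknown config key(s): %s (valid keys: %s)",
                 paste(unknown, collapse = ", "),
                 paste(valid, collapse = ", ")), call. = FALSE)
  overrides <- overrides[!vapply(overrides, is.null, logical(1))]
  utils::modifyList(cfg, overrides)
}

#' @rdname load_run_config
#' @param config a named list as returned by `load_run_config()`.
#' @export
dump_run_config <- function(config, path) {
  config$tool_version <- as.character(utils::packageVersion("habnet"))
  yaml::write_yaml(config, path)
  invisible(path)
}
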