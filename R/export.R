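#' Export a network for Cytoscape and downstream tools
#'
#' Writes four text artifacts into `out_dir`: a SIF edge list with
#' interaction labels `pos`/`neg` (regulator first), a GraphML file that
#' round-trips the full attributed graph, a node attribute CSV (`id`,
#' `class`, `family`, `processes`, `shape` with the circle/square/triangle
#' mapping for regulators, genes/proteins and metabolites), and an edge
#' attribute CSV (`tf`, `target`, `r`, `lag`, `n_pairs`, `p`, `sign`).
#' An empty network yields an empty SIF and header-only CSVs.
#'
#' @param net a network from [build_network()].
#' @param out_dir output directory (created if needed).
#' @param basename stem for the file names (default the network name).
#' @return named character vector of the written paths, invisibly.
#' @export
export_network <- function(net, out_dir, basename = NULL) {
  basename <- basename %||% igraph::graph_attr(net, "name") %||% "network"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  et <- edge_table(net)
  paths <- c(
    sif = file.path(out_dir, paste0(basename, ".sif")),
    graphml = file.path(out_dir, paste0(basename, ".graphml")),
    nodes = file.path(out_dir, paste0(basename, "_nodes.csv")),
    edges = file.path(out_dir, paste0(basename, "_edges.csv")))
  writeLines(if (nrow(et))
    sprintf("%s %s %s", et$tf, ifelse(et$sign >= 0, "pos", "neg"), et$target)
    else character(), paths["sif"])
  v <- igraph::V(net)
  nodes <- data.frame(id = v$name, class = v$class, family = v$family,
                      processes = v$processes, shape = v$shape,
                      stringsAsFactors = FALSE)
  write.csv(nodes, paths["nodes"], row.names = FALSE)
  write.csv(et, paths["edges"], row.names = FALSE)
  igraph::write_graph(net, paths["graphml"], format = "graphml")
  invisible(paths)
}

#' Read a GraphML network back
#'
#' Restores a network written by [export_network()]; node and edge
#' attributes survive the round trip.
#'
#' @param path GraphML file.
#' @return an \pkg{igraph} graph.
#' @export
read_network_graphml <- function(path) {
  if (!file.exists(path)) stop_("file not found: ", path)
  igraph::read_graph(path, format = "graphml")
}
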