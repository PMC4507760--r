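#' Assemble the signed tripartite regulatory network
#'
#' Builds an undirected \pkg{igraph} graph from retained correlation
#' edges. Vertices carry `class`, `family`, `processes` (`;`-separated)
#' and the Cytoscape `shape` (regulators circle, genes/proteins square,
#' metabolites triangle); edges carry `r`, `lag`, `n_pairs`, `p`, `sign`,
#' plus `tf`/`target` so the regulator endpoint is always identifiable.
#' Edges must join a regulator to a non-regulator (tripartite/bipartite
#' constraint); duplicate edges per node pair are collapsed to the one
#' with the largest `|r|`. Annotated entities with no retained edge are
#' omitted unless `keep_isolated`.
#'
#' @param edges a [correlate_all()] result (or any data frame with
#'   columns `tf`, `target` and optionally `r`, `lag`, `n_pairs`, `p`,
#'   `sign`).
#' @param ann an [annotations()] table covering every endpoint.
#' @param keep_isolated logical; also include annotated entities without
#'   edges.
#' @param name network name stored as the graph attribute `name`.
#' @return an \pkg{igraph} graph.
#' @export
build_network <- function(edges, ann, keep_isolated = FALSE, name = "whole") {
  stopifnot(inherits(ann, "lagnet_annotations"))
  edges <- as.data.frame(edges)
  if (nrow(edges)) {
    tf_cls <- ann_class(ann, edges$tf)
    tg_cls <- ann_class(ann, edges$target)
    if (any(edges$tf == edges$target)) stop_("bipartite violation: self-loop")
    if (any(!is_regulator_class(tf_cls) | is_regulator_class(tg_cls)))
      stop_("bipartite violation: edges must join a TF/TR to a non-regulator")
    ## deduplicate per node pair, keeping the strongest correlation
    key <- paste(edges$tf, edges$target)
    if (is.null(edges$r)) edges$r <- NA_real_
    edges <- edges[order(key, -abs(edges$r)), , drop = FALSE]
    edges <- edges[!duplicated(paste(edges$tf, edges$target)), , drop = FALSE]
  }
  node_ids <- if (keep_isolated) ann$id else unique(c(edges$tf, edges$target))
  i <- match(node_ids, ann$id)
  if (anyNA(i)) stop_("unannotated node: ",
                      paste(node_ids[is.na(i)], collapse = ", "))
  vert <- data.frame(
    name = node_ids,
    class = ann$class[i],
    family = ann$family[i],
    processes = vapply(ann$processes[i], paste, "", collapse = ";"),
    shape = class_shape(ann$class[i]),
    stringsAsFactors = FALSE)
  ecols <- intersect(c("tf", "target", "r", "lag", "n_pairs", "p", "sign"),
                     names(edges))
  g <- igraph::graph_from_data_frame(
    d = if (nrow(edges)) cbind(edges[c("tf", "target")], edges[ecols])
        else data.frame(from = character(), to = character()),
    directed = FALSE, vertices = vert)
  g <- igraph::set_graph_attr(g, "name", name)
  g
}

regulator_vertices <- function(net)
  igraph::V(net)[is_regulator_class(igraph::V(net)$class)]

## edge table with the regulator endpoint first
edge_table <- function(net) {
  if (igraph::ecount(net) == 0)
    return(data.frame(tf = character(), target = character(),
                      r = numeric(), lag = integer(), n_pairs = integer(),
                      p = numeric(), sign = integer()))
  ends <- igraph::as_edgelist(net)
  cls1 <- igraph::V(net)[ends[, 1]]$class
  swap <- !is_regulator_class(cls1)
  tf <- ifelse(swap, ends[, 2], ends[, 1])
  tg <- ifelse(swap, ends[, 1], ends[, 2])
  data.frame(tf = tf, target = tg,
             r = igraph::E(net)$r %||% NA_real_,
             lag = igraph::E(net)$lag %||% NA_integer_,
             n_pairs = igraph::E(net)$n_pairs %||% NA_integer_,
             p = igraph::E(net)$p %||% NA_real_,
             sign = igraph::E(net)$sign %||% NA_integer_,
             stringsAsFactors = FALSE)
}

#' Induced subnetwork for one biological process
#'
#' Keeps every regulator plus the non-regulator nodes annotated with the
#' given process label, and the edges among them. A process with no
#' annotated nodes yields a regulator-only, zero-edge network.
#'
#' @param net a network from [build_network()].
#' @param process_label one of [process_vocabulary()].
#' @return an \pkg{igraph} graph named after the label.
#' @export
process_subnetwork <- function(net, process_label) {
  if (!process_label %in% process_vocabulary())
    stop_("unknown process label: ", process_label)
  v <- igraph::V(net)
  has <- vapply(strsplit(v$processes %||% rep("", length(v)), ";"),
                function(p) process_label %in% p, TRUE)
  keep <- is_regulator_class(v$class) | has
  g <- igraph::induced_subgraph(net, which(keep))
  igraph::set_graph_attr(g, "name", process_label)
}

#' Mine single-input motifs (SIMs)
#'
#' A SIM is one regulator together with the targets whose only regulator
#' neighbour in the network is that regulator; motifs need at least two
#' such exclusive targets. By construction no target belongs to two
#' motifs.
#'
#' @param net a network from [build_network()].
#' @return list of class `sim_motifs`; each element has `regulator` and
#'   `targets`.
#' @export
find_sims <- function(net) {
  v <- igraph::V(net)
  is_reg <- is_regulator_class(v$class)
  sole <- list()
  for (ti in which(!is_reg)) {
    nb <- igraph::neighbors(net, ti)
    regnb <- nb[is_regulator_class(nb$class)]
    if (length(regnb) == 1)
      sole[[v$name[ti]]] <- regnb$name
  }
  by_reg <- split(names(sole), unlist(sole, use.names = FALSE))
  out <- lapply(names(by_reg)[lengths(by_reg) >= 2], function(r)
    list(regulator = r, targets = sort(by_reg[[r]])))
  structure(out, class = "sim_motifs")
}

#' @export
print.sim_motifs <- function(x, ...) {
  cat(sprintf("%d single-input motif(s)\n", length(x)))
  for (m in x)
    cat(sprintf("  %s -> %d exclusive target(s)\n", m$regulator, length(m$targets)))
  invisible(x)
}

#' Merge single-input motifs into the SIM subnetwork
#'
#' @param motifs a [find_sims()] result mined from `net`.
#' @param net the network the motifs were mined from.
#' @return an \pkg{igraph} graph containing exactly the motif regulators,
#'   their exclusive targets, and the connecting edges; named `"SIM"`.
#' @export
merge_motifs <- function(motifs, net) {
  nodes <- unique(unlist(lapply(motifs, function(m) c(m$regulator, m$targets))))
  g <- igraph::induced_subgraph(net, which(igraph::V(net)$name %in% nodes))
  igraph::set_graph_attr(g, "name", "SIM")
}

#' Degree histograms and scale-free diagnostics
#'
#' Tabulates the degree distribution over all nodes and over regulator
#' nodes, and fits a power law by least squares on logarithmically binned
#' log-log counts (bin edges at powers of two, counts normalised by bin
#' width). The network is flagged `scale_free_like` when the fitted
#' exponent lies in `[1, 4]` and the log-log fit has R-squared at least
#' 0.8 — a conservative diagnostic, not an inferential claim. The fit is
#' only attempted with at least four non-empty degree bins.
#'
#' @param net a network from [build_network()] (or any \pkg{igraph} graph).
#' @return list of class `degree_stats`: `histogram_all`, `histogram_tf`
#'   (data frames `degree`, `count`), `exponent`, `r_squared`, `n_bins`,
#'   `scale_free_like` (`NA` when undetermined), `fit` (binned points).
#' @export
degree_stats <- function(net) {
  if (igraph::vcount(net) == 0) stop_("empty network")
  deg <- igraph::degree(net)
  is_reg <- is_regulator_class(igraph::V(net)$class %||%
                               rep("metabolic_gene", length(deg)))
  hist_df <- function(d) {
    tb <- table(d)
    data.frame(degree = as.integer(names(tb)), count = as.integer(tb))
  }
  out <- list(histogram_all = hist_df(deg), histogram_tf = hist_df(deg[is_reg]),
              exponent = NA_real_, r_squared = NA_real_, n_bins = 0L,
              scale_free_like = NA, fit = NULL)
  d <- deg[deg > 0]
  if (length(d)) {
    edges <- 2^(0:ceiling(log2(max(d) + 1)))
    cnt <- as.integer(table(cut(d, breaks = edges - 0.5)))
    wid <- diff(edges)
    mid <- sqrt(edges[-1] * edges[-length(edges)])
    keep <- cnt > 0
    out$n_bins <- sum(keep)
    if (sum(keep) >= 4) {
      fit <- lm(log10(cnt[keep] / wid[keep]) ~ log10(mid[keep]))
      out$exponent <- -unname(coef(fit)[2])
      out$r_squared <- summary(fit)$r.squared
      out$scale_free_like <- out$exponent >= 1 && out$exponent <= 4 &&
        out$r_squared >= 0.8
      out$fit <- data.frame(degree = mid[keep],
                            density = cnt[keep] / wid[keep])
    }
  }
  structure(out, class = "degree_stats")
}

#' @export
print.degree_stats <- function(x, ...) {
  cat(sprintf("degrees: max %d, %d bins; power-law exponent %s (R^2 %s), scale-free-like: %s\n",
              max(x$histogram_all$degree), x$n_bins,
              format(x$exponent, digits = 3), format(x$r_squared, digits = 3),
              format(x$scale_free_like)))
  invisible(x)
}

#' @export
plot.degree_stats <- function(x, ...) {
  h <- x$histogram_all[x$histogram_all$degree > 0, ]
  plot(h$degree, h$count, log = "xy", xlab = "degree", ylab = "count",
       pch = 19, main = "degree distribution", ...)
  if (!is.na(x$exponent) && !is.null(x$fit)) {
    points(x$fit$degree, x$fit$density, col = "grey50", pch = 1)
    legend("topright", bty = "n",
           legend = sprintf("exponent %.2f, R2 %.2f", x$exponent, x$r_squared))
  }
  invisible(x)
}
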