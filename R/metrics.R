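#' Largest connected component of a graph
#'
#' @param g igraph object.
#' @return Induced subgraph on the largest component (ties broken by the
#'   component containing the lowest vertex index).
#' @export
largest_component <- function(g) {
  comp <- igraph::components(g)
  keep <- which(comp$membership == which.max(comp$csize))
  igraph::induced_subgraph(g, keep)
}

#' Average shortest-path length
#'
#' Mean hop distance over ordered reachable pairs. On disconnected graphs
#' the mean is taken over the largest connected component, with the
#' denominator n(n-1) using that component's size.
#'
#' @param g igraph object.
#' @return Mean path length in hops (`NaN` for graphs with < 2 nodes in the
#'   largest component).
#' @export
average_path_length <- function(g) {
  lcc <- largest_component(g)
  n <- igraph::vcount(lcc)
  if (n < 2L) return(NaN)
  d <- igraph::distances(lcc)
  sum(d[upper.tri(d)]) * 2 / (n * (n - 1))
}

#' Average local clustering coefficient
#'
#' Watts-Strogatz clustering: the mean over all nodes of
#' triangles(v) / choose(k_v, 2), with nodes of degree < 2 contributing 0.
#'
#' @param g igraph object.
#' @return Dimensionless coefficient in \[0, 1\].
#' @export
clustering_coefficient <- function(g) {
  if (igraph::vcount(g) == 0L) return(NaN)
  igraph::transitivity(g, type = "localaverage", isolates = "zero")
}

#' Graph density
#'
#' Edge count over the number of possible edges choose(n, 2).
#'
#' @param g igraph object.
#' @return Density in \[0, 1\].
#' @export
graph_density <- function(g) {
  igraph::edge_density(g)
}

#' Degree assortativity
#'
#' Pearson correlation of endpoint degrees over the (symmetrised) edge list.
#' Degenerate graphs whose edge-endpoint degrees have zero variance (e.g.
#' regular graphs) have no defined correlation: `NaN` is returned with a
#' warning.
#'
#' @param g igraph object.
#' @return Correlation in \[-1, 1\], or `NaN`.
#' @export
assortativity_coefficient <- function(g) {
  if (igraph::ecount(g) == 0L) {
    warning("assortativity undefined: graph has no edges")
    return(NaN)
  }
  deg <- igraph::degree(g)
  ends <- igraph::ends(g, igraph::E(g), names = FALSE)
  dd <- c(deg[ends[, 1]], deg[ends[, 2]])
  if (stats::var(dd) == 0) {
    warning("assortativity undefined: zero degree variance over edges")
    return(NaN)
  }
  igraph::assortativity_degree(g)
}

#' Descriptive network summary
#'
#' One row of the statistics reported per network: node count (`size`), edge
#' count (`order`, following the source tables' naming where "Size" is nodes
#' and "Order" is edges), isolated and pendant node counts, average and
#' maximum degree, diameter, largest-component fraction, average path
#' length, clustering coefficient, density and degree assortativity.
#' Distance-based statistics (diameter, path length) are computed on the
#' largest connected component.
#'
#' @param net igraph object (>= 1 node).
#' @return One-row data frame of class `network_summary`.
#' @export
summarize_network <- function(net) {
  n <- igraph::vcount(net)
  if (n < 1L) stop("summarize_network needs at least one node")
  m <- igraph::ecount(net)
  deg <- igraph::degree(net)
  lcc <- largest_component(net)
  dia <- if (igraph::vcount(lcc) > 1L) max(igraph::distances(lcc)) else 0
  out <- data.frame(
    size = n,
    order = m,
    isolated = sum(deg == 0L),
    pendant = sum(deg == 1L),
    ave_degree = 2 * m / n,
    max_degree = if (n > 0L) max(deg) else 0L,
    diameter = dia,
    largest_cc_fraction = igraph::vcount(lcc) / n,
    ave_path_length = average_path_length(net),
    cluster_coef = clustering_coefficient(net),
    density = graph_density(net),
    assortativity = suppressWarnings(assortativity_coefficient(net)))
  class(out) <- c("network_summary", "data.frame")
  out
}

#' Side-by-side summary table for several networks
#'
#' Formats one or more summaries in the row layout of the descriptive
#' tables: properties as rows, networks as columns.
#'
#' @param summaries Named list of `network_summary` rows (or igraphs, which
#'   are summarised first).
#' @return Data frame with a `property` column and one column per network.
#' @export
summary_table <- function(summaries) {
  if (length(summaries) == 0L) stop("no summaries")
  summaries <- lapply(summaries, function(s)
    if (igraph::is_igraph(s)) summarize_network(s) else s)
  nm <- names(summaries)
  if (is.null(nm)) nm <- paste0("network", seq_along(summaries))
  out <- data.frame(property = names(summaries[[1]]))
  for (i in seq_along(summaries))
    out[[nm[i]]] <- as.numeric(summaries[[i]][1, ])
  out
}
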