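#' Degree centrality
#'
#' Number of connections of each node normalised by the maximum possible on
#' a simple graph, n - 1.
#'
#' @param g igraph object.
#' @return Named numeric vector in \[0, 1\].
#' @export
degree_centrality <- function(g) {
  n <- igraph::vcount(g)
  d <- igraph::degree(g)
  if (n <= 1L) return(d * 0)
  d / (n - 1)
}

#' Eigenvector centrality by power iteration
#'
#' Principal eigenvector of the adjacency matrix (Ax = lambda x), computed
#' by power iteration from a uniform positive start, so on disconnected
#' graphs the scores of the dominant component are reported and the other
#' components decay to 0. Scores are non-negative and have unit Euclidean
#' norm.
#'
#' @param g igraph object with at least one edge.
#' @param tol Convergence tolerance on the max absolute score change.
#' @param max_iter Iteration cap; exceeding it is an error.
#' @return Named numeric vector with unit Euclidean norm.
#' @export
eigenvector_centrality <- function(g, tol = 1e-8, max_iter = 1000) {
  n <- igraph::vcount(g)
  if (igraph::ecount(g) == 0L)
    stop("eigenvector centrality undefined on an edgeless graph")
  A <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  x <- rep(1 / sqrt(n), n)
  for (it in seq_len(max_iter)) {
    # shifted iteration (A + I): same principal eigenvector, but immune
    # to the sign-flip oscillation of bipartite spectra
    x_new <- as.numeric(A %*% x) + x
    nrm <- sqrt(sum(x_new^2))
    if (nrm == 0) stop("power iteration collapsed to the zero vector")
    x_new <- x_new / nrm
    if (max(abs(x_new - x)) < tol) {
      names(x_new) <- igraph::V(g)$name
      return(x_new)
    }
    x <- x_new
  }
  stop("eigenvector centrality did not converge within max_iter = ",
       max_iter, " iterations (tol = ", tol, ")")
}

#' Closeness centrality
#'
#' (n_v - 1) / sum of distances from v to its reachable nodes, where n_v is
#' the size of v's connected component; on disconnected graphs the score is
#' scaled by the component fraction (n_v - 1)/(n - 1), the standard
#' within-component convention. Isolated nodes score 0.
#'
#' @param g igraph object.
#' @return Named numeric vector in \[0, 1\].
#' @export
closeness_centrality <- function(g) {
  n <- igraph::vcount(g)
  d <- igraph::distances(g)
  out <- numeric(n)
  for (v in seq_len(n)) {
    reach <- which(is.finite(d[v, ]) & seq_len(n) != v)
    if (length(reach) == 0L) next
    out[v] <- (length(reach) / sum(d[v, reach])) *
      (length(reach) / (n - 1))
  }
  names(out) <- igraph::V(g)$name
  out
}

#' Betweenness centrality
#'
#' Fraction of shortest s-t paths passing through each node (endpoints
#' excluded), accumulated with Brandes' algorithm; when `normalized` the
#' scores are divided by (n-1)(n-2)/2, the number of node pairs a vertex
#' could lie between.
#'
#' @param g igraph object.
#' @param normalized Report normalised scores (default TRUE).
#' @return Named numeric vector (>= 0).
#' @export
betweenness_centrality <- function(g, normalized = TRUE) {
  igraph::betweenness(g, directed = FALSE, normalized = normalized)
}

#' All four centralities with node annotations
#'
#' @param net igraph from [build_network()].
#' @param tol,max_iter Passed to [eigenvector_centrality()].
#' @return Data frame: `node`, `category`, `subunit`, `degree_c`,
#'   `eigenvector_c`, `closeness_c`, `betweenness_c`.
#' @export
centrality_table <- function(net, tol = 1e-8, max_iter = 1000) {
  data.frame(
    node = igraph::V(net)$name,
    category = igraph::V(net)$category,
    subunit = igraph::V(net)$subunit,
    degree_c = unname(degree_centrality(net)),
    eigenvector_c = unname(eigenvector_centrality(net, tol, max_iter)),
    closeness_c = unname(closeness_centrality(net)),
    betweenness_c = unname(betweenness_centrality(net)),
    stringsAsFactors = FALSE)
}

#' Top-k hubs per centrality measure
#'
#' Orders nodes by descending score for each measure; ties are broken
#' lexicographically by node name (this package's convention).
#'
#' @param scores Either a data frame from [centrality_table()] or a named
#'   numeric vector for a single measure.
#' @param k Number of hubs per measure (default 15).
#' @return For a vector: character vector of the top-k names. For a table:
#'   data frame with one column per measure.
#' @export
rank_hubs <- function(scores, k = 15) {
  top <- function(v, nm) {
    o <- order(-v, nm)
    nm[o][seq_len(min(k, length(nm)))]
  }
  if (is.data.frame(scores)) {
    meas <- intersect(c("degree_c", "eigenvector_c", "closeness_c",
                        "betweenness_c"), names(scores))
    if (length(meas) == 0L) stop("no centrality columns in 'scores'")
    as.data.frame(lapply(stats::setNames(meas, meas), function(mm)
      top(scores[[mm]], scores$node)), stringsAsFactors = FALSE)
  } else {
    if (is.null(names(scores))) stop("scores must be named")
    top(scores, names(scores))
  }
}
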