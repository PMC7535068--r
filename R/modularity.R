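#' Modularity Q of a node partition
#'
#' Q = (1/2m) * sum_ij (A_ij - k_i k_j / 2m) delta(g_i, g_j): the within-
#' community edge fraction in excess of the degree-preserving random
#' expectation. An edgeless graph scores 0 under any partition.
#'
#' @param g igraph object.
#' @param membership Integer/character community labels, one per vertex (in
#'   vertex order, or named by vertex name); every vertex must be covered.
#' @return Modularity score in \[-0.5, 1\].
#' @export
modularity_Q <- function(g, membership) {
  n <- igraph::vcount(g)
  if (!is.null(names(membership))) {
    vn <- igraph::V(g)$name
    if (is.null(vn)) vn <- as.character(seq_len(n))
    if (!setequal(names(membership), vn))
      stop("membership names do not cover the vertex set")
    membership <- membership[vn]
  }
  if (length(membership) != n || anyNA(membership))
    stop("membership must cover all ", n, " nodes")
  m <- igraph::ecount(g)
  if (m == 0L) return(0)
  memb <- as.integer(factor(membership))
  deg <- igraph::degree(g)
  ends <- igraph::ends(g, igraph::E(g), names = FALSE)
  within <- memb[ends[, 1]] == memb[ends[, 2]]
  k <- max(memb)
  d_c <- vapply(seq_len(k), function(cc) sum(deg[memb == cc]), 0)
  l_c <- vapply(seq_len(k), function(cc)
    sum(within & memb[ends[, 1]] == cc), 0)
  sum(l_c / m - (d_c / (2 * m))^2)
}

#' Greedy modularity maximization (Clauset-Newman-Moore)
#'
#' Agglomerative merging of the community pair with the largest modularity
#' gain until no merge increases Q, as implemented by
#' [igraph::cluster_fast_greedy()]; the returned partition is the merge
#' step with maximal modularity. Deterministic for a given graph. An
#' edgeless graph yields the singleton partition with Q = 0.
#'
#' @param g Simple undirected igraph.
#' @return A `community_partition`: list with `membership` (named integer),
#'   `blocks` (list of node-name vectors), `Q`, and the merge history
#'   (`merges`, `modularity_sequence` with entry i giving Q after i - 1
#'   merges).
#' @export
greedy_communities <- function(g) {
  n <- igraph::vcount(g)
  nm <- igraph::V(g)$name
  if (is.null(nm)) nm <- as.character(seq_len(n))
  if (igraph::ecount(g) == 0L) {
    memb <- stats::setNames(seq_len(n), nm)
    return(structure(list(membership = memb,
                          blocks = as.list(nm), Q = 0,
                          merges = matrix(integer(), 0, 2),
                          modularity_sequence = 0),
                     class = "community_partition"))
  }
  cfg <- igraph::cluster_fast_greedy(g)
  # cut the merge sequence at maximal Q; ties go to the later step, so
  # zero-gain merges are still applied (a complete graph stays one block)
  seq_q <- cfg$modularity
  steps <- max(which(seq_q >= max(seq_q) - 1e-12)) - 1L
  memb <- stats::setNames(
    partition_from_merges(n, cfg$merges, steps), nm)
  blocks <- split(nm, memb)
  names(blocks) <- NULL
  structure(list(membership = memb, blocks = blocks,
                 Q = modularity_Q(g, memb),
                 merges = cfg$merges,
                 modularity_sequence = cfg$modularity),
            class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  cat("community_partition:", length(x$blocks), "blocks, Q =",
      round(x$Q, 4), "\n")
  invisible(x)
}

#' Partition after a given number of agglomerative merges
#'
#' Reconstructs the community membership reached after `steps` merges of a
#' merge history (rows merge two community ids; leaves are 1..n, the i-th
#' merge creates community n + i), e.g. to audit the greedy merge sequence
#' against from-scratch modularity evaluation.
#'
#' @param n Number of leaves (graph nodes).
#' @param merges Two-column merge matrix.
#' @param steps Number of merges applied (0 = singleton partition).
#' @return Integer membership vector of length `n`.
#' @export
partition_from_merges <- function(n, merges, steps) {
  stopifnot(steps >= 0, steps <= nrow(merges))
  n <- as.integer(n)
  merges <- matrix(as.integer(merges), ncol = 2)
  parent <- seq_len(n + steps)
  for (i in seq_len(steps)) {
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    parent[find(merges[i, 1])] <- n + i
    parent[find(merges[i, 2])] <- n + i
  }
  root <- vapply(seq_len(n), function(x) {
    while (parent[x] != x) x <- parent[x]
    as.integer(x)
  }, 0L)
  as.integer(factor(root))
}

#' Recursive modularity decomposition
#'
#' Runs [greedy_communities()] on the whole network, then independently on
#' the induced subgraph of every resulting block with at least `min_size`
#' nodes (edges leaving a block are ignored at deeper levels), recursing
#' until blocks are small or a decomposition returns a single block.
#'
#' @param g igraph object.
#' @param min_size Minimum block size to decompose further (default 9,
#'   with >= semantics).
#' @return A `community_tree`: nested list with `label` (path-like, e.g.
#'   `"2/1"`), `nodes`, `depth`, `Q` and `children` (NULL at leaves).
#' @export
recursive_decomposition <- function(g, min_size = 9) {
  nm <- igraph::V(g)$name
  if (is.null(nm)) {
    nm <- as.character(seq_len(igraph::vcount(g)))
    igraph::V(g)$name <- nm
  }
  descend <- function(sub, label, depth) {
    node <- list(label = label, nodes = igraph::V(sub)$name,
                 depth = depth, Q = NA_real_, children = NULL)
    part <- greedy_communities(sub)
    node$Q <- part$Q
    if (length(part$blocks) < 2L) return(node)
    node$children <- lapply(seq_along(part$blocks), function(i) {
      blk <- part$blocks[[i]]
      child_label <- if (label == "") as.character(i)
                     else paste(label, i, sep = "/")
      child <- list(label = child_label, nodes = blk, depth = depth + 1L,
                    Q = NA_real_, children = NULL)
      if (length(blk) >= min_size)
        descend(igraph::induced_subgraph(sub, blk), child_label,
                depth + 1L)
      else child
    })
    node
  }
  structure(descend(g, "", 0L), class = "community_tree")
}

#' Leaf community labels of a decomposition tree
#'
#' @param tree A `community_tree`.
#' @return Data frame with columns `node` and `community` (path-like leaf
#'   label, e.g. `"2/1"`; `"0"` when the root did not split).
#' @export
community_labels <- function(tree) {
  rows <- list()
  walk <- function(nd) {
    if (is.null(nd$children)) {
      lbl <- if (nd$label == "") "0" else nd$label
      rows[[length(rows) + 1L]] <<- data.frame(
        node = nd$nodes, community = lbl, stringsAsFactors = FALSE)
    } else {
      for (ch in nd$children) walk(ch)
    }
  }
  walk(tree)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Tree depth of a decomposition
#'
#' @param tree A `community_tree`.
#' @return Integer: 1 for a root-only tree, 2 when the root split once, ...
#' @export
tree_depth <- function(tree) {
  walk <- function(nd) {
    if (is.null(nd$children)) return(1L)
    1L + max(vapply(nd$children, walk, 0L))
  }
  walk(tree)
}
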