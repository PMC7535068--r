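# Independent brute-force oracles used to validate the graph machinery.
# They work directly on adjacency matrices and deliberately avoid the code
# paths (and igraph routines) used by the package functions they check.

adj_of <- function(g) {
  as.matrix(igraph::as_adjacency_matrix(g))
}

# all-pairs shortest paths by Floyd-Warshall
bf_distances <- function(A) {
  n <- nrow(A)
  d <- ifelse(A > 0, 1, Inf)
  diag(d) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

bf_largest_component <- function(A) {
  d <- bf_distances(A)
  n <- nrow(A)
  seen <- rep(FALSE, n)
  best <- integer()
  for (i in seq_len(n)) {
    if (seen[i]) next
    comp <- which(is.finite(d[i, ]))
    seen[comp] <- TRUE
    if (length(comp) > length(best)) best <- comp
  }
  best
}

bf_avg_path_length <- function(A) {
  comp <- bf_largest_component(A)
  if (length(comp) < 2) return(NaN)
  d <- bf_distances(A[comp, comp, drop = FALSE])
  mean(d[row(d) != col(d)])
}

bf_diameter <- function(A) {
  comp <- bf_largest_component(A)
  if (length(comp) < 2) return(0)
  max(bf_distances(A[comp, comp, drop = FALSE]))
}

# Watts-Strogatz average local clustering; degree < 2 contributes 0
bf_clustering <- function(A) {
  n <- nrow(A)
  cc <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(A[v, ] > 0)
    k <- length(nb)
    if (k < 2) next
    links <- sum(A[nb, nb]) / 2
    cc[v] <- links / choose(k, 2)
  }
  mean(cc)
}

bf_density <- function(A) {
  n <- nrow(A)
  (sum(A) / 2) / choose(n, 2)
}

# textbook degree-degree Pearson correlation over symmetrised edge ends
bf_assortativity <- function(A) {
  n <- nrow(A)
  js <- c(); ks <- c()
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) if (A[i, j] > 0) {
    di <- sum(A[i, ]); dj <- sum(A[j, ])
    js <- c(js, di, dj); ks <- c(ks, dj, di)
  }
  num <- mean(js * ks) - mean(js) * mean(ks)
  den <- sqrt(mean(js^2) - mean(js)^2) * sqrt(mean(ks^2) - mean(ks)^2)
  num / den
}

bf_closeness <- function(A) {
  n <- nrow(A)
  d <- bf_distances(A)
  vapply(seq_len(n), function(v) {
    reach <- which(is.finite(d[v, ]) & seq_len(n) != v)
    if (length(reach) == 0) return(0)
    (length(reach) / sum(d[v, reach])) * (length(reach) / (n - 1))
  }, 0)
}

# betweenness by explicit enumeration of all shortest simple paths
bf_betweenness <- function(g, normalized = TRUE) {
  n <- igraph::vcount(g)
  A <- adj_of(g)
  d <- bf_distances(A)
  score <- numeric(n)
  for (s in seq_len(n - 1)) for (t in seq(s + 1, n)) {
    if (!is.finite(d[s, t]) || d[s, t] == 0) next
    paths <- igraph::all_simple_paths(g, from = s, to = t,
                                      cutoff = d[s, t])
    paths <- Filter(function(p) length(p) - 1 == d[s, t], paths)
    sigma <- length(paths)
    for (v in setdiff(seq_len(n), c(s, t))) {
      through <- sum(vapply(paths, function(p) v %in% as.integer(p),
                            TRUE))
      score[v] <- score[v] + through / sigma
    }
  }
  if (normalized) score <- score / ((n - 1) * (n - 2) / 2)
  stats::setNames(score, igraph::V(g)$name)
}

# Q by the literal double sum over the adjacency matrix
bf_modularity <- function(g, membership) {
  A <- adj_of(g)
  m <- sum(A) / 2
  if (m == 0) return(0)
  k <- rowSums(A)
  n <- nrow(A)
  q <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    if (membership[i] == membership[j])
      q <- q + A[i, j] - k[i] * k[j] / (2 * m)
  q / (2 * m)
}

# seeded random graph family used by the property tests
random_graph <- function(n, p, seed) {
  set.seed(seed)
  igraph::sample_gnp(n, p)
}

# adjusted Rand index between two label vectors
ari <- function(a, b) {
  mclust::adjustedRandIndex(a, b)
}

# small labelled element network built by hand
make_labelled_net <- function(edges, categories, subunits) {
  nodes <- data.frame(name = names(categories),
                      category = unname(categories),
                      subunit = unname(subunits),
                      stringsAsFactors = FALSE)
  build_network(nodes,
                data.frame(element_a = edges[, 1], element_b = edges[, 2],
                           stringsAsFactors = FALSE))
}

# default toy element table used across structure/SASA tests
toy_elements <- function(n_atoms = c(30, 20, 20, 15, 15)) {
  k <- length(n_atoms)
  data.frame(
    name = paste0("E", seq_len(k)),
    category = rep_len(c("rRNA_domain", "rprotein", "rprotein", "tRNA",
                         "mRNA"), k),
    subunit = rep_len(c("50S", "50S", "30S", "none", "none"), k),
    n_atoms = n_atoms,
    stringsAsFactors = FALSE)
}
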