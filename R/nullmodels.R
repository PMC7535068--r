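#' Erdos-Renyi null ensemble
#'
#' Generates `reps` G(n, p) graphs and averages the descriptive statistics
#' per replicate; distance statistics (path length, diameter) are computed
#' on each replicate's largest connected component. Replicate assortativity
#' is averaged over the replicates where it is defined (at least one edge
#' and non-degenerate degrees). Runs are reproducible given `seed`.
#'
#' @param n Nodes (>= 2).
#' @param p Attachment probability in \[0, 1\].
#' @param reps Number of replicates (>= 1).
#' @param seed Optional integer seed.
#' @return An `er_ensemble`: list with `means` and `sds` (named over the
#'   [summarize_network()] fields), `reps`, `n`, `p`, `seed`.
#' @export
er_ensemble <- function(n, p, reps = 5000, seed = NULL) {
  stopifnot(n >= 2, p >= 0, p <= 1, reps >= 1)
  if (!is.null(seed)) set.seed(seed)
  fields <- c("size", "order", "isolated", "pendant", "ave_degree",
              "max_degree", "diameter", "largest_cc_fraction",
              "ave_path_length", "cluster_coef", "density", "assortativity")
  stats <- matrix(NA_real_, nrow = reps, ncol = length(fields),
                  dimnames = list(NULL, fields))
  for (rpt in seq_len(reps)) {
    g <- igraph::sample_gnp(n, p)
    deg <- igraph::degree(g)
    m <- igraph::ecount(g)
    comp <- igraph::components(g)
    lcc <- igraph::induced_subgraph(g, which(comp$membership ==
                                             which.max(comp$csize)))
    nl <- igraph::vcount(lcc)
    if (nl > 1L) {
      d <- igraph::distances(lcc)
      L <- sum(d[upper.tri(d)]) * 2 / (nl * (nl - 1))
      dia <- max(d)
    } else {
      L <- NA_real_; dia <- 0
    }
    asr <- if (m > 0L) {
      ends <- igraph::ends(g, igraph::E(g), names = FALSE)
      dd <- c(deg[ends[, 1]], deg[ends[, 2]])
      if (stats::var(dd) > 0) igraph::assortativity_degree(g) else NA_real_
    } else NA_real_
    stats[rpt, ] <- c(n, m, sum(deg == 0L), sum(deg == 1L), 2 * m / n,
                      max(deg), dia, nl / n, L,
                      igraph::transitivity(g, type = "localaverage",
                                           isolates = "zero"),
                      igraph::edge_density(g), asr)
  }
  structure(list(means = colMeans(stats, na.rm = TRUE),
                 sds = apply(stats, 2, stats::sd, na.rm = TRUE),
                 reps = as.integer(reps), n = as.integer(n), p = p,
                 seed = seed),
            class = "er_ensemble")
}

#' @export
print.er_ensemble <- function(x, ...) {
  cat(sprintf("Erdos-Renyi ensemble: %d replicates of G(%d, %.4g)\n",
              x$reps, x$n, x$p))
  print(round(x$means, 4))
  invisible(x)
}

#' Periodic nearest-unconnected-neighbour ring lattice
#'
#' Deterministic regular null model: n nodes on a ring, edges added in
#' rounds of increasing circular neighbour distance (all distance-1 edges,
#' then all distance-2 edges, ...), within a round in ascending node index,
#' stopping exactly at `m` edges. For (n = 68, m = 235) this yields degrees
#' in 6..8 with maximum degree 8.
#'
#' @param n Nodes (>= 2).
#' @param m Edges (<= n(n-1)/2).
#' @return igraph object with exactly `m` edges.
#' @export
ring_lattice <- function(n, m) {
  stopifnot(n >= 2, m >= 0)
  if (m > n * (n - 1) / 2)
    stop("m = ", m, " exceeds the ", n * (n - 1) / 2,
         " possible edges on ", n, " nodes")
  from <- integer(m); to <- integer(m)
  count <- 0L; d <- 1L
  while (count < m) {
    half_ring <- d * 2L == n  # distance n/2 pairs appear once, not twice
    for (i in 0:(n - 1L)) {
      if (half_ring && i >= n / 2) break
      count <- count + 1L
      from[count] <- i + 1L
      to[count] <- (i + d) %% n + 1L
      if (count == m) break
    }
    d <- d + 1L
  }
  igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
}

#' Small-world coefficient sigma
#'
#' (C / C_rand) / (L / L_rand); sigma > 1 indicates a small-world network.
#'
#' @param C,L Observed clustering coefficient and average path length.
#' @param C_rand,L_rand Random-ensemble means of the same quantities.
#' @return Dimensionless sigma.
#' @export
sw_sigma <- function(C, C_rand, L, L_rand) {
  (C / C_rand) / (L / L_rand)
}

#' Small-world measure omega
#'
#' L_rand / L - C / C_reg; omega near 0 (roughly -0.5 < omega < 0.5)
#' indicates a small-world network, -1 a lattice-like and +1 a random-like
#' graph.
#'
#' @param L,C Observed average path length and clustering coefficient.
#' @param L_rand Random-ensemble mean path length.
#' @param C_reg Clustering coefficient of the matched regular lattice.
#' @return Dimensionless omega.
#' @export
sw_omega <- function(L, L_rand, C, C_reg) {
  L_rand / L - C / C_reg
}

#' Small-world analysis of a network
#'
#' Compares the observed clustering and path length against an Erdos-Renyi
#' ensemble matched in size and density (p = m / choose(n, 2)) and a
#' matched [ring_lattice()], and evaluates [sw_sigma()] and [sw_omega()].
#'
#' @param net igraph object.
#' @param reps Ensemble replicates.
#' @param seed Optional integer seed for the ensemble.
#' @return A `small_world_stats` list: `sigma`, `omega`, the components
#'   (`C`, `C_rand`, `C_reg`, `L`, `L_rand`), plus the full `ensemble` and
#'   `lattice` objects.
#' @export
small_world_stats <- function(net, reps = 5000, seed = NULL) {
  n <- igraph::vcount(net)
  m <- igraph::ecount(net)
  p <- m / choose(n, 2)
  ens <- er_ensemble(n, p, reps = reps, seed = seed)
  lat <- ring_lattice(n, m)
  C <- clustering_coefficient(net)
  L <- average_path_length(net)
  C_rand <- unname(ens$means["cluster_coef"])
  L_rand <- unname(ens$means["ave_path_length"])
  C_reg <- clustering_coefficient(lat)
  structure(list(sigma = sw_sigma(C, C_rand, L, L_rand),
                 omega = sw_omega(L, L_rand, C, C_reg),
                 C = C, C_rand = C_rand, C_reg = C_reg,
                 L = L, L_rand = L_rand,
                 ensemble = ens, lattice = lat),
            class = "small_world_stats")
}

#' @export
print.small_world_stats <- function(x, ...) {
  cat(sprintf(paste0("small-world: sigma = %.3f, omega = %.3f\n",
                     "  C = %.3f, C_rand = %.3f, C_reg = %.3f\n",
                     "  L = %.3f, L_rand = %.3f\n"),
              x$sigma, x$omega, x$C, x$C_rand, x$C_reg, x$L, x$L_rand))
  invisible(x)
}

#' Observed / random / regular comparison table
#'
#' Three-column report (observed network, ensemble means, ring lattice)
#' over the descriptive statistics, with sigma and omega appended; the
#' ensemble seed is recorded in attribute `seed`.
#'
#' @param net igraph object.
#' @param sw A `small_world_stats` for `net` (computed if omitted).
#' @inheritParams small_world_stats
#' @return Data frame with columns `property`, `observed`, `random`,
#'   `regular`.
#' @export
null_model_table <- function(net, sw = NULL, reps = 5000, seed = NULL) {
  if (is.null(sw)) sw <- small_world_stats(net, reps = reps, seed = seed)
  obs <- summarize_network(net)
  reg <- summarize_network(sw$lattice)
  fields <- names(obs)
  out <- data.frame(
    property = c(fields, "sigma", "omega"),
    observed = c(as.numeric(obs[1, ]), sw$sigma, sw$omega),
    random = c(unname(sw$ensemble$means[fields]), NA, NA),
    regular = c(as.numeric(reg[1, ]), NA, NA))
  attr(out, "seed") <- sw$ensemble$seed
  out
}
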