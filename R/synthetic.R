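# --- synthetic fixtures: structures with planted contacts, ribosome-like
# --- networks and planted-partition graphs. All generators are seeded and
# --- bit-reproducible.

# compact carbon blob: one central atom plus golden-spiral shells 3 A apart
.blob_coords <- function(n_atoms, jitter = 0.15) {
  stopifnot(n_atoms >= 1)
  pts <- matrix(0, 1, 3)
  shell <- 1L
  while (nrow(pts) < n_atoms) {
    cap <- 11L * shell^2  # close to the area-proportional capacity
    take <- min(cap, n_atoms - nrow(pts))
    pts <- rbind(pts, sphere_points(take) * 3 * shell)
    shell <- shell + 1L
  }
  pts + matrix(stats::runif(3 * nrow(pts), -jitter, jitter), ncol = 3)
}

# well separated unit directions used to place children around a parent
.direction_bank <- function() {
  sphere_points(26)
}

#' Generate a toy multi-chain structure with planted contacts
#'
#' Builds each element as a compact blob of carbon atoms (one chain per
#' element), positions blobs so that exactly the planted adjacency pairs
#' touch (surface gap `contact_gap`, less than one probe diameter, so
#' pairing them buries solvent-accessible area) while every other pair is
#' separated by at least `apart_gap`. Along every planted contact one
#' dedicated surface atom per element faces the partner, making the burial
#' unambiguous. The planted adjacency must be a forest (trees are placed by
#' breadth-first traversal); denser mutual-contact patterns are rejected as
#' infeasible. Deterministic given `seed`.
#'
#' @param elements Data frame with columns `name`, `category`, `subunit`,
#'   `n_atoms` (one row per element; at most 52 elements, one PDB chain
#'   each).
#' @param adjacency Planted contacts: 2-column matrix or data frame of
#'   element-name pairs (may be empty).
#' @param contact_gap Surface separation of touching pairs in Angstrom;
#'   must be < 2.8 (one probe diameter).
#' @param apart_gap Minimum surface separation of non-touching pairs; must
#'   exceed 2 * probe + 2 * max vdW radius = 6.2.
#' @param seed Integer seed.
#' @param path Optional output path; when given the structure is written as
#'   a PDB file.
#' @return A `toy_structure`: list with `model` (a `structure_model`),
#'   `element_map`, `adjacency` (canonicalised pair data frame),
#'   `n_atoms_total` (declared atom count incl. the per-contact surface
#'   atoms) and `file` (the PDB path or NULL).
#' @export
generate_toy_structure <- function(elements, adjacency = NULL,
                                   contact_gap = 1.0, apart_gap = 8,
                                   seed = 1, path = NULL) {
  stopifnot(is.data.frame(elements),
            all(c("name", "category", "subunit", "n_atoms") %in%
                names(elements)))
  k <- nrow(elements)
  if (k > 52L) stop("at most 52 elements (one chain letter each)")
  if (anyDuplicated(elements$name)) stop("duplicate element names")
  vdw <- 1.7  # all atoms are carbon
  probe <- 1.4
  if (contact_gap >= 2 * probe)
    stop("contact_gap must be < ", 2 * probe,
         " so that touching pairs bury area")
  if (apart_gap <= 2 * probe + 2 * vdw)
    stop("apart_gap must exceed ", 2 * probe + 2 * vdw)

  adj <- if (is.null(adjacency) || NROW(adjacency) == 0L) {
    data.frame(a = character(), b = character(), stringsAsFactors = FALSE)
  } else {
    adjacency <- as.matrix(adjacency)
    bad <- setdiff(unique(c(adjacency)), elements$name)
    if (length(bad)) stop("adjacency references unknown element(s): ",
                          paste(bad, collapse = ", "))
    data.frame(a = pmin(adjacency[, 1], adjacency[, 2]),
               b = pmax(adjacency[, 1], adjacency[, 2]),
               stringsAsFactors = FALSE)
  }
  adj <- unique(adj)
  if (any(adj$a == adj$b)) stop("self-contacts are not allowed")

  ag <- igraph::graph_from_data_frame(
    adj, directed = FALSE,
    vertices = data.frame(name = elements$name))
  if (igraph::ecount(ag) > 0L &&
      igraph::ecount(ag) > igraph::vcount(ag) -
        igraph::components(ag)$no)
    stop("infeasible packing: planted adjacency contains a cycle; ",
         "only forest adjacencies can be embedded")

  set.seed(seed)
  blobs <- lapply(elements$n_atoms, .blob_coords)
  rho <- vapply(blobs, function(b) max(sqrt(rowSums(b^2))), 0)
  names(blobs) <- names(rho) <- elements$name

  # place tree components one after another along x, far apart
  centres <- matrix(NA_real_, k, 3, dimnames = list(elements$name, NULL))
  dirs <- .direction_bank()
  comp <- igraph::components(ag)
  offset <- 0
  touch_dist <- function(a, b) rho[a] + rho[b] + 2 * vdw + contact_gap
  for (cc in seq_len(comp$no)) {
    members <- elements$name[comp$membership == cc]
    root <- members[1]
    centres[root, ] <- c(offset, 0, 0)
    if (length(members) > 1L) {
      order_bfs <- igraph::bfs(ag, root = root, unreachable = FALSE)$order
      order_bfs <- igraph::V(ag)$name[order_bfs[!is.na(order_bfs)]]
      used_dir <- list()
      for (v in order_bfs[-1]) {
        parent <- intersect(igraph::neighbors(ag, v)$name,
                            rownames(centres)[!is.na(centres[, 1])])[1]
        taken <- used_dir[[parent]]
        if (is.null(taken)) taken <- matrix(0, 0, 3)
        score <- apply(dirs, 1, function(u)
          if (nrow(taken) == 0) 1 else min(acos(pmin(1, pmax(-1,
            taken %*% u)))))
        u <- dirs[which.max(score), ]
        used_dir[[parent]] <- rbind(taken, u, deparse.level = 0)
        used_dir[[v]] <- matrix(-u, 1, 3)
        centres[v, ] <- centres[parent, ] + u * touch_dist(parent, v)
      }
    }
    span <- max(centres[members, 1] + rho[members])
    offset <- span + apart_gap + 2 * vdw + max(rho) * 2 + 10
  }

  # one dedicated surface atom per element per planted contact
  extra <- stats::setNames(vector("list", k), elements$name)
  for (q in seq_len(nrow(adj))) {
    a <- adj$a[q]; b <- adj$b[q]
    u <- centres[b, ] - centres[a, ]
    u <- u / sqrt(sum(u^2))
    gap_now <- sqrt(sum((centres[b, ] - centres[a, ])^2))
    stopifnot(abs(gap_now - touch_dist(a, b)) < 1e-6)
    extra[[a]] <- rbind(extra[[a]], u * rho[a])
    extra[[b]] <- rbind(extra[[b]], -u * rho[b])
  }

  chains <- c(LETTERS, letters)[seq_len(k)]
  atoms <- do.call(rbind, lapply(seq_len(k), function(i) {
    xyz <- rbind(blobs[[i]], extra[[i]])
    xyz <- sweep(xyz, 2, centres[i, ], "+")
    data.frame(chain = chains[i], resno = seq_len(nrow(xyz)),
               resid = "UNK", elety = "C", elesy = "C",
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
               radius = vdw, hetero = FALSE, stringsAsFactors = FALSE)
  }))

  # verify the planted geometry: non-adjacent pairs must stay apart
  planted_key <- paste(adj$a, adj$b)
  for (i in seq_len(k - 1)) for (j in seq(i + 1, length.out = k - i)) {
    ai <- atoms[atoms$chain == chains[i], c("x", "y", "z")]
    aj <- atoms[atoms$chain == chains[j], c("x", "y", "z")]
    gap <- sqrt(min(outer(rowSums(ai^2), rowSums(aj^2), "+") -
                    2 * as.matrix(ai) %*% t(as.matrix(aj)))) - 2 * vdw
    key <- paste(min(elements$name[c(i, j)]), max(elements$name[c(i, j)]))
    if (!(key %in% planted_key) && gap < apart_gap)
      stop("infeasible packing: elements ", elements$name[i], " and ",
           elements$name[j], " ended up ", round(gap, 2),
           " A apart (< apart_gap)")
  }

  model <- structure(list(atoms = atoms, source_id = "toy",
                          model_index = 1L), class = "structure_model")
  emap <- element_map(lapply(seq_len(k), function(i)
    list(name = elements$name[i], category = elements$category[i],
         subunit = elements$subunit[i], chain = chains[i],
         ranges = "all")))
  if (!is.null(path)) write_structure(model, path)
  structure(list(model = model, element_map = emap, adjacency = adj,
                 n_atoms_total = nrow(atoms),
                 file = path),
            class = "toy_structure")
}

#' Generate a ribosome-like random network
#'
#' Statistical stand-in for an element contact network: a configuration-
#' model simple graph over a degree sequence with a few high-degree hub
#' nodes (the rRNA-domain stand-ins) and many low-degree nodes (rprotein
#' stand-ins), which produces the hub-periphery wiring and negative degree
#' assortativity seen in the real networks. Node and edge counts are exact.
#'
#' @param n_nodes,n_edges Graph size (defaults 68 nodes, 235 edges).
#' @param n_hubs Number of hub nodes (default 12); 0 gives a near-uniform
#'   low-degree sequence.
#' @param hub_degree_range Inclusive integer range hub degrees are drawn
#'   from (default 12..23).
#' @param max_low_degree Degree cap for non-hub nodes (default 8).
#' @param seed Integer seed.
#' @return igraph with vertex attributes `category` (rRNA_domain for hubs,
#'   rprotein otherwise) and `subunit` (split 50S/30S), named like rRNA
#'   domains and r-proteins.
#' @export
generate_ribosome_like_network <- function(n_nodes = 68, n_edges = 235,
                                           n_hubs = 12,
                                           hub_degree_range = c(12, 23),
                                           max_low_degree = 8,
                                           seed = NULL) {
  stopifnot(n_nodes > n_hubs, n_edges >= n_nodes - 1)
  if (!is.null(seed)) set.seed(seed)
  n_low <- n_nodes - n_hubs
  total <- 2L * n_edges
  for (attempt in 1:100) {
    hub_deg <- if (n_hubs > 0L)
      sample(seq(hub_degree_range[1], hub_degree_range[2]), n_hubs,
             replace = TRUE) else integer()
    rem <- total - sum(hub_deg)
    if (rem < n_low || rem > n_low * max_low_degree) next
    low_deg <- rep(1L, n_low)
    spare <- rem - n_low
    while (spare > 0L) {
      cand <- which(low_deg < max_low_degree)
      pick <- cand[sample.int(length(cand), 1L)]
      low_deg[pick] <- low_deg[pick] + 1L
      spare <- spare - 1L
    }
    degs <- c(hub_deg, low_deg)
    g <- tryCatch(igraph::sample_degseq(degs, method = "vl"),
                  error = function(e) NULL)
    if (!is.null(g)) {
      su <- c(rep(c("50S", "30S"), length.out = n_hubs),
              rep(c("50S", "30S"), length.out = n_low))
      hub_names <- if (n_hubs > 0) paste0("rRNA-D", seq_len(n_hubs))
                   else character()
      low_names <- paste0(ifelse(su[seq_len(n_low) + n_hubs] == "50S",
                                 "L", "S"), seq_len(n_low))
      igraph::V(g)$name <- c(hub_names, low_names)
      igraph::V(g)$category <- c(rep("rRNA_domain", n_hubs),
                                 rep("rprotein", n_low))
      igraph::V(g)$subunit <- su
      igraph::E(g)$class <- NA_character_
      g <- igraph::set_graph_attr(g, "source_id", "synthetic")
      igraph::E(g)$class <- edge_classes(g)
      igraph::E(g)$intersubunit <- .intersubunit_flags(g)
      return(g)
    }
  }
  stop("could not realise a simple graph for the requested degree ",
       "sequence after 100 attempts")
}

#' Generate a planted-partition (stochastic block model) graph
#'
#' Within-group edges appear with probability `p_in`, between-group edges
#' with `p_out`; the planted labels are returned as the vertex attribute
#' `block`.
#'
#' @param k_groups Number of groups.
#' @param sizes Group sizes: scalar (equal sizes) or length-`k_groups`
#'   vector.
#' @param p_in,p_out Within/between edge probabilities.
#' @param seed Integer seed.
#' @return igraph with vertex attributes `name` and `block`.
#' @export
generate_planted_partition <- function(k_groups, sizes, p_in, p_out,
                                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (length(sizes) == 1L) sizes <- rep(sizes, k_groups)
  stopifnot(length(sizes) == k_groups)
  pm <- matrix(p_out, k_groups, k_groups)
  diag(pm) <- p_in
  g <- igraph::sample_sbm(sum(sizes), pref.matrix = pm,
                          block.sizes = sizes)
  igraph::V(g)$block <- rep(seq_len(k_groups), sizes)
  igraph::V(g)$name <- paste0("g", igraph::V(g)$block, "_",
                              unlist(lapply(sizes, seq_len)))
  g
}
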