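#' Assemble the element interaction network
#'
#' Nodes are all elements (including any that end up with no contacts);
#' edges are the interaction calls flagged `is_interaction`. The result is a
#' simple undirected igraph with vertex attributes `category` and `subunit`,
#' per-edge `class` labels (see [edge_classes()]) and graph-level provenance
#' (`source_id`, `state`).
#'
#' @param elements List of `element` objects, or a data frame with columns
#'   `name`, `category`, `subunit`.
#' @param calls Interaction calls from [detect_interactions()] (or an edge
#'   data frame with `element_a`/`element_b` columns; an `is_interaction`
#'   column, when present, filters the rows).
#' @param source_id,state Provenance labels stored on the graph.
#' @return An igraph object.
#' @export
build_network <- function(elements, calls, source_id = "", state = "") {
  v <- if (is.data.frame(elements)) elements else
    data.frame(name = vapply(elements, function(e) e$name, ""),
               category = vapply(elements, function(e) e$category, ""),
               subunit = vapply(elements, function(e) e$subunit, ""),
               stringsAsFactors = FALSE)
  if (anyDuplicated(v$name)) stop("duplicate element names")
  ed <- calls
  if ("is_interaction" %in% names(ed))
    ed <- ed[ed$is_interaction, , drop = FALSE]
  bad <- setdiff(unique(c(ed$element_a, ed$element_b)), v$name)
  if (length(bad) > 0L)
    stop("interaction calls reference unknown element(s): ",
         paste(bad, collapse = ", "))
  edges <- data.frame(from = ed$element_a, to = ed$element_b,
                      stringsAsFactors = FALSE)
  if ("buried_area" %in% names(ed)) edges$buried_area <- ed$buried_area
  g <- igraph::graph_from_data_frame(edges, directed = FALSE, vertices = v)
  g <- igraph::simplify(g, edge.attr.comb = "first")
  igraph::E(g)$class <- edge_classes(g)
  igraph::E(g)$intersubunit <- .intersubunit_flags(g)
  g <- igraph::set_graph_attr(g, "source_id", source_id)
  igraph::set_graph_attr(g, "state", state)
}

.check_categories <- function(net) {
  if (!"category" %in% igraph::vertex_attr_names(net))
    stop("network lacks a 'category' vertex attribute")
}

#' Per-edge interaction class labels
#'
#' Classes partition the edges with the precedence: any edge touching a tRNA
#' or mRNA node is `mrna_trna`; otherwise two RNA endpoints give `rrna_rrna`;
#' two protein endpoints (ribosomal protein or elongation factor) give
#' `rprot_rprot`; the rest are `rrna_rprot`. Nodes of category `other` are
#' treated as protein-like, with a warning.
#'
#' @param net An igraph from [build_network()].
#' @return Character vector, one label per edge.
#' @export
edge_classes <- function(net) {
  .check_categories(net)
  cat <- igraph::V(net)$category
  if (any(cat == "other"))
    warning("nodes with category 'other' are classed as protein-like")
  ends <- igraph::ends(net, igraph::E(net), names = FALSE)
  ca <- cat[ends[, 1]]; cb <- cat[ends[, 2]]
  protein <- c("rprotein", "elongation_factor", "other")
  ifelse(ca %in% c("tRNA", "mRNA") | cb %in% c("tRNA", "mRNA"), "mrna_trna",
    ifelse(ca == "rRNA_domain" & cb == "rRNA_domain", "rrna_rrna",
      ifelse(ca %in% protein & cb %in% protein, "rprot_rprot",
             "rrna_rprot")))
}

#' Count edges by interaction class
#'
#' @param net An igraph from [build_network()].
#' @return Named integer vector (`rrna_rrna`, `rprot_rprot`, `rrna_rprot`,
#'   `mrna_trna`) summing exactly to the edge count.
#' @export
classify_edges <- function(net) {
  cl <- edge_classes(net)
  lv <- c("rrna_rrna", "rprot_rprot", "rrna_rprot", "mrna_trna")
  out <- vapply(lv, function(l) sum(cl == l), 0L)
  stopifnot(sum(out) == igraph::ecount(net))
  out
}

.intersubunit_flags <- function(net) {
  cat <- igraph::V(net)$category
  su <- igraph::V(net)$subunit
  ends <- igraph::ends(net, igraph::E(net), names = FALSE)
  core <- cat %in% c("rprotein", "rRNA_domain")
  core[ends[, 1]] & core[ends[, 2]] &
    ((su[ends[, 1]] == "30S" & su[ends[, 2]] == "50S") |
     (su[ends[, 1]] == "50S" & su[ends[, 2]] == "30S"))
}

#' Count inter-subunit bridge edges
#'
#' Edges with one endpoint in the 30S and the other in the 50S subunit,
#' both endpoints being ribosomal elements (rprotein or rRNA domain);
#' tRNA, mRNA and elongation-factor contacts are not bridges.
#'
#' @param net An igraph from [build_network()].
#' @return Integer count.
#' @export
count_intersubunit <- function(net) {
  .check_categories(net)
  sum(.intersubunit_flags(net))
}

.edge_keys <- function(net) {
  e <- igraph::ends(net, igraph::E(net), names = TRUE)
  paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]), sep = "\t")
}

#' Percent connectivity difference between two networks
#'
#' Counts edge changes between two states/species. Only element pairs whose
#' both endpoints exist in the two networks can contribute changed edges
#' (numerator = size of the symmetric difference of the restricted edge
#' sets), while the denominator is the size of the union of all edges of
#' both networks, so contacts of elements present in only one file inflate
#' the denominator but never the numerator.
#'
#' @param a,b igraphs from [build_network()].
#' @return List with `pct_diff_total`, `pct_diff_by_class`, `shared_nodes`,
#'   `n_changed`, `n_union`.
#' @export
compare_networks <- function(a, b) {
  na <- igraph::V(a)$name; nb <- igraph::V(b)$name
  shared <- intersect(na, nb)
  if (length(shared) < 2L)
    stop("networks share fewer than two nodes; comparison undefined")
  ka <- .edge_keys(a); kb <- .edge_keys(b)
  cla <- igraph::E(a)$class; clb <- igraph::E(b)$class
  in_shared <- function(keys) {
    ends <- do.call(rbind, strsplit(keys, "\t", fixed = TRUE))
    ends[, 1] %in% shared & ends[, 2] %in% shared
  }
  pct <- function(sel_a, sel_b) {
    ra <- ka[sel_a]; rb <- kb[sel_b]
    num <- length(setdiff(ra[in_shared(ra)], rb)) +
           length(setdiff(rb[in_shared(rb)], ra))
    den <- length(union(ra, rb))
    if (den == 0L) return(NA_real_)
    100 * num / den
  }
  classes <- sort(unique(c(cla, clb)))
  by_class <- vapply(classes, function(cl)
    pct(cla == cl, clb == cl), numeric(1))
  list(pct_diff_total = pct(rep(TRUE, length(ka)), rep(TRUE, length(kb))),
       pct_diff_by_class = by_class,
       shared_nodes = shared,
       n_changed = length(setdiff(ka[in_shared(ka)], kb)) +
                   length(setdiff(kb[in_shared(kb)], ka)),
       n_union = length(union(ka, kb)))
}

#' Export / import a network as node and edge TSV tables
#'
#' The edge table has columns `node_a`, `node_b`, `class`, `intersubunit`;
#' the node table `name`, `category`, `subunit` (so degree-0 nodes survive
#' the round trip). `read_network_tsv()` rebuilds the identical graph.
#'
#' @param net igraph from [build_network()].
#' @param prefix Path prefix; writes `<prefix>_nodes.tsv` and
#'   `<prefix>_edges.tsv`.
#' @return The file paths (write) or the rebuilt igraph (read), invisibly.
#' @export
write_network_tsv <- function(net, prefix) {
  nodes <- data.frame(name = igraph::V(net)$name,
                      category = igraph::V(net)$category,
                      subunit = igraph::V(net)$subunit,
                      stringsAsFactors = FALSE)
  e <- igraph::ends(net, igraph::E(net), names = TRUE)
  edges <- data.frame(node_a = e[, 1], node_b = e[, 2],
                      class = igraph::E(net)$class,
                      intersubunit = igraph::E(net)$intersubunit,
                      stringsAsFactors = FALSE)
  paths <- paste0(prefix, c("_nodes.tsv", "_edges.tsv"))
  utils::write.table(nodes, paths[1], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(edges, paths[2], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' @rdname write_network_tsv
#' @param source_id,state Provenance labels for the rebuilt graph.
#' @export
read_network_tsv <- function(prefix, source_id = "", state = "") {
  nodes <- utils::read.table(paste0(prefix, "_nodes.tsv"), header = TRUE,
                             sep = "\t", stringsAsFactors = FALSE)
  edges <- utils::read.table(paste0(prefix, "_edges.tsv"), header = TRUE,
                             sep = "\t", stringsAsFactors = FALSE)
  build_network(nodes,
                data.frame(element_a = edges$node_a,
                           element_b = edges$node_b,
                           stringsAsFactors = FALSE),
                source_id = source_id, state = state)
}

#' Export a network as GraphML
#'
#' @param net igraph object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(net, path) {
  igraph::write_graph(net, path, format = "graphml")
  invisible(path)
}
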