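#' Extract a subnetwork by category or subunit
#'
#' Restricts a network the way the rRNA-free / rprotein-free and per-subunit
#' comparisons are defined: nodes of excluded categories are removed with
#' their incident edges; optionally only edges touching at least one node of
#' a given category are kept; optionally the network is restricted to one
#' subunit. The result may be disconnected; the metric functions handle
#' that component-aware.
#'
#' @param net igraph from [build_network()].
#' @param exclude Character vector of categories to remove (default none).
#' @param require_touch Keep only edges with at least one endpoint of this
#'   category (default NULL: keep all remaining edges).
#' @param subunit Restrict to nodes of this subunit (`"30S"` or `"50S"`;
#'   default NULL).
#' @return igraph object.
#' @export
subnetwork <- function(net, exclude = NULL, require_touch = NULL,
                       subunit = NULL) {
  .check_categories(net)
  keep <- rep(TRUE, igraph::vcount(net))
  if (!is.null(exclude))
    keep <- keep & !(igraph::V(net)$category %in% exclude)
  if (!is.null(subunit))
    keep <- keep & igraph::V(net)$subunit == subunit
  g <- igraph::induced_subgraph(net, which(keep))
  if (!is.null(require_touch)) {
    cat <- igraph::V(g)$category
    ends <- igraph::ends(g, igraph::E(g), names = FALSE)
    drop <- which(!(cat[ends[, 1]] %in% require_touch |
                    cat[ends[, 2]] %in% require_touch))
    if (length(drop)) g <- igraph::delete_edges(g, drop)
  }
  g
}

.stage <- function(name, input_id, expr) {
  tryCatch(expr, error = function(e)
    stop("[stage ", name, " / input ", input_id, "] ",
         conditionMessage(e), call. = FALSE))
}

.default_config <- function() {
  list(sasa = list(probe_radius = 1.4, n_sphere_points = 960,
                   min_buried_area = 0.1),
       null_models = list(reps = 5000, seed = 1),
       modularity = list(min_size = 9),
       hubs = list(k = 15))
}

#' Run the full analysis pipeline from a configuration
#'
#' For every input (a structure file plus element map, or a precomputed
#' interaction/edge table) the pipeline detects interactions, builds the
#' element network and writes: the interaction table, the descriptive
#' summary (side-by-side for all inputs), the observed/random/regular
#' null-model comparison, per-node centralities with top-k hub lists, the
#' recursive community decomposition, and a GraphML export. With two or
#' more inputs a pairwise percent-connectivity-difference table is added.
#' A log (stage timings, seeds, parameters) and the resolved configuration
#' are written beside the outputs, so a rerun with the same configuration
#' and seed is byte-identical.
#'
#' @param config A list, or path to a YAML file, with fields `inputs` (list
#'   of entries with `id` and either `structure` + `element_map` paths or
#'   `interactions` path + `element_map`), optional `sasa`
#'   (`probe_radius`, `n_sphere_points`, `min_buried_area`), `null_models`
#'   (`reps`, `seed`), `modularity` (`min_size`), `hubs` (`k`) and
#'   `out_dir`.
#' @param out_dir Output directory (overrides the config key).
#' @return Invisibly, a named list per input with the network, summary,
#'   small-world stats, centrality table and community tree.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  def <- .default_config()
  for (key in names(def))
    config[[key]] <- utils::modifyList(def[[key]],
                                       config[[key]] %||% list())
  if (!is.null(out_dir)) config$out_dir <- out_dir
  if (is.null(config$out_dir)) stop("config lacks 'out_dir'")
  if (length(config$inputs) == 0L) stop("config lists no inputs")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  logf <- function(...) {
    writeLines(paste0(format(Sys.time(), "%H:%M:%S "), sprintf(...)),
               log_con)
  }
  logf("pipeline start: %d input(s), null-model seed %s",
       length(config$inputs), config$null_models$seed)

  results <- list()
  for (inp in config$inputs) {
    id <- inp$id %||% stop("every input needs an 'id'")
    odir <- file.path(config$out_dir, id)
    dir.create(odir, showWarnings = FALSE)
    emap <- .stage("element_map", id, read_element_map(inp$element_map))
    if (!is.null(inp$structure)) {
      model <- .stage("parse", id, parse_structure(inp$structure))
      elements <- .stage("assign", id, assign_elements(model, emap))
      calls <- .stage("detect", id, detect_interactions(
        elements,
        probe_radius = config$sasa$probe_radius,
        n_sphere_points = config$sasa$n_sphere_points,
        min_buried_area = config$sasa$min_buried_area))
      write_interactions(calls, file.path(odir, "interactions.tsv"))
      net <- .stage("network", id,
                    build_network(elements, calls, source_id = id))
    } else if (!is.null(inp$interactions)) {
      calls <- .stage("read_interactions", id,
                      read_interactions(inp$interactions))
      nodes <- data.frame(
        name = vapply(emap$entries, `[[`, "", "name"),
        category = vapply(emap$entries, `[[`, "", "category"),
        subunit = vapply(emap$entries, `[[`, "", "subunit"),
        stringsAsFactors = FALSE)
      net <- .stage("network", id,
                    build_network(nodes, calls, source_id = id))
    } else {
      stop("input '", id, "' has neither 'structure' nor 'interactions'")
    }
    logf("input %s: %d nodes, %d edges", id, igraph::vcount(net),
         igraph::ecount(net))

    summ <- .stage("summary", id, summarize_network(net))
    sw <- .stage("null_models", id, small_world_stats(
      net, reps = config$null_models$reps,
      seed = config$null_models$seed))
    utils::write.table(null_model_table(net, sw),
                       file.path(odir, "null_models.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    cent <- .stage("centrality", id, centrality_table(net))
    utils::write.table(cent, file.path(odir, "centrality.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(rank_hubs(cent, k = config$hubs$k),
                       file.path(odir, "top_hubs.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    tree <- .stage("modularity", id, recursive_decomposition(
      net, min_size = config$modularity$min_size))
    utils::write.table(community_labels(tree),
                       file.path(odir, "communities.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_network_graphml(net, file.path(odir, "network.graphml"))
    write_network_tsv(net, file.path(odir, "network"))
    results[[id]] <- list(network = net, summary = summ,
                          small_world = sw, centrality = cent,
                          community_tree = tree)
  }

  utils::write.table(
    summary_table(lapply(results, `[[`, "summary")),
    file.path(config$out_dir, "summary.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)

  if (length(results) >= 2L) {
    ids <- names(results)
    rows <- list()
    for (i in seq_along(ids)[-length(ids)]) for (j in seq(i + 1,
                                                          length(ids))) {
      cmp <- .stage("compare", paste(ids[i], ids[j]),
                    compare_networks(results[[ids[i]]]$network,
                                     results[[ids[j]]]$network))
      rows[[length(rows) + 1L]] <- data.frame(
        a = ids[i], b = ids[j], pct_diff = cmp$pct_diff_total,
        n_changed = cmp$n_changed, n_union = cmp$n_union)
    }
    utils::write.table(do.call(rbind, rows),
                       file.path(config$out_dir, "comparisons.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  yaml::write_yaml(config, file.path(config$out_dir,
                                     "resolved_config.yaml"))
  logf("pipeline done")
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
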