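test_that("positive calls become edges and all elements become nodes", {
  net <- make_labelled_net(
    cbind(c("a", "b"), c("b", "c")),
    categories = c(a = "rprotein", b = "rprotein", c = "rprotein",
                   d = "rprotein"),
    subunits = c(a = "50S", b = "50S", c = "50S", d = "50S"))
  expect_equal(igraph::vcount(net), 4L)  # degree-0 node kept
  expect_equal(igraph::ecount(net), 2L)
  expect_equal(sort(igraph::degree(net)), c(0, 1, 1, 2),
               ignore_attr = TRUE)
})

test_that("calls that reference unknown elements are rejected", {
  nodes <- data.frame(name = c("a", "b"), category = "rprotein",
                      subunit = "50S")
  expect_error(build_network(nodes, data.frame(element_a = "a",
                                               element_b = "zz")),
               "unknown element")
})

test_that("a planted toy adjacency is reconstructed isomorphically", {
  toy <- generate_toy_structure(toy_elements(),
                                cbind(c("E1", "E2", "E2"),
                                      c("E2", "E3", "E4")), seed = 17)
  elements <- assign_elements(toy$model, toy$element_map)
  net <- build_network(elements, detect_interactions(elements))
  ref <- igraph::graph_from_data_frame(toy$adjacency, directed = FALSE,
                                       vertices = toy_elements()["name"])
  expect_true(igraph::isomorphic(net, ref))
  got <- apply(igraph::ends(net, igraph::E(net)), 1,
               function(e) paste(sort(e), collapse = "-"))
  want <- paste(toy$adjacency$a, toy$adjacency$b, sep = "-")
  expect_setequal(got, want)
})

test_that("edge classes follow the tRNA/mRNA-first precedence", {
  cats <- c("23S-D2" = "rRNA_domain", "16S-3m" = "rRNA_domain",
            "L4" = "rprotein", "L2" = "rprotein",
            "EF-G" = "elongation_factor", "tRNA-A" = "tRNA",
            "mRNA" = "mRNA")
  subs <- c("23S-D2" = "50S", "16S-3m" = "30S", "L4" = "50S",
            "L2" = "50S", "EF-G" = "none", "tRNA-A" = "none",
            "mRNA" = "none")
  edges <- cbind(
    c("23S-D2", "23S-D2", "L4", "tRNA-A", "EF-G", "EF-G", "mRNA"),
    c("L4", "16S-3m", "L2", "16S-3m", "tRNA-A", "L2", "tRNA-A"))
  net <- make_labelled_net(edges, cats, subs)
  cl <- igraph::E(net)$class
  ends <- igraph::ends(net, igraph::E(net))
  key <- apply(ends, 1, function(e) paste(sort(e), collapse = "+"))
  got <- stats::setNames(cl, key)
  expect_equal(got[["23S-D2+L4"]], "rrna_rprot")
  expect_equal(got[["16S-3m+23S-D2"]], "rrna_rrna")
  expect_equal(got[["L2+L4"]], "rprot_rprot")
  # tRNA/mRNA involvement wins even over two RNA endpoints
  expect_equal(got[["16S-3m+tRNA-A"]], "mrna_trna")
  expect_equal(got[["EF-G+tRNA-A"]], "mrna_trna")
  expect_equal(got[["mRNA+tRNA-A"]], "mrna_trna")
  # elongation factors count as proteins
  expect_equal(got[["EF-G+L2"]], "rprot_rprot")
  counts <- classify_edges(net)
  expect_equal(unname(counts), c(1L, 2L, 1L, 3L))
  expect_equal(sum(counts), igraph::ecount(net))
})

test_that("class counts always partition the edge set", {
  cats_pool <- c("rRNA_domain", "rprotein", "tRNA", "mRNA",
                 "elongation_factor")
  for (seed in 1:5) {
    set.seed(seed)
    g <- igraph::sample_gnp(12, 0.4)
    igraph::V(g)$name <- paste0("n", 1:12)
    igraph::V(g)$category <- sample(cats_pool, 12, replace = TRUE)
    igraph::V(g)$subunit <- sample(c("30S", "50S", "none"), 12,
                                   replace = TRUE)
    expect_equal(sum(classify_edges(g)), igraph::ecount(g))
  }
})

test_that("inter-subunit counting sees only ribosomal 30S-50S bridges", {
  cats <- c(A = "rRNA_domain", B = "rprotein", C = "rprotein",
            D = "rprotein", TA = "tRNA")
  # planted: 2 cross-subunit ribosomal edges; tRNA bridge does not count
  subs <- c(A = "50S", B = "50S", C = "30S", D = "30S", TA = "none")
  net <- make_labelled_net(
    cbind(c("A", "A", "B", "C", "TA"), c("B", "C", "D", "D", "C")),
    cats, subs)
  # by hand: A(50S)-C(30S) and B(50S)-D(30S) cross; C-D is within 30S
  # and the tRNA contact is not a bridge
  expect_equal(count_intersubunit(net), 2L)
})

test_that("inter-subunit count is zero when one subunit is absent", {
  net <- make_labelled_net(cbind("a", "b"),
                           c(a = "rprotein", b = "rRNA_domain"),
                           c(a = "50S", b = "50S"))
  expect_equal(count_intersubunit(net), 0L)
})

test_that("identical networks differ by zero percent", {
  toyn <- generate_ribosome_like_network(seed = 5)
  cmp <- compare_networks(toyn, toyn)
  expect_equal(cmp$pct_diff_total, 0)
})

test_that("percent difference uses shared-pair numerator, union denominator", {
  cats <- c(x = "rprotein", y = "rprotein", z = "rprotein")
  subs <- c(x = "50S", y = "50S", z = "50S")
  a <- make_labelled_net(cbind("x", "y"), cats, subs)
  b <- make_labelled_net(cbind("x", "z"), cats, subs)
  cmp <- compare_networks(a, b)
  expect_equal(cmp$n_changed, 2L)
  expect_equal(cmp$n_union, 2L)
  expect_equal(cmp$pct_diff_total, 100)
})

test_that("edges of nodes absent from one network only inflate the denominator", {
  # w exists only in network a; its edge may not count as a change
  cats_a <- c(x = "rprotein", y = "rprotein", w = "rprotein")
  cats_b <- c(x = "rprotein", y = "rprotein")
  a <- make_labelled_net(cbind(c("x", "x"), c("y", "w")), cats_a,
                         stats::setNames(rep("50S", 3), names(cats_a)))
  b <- make_labelled_net(cbind("x", "y"), cats_b,
                         stats::setNames(rep("50S", 2), names(cats_b)))
  cmp <- compare_networks(a, b)
  expect_equal(cmp$n_changed, 0L)
  expect_equal(cmp$n_union, 2L)
  expect_equal(cmp$pct_diff_total, 0)
})

test_that("percent difference matches brute-force set arithmetic", {
  for (seed in 1:4) {
    set.seed(seed)
    nodes <- data.frame(name = paste0("n", 1:30),
                        category = "rprotein", subunit = "50S")
    mk <- function() {
      e <- t(utils::combn(30, 2))
      e <- e[stats::runif(nrow(e)) < 0.1, , drop = FALSE]
      build_network(nodes, data.frame(element_a = paste0("n", e[, 1]),
                                      element_b = paste0("n", e[, 2])))
    }
    a <- mk(); b <- mk()
    key <- function(net) apply(igraph::ends(net, igraph::E(net)), 1,
                               function(x) paste(sort(x), collapse = "|"))
    ka <- key(a); kb <- key(b)
    want <- 100 * (length(setdiff(ka, kb)) + length(setdiff(kb, ka))) /
      length(union(ka, kb))
    cmp <- compare_networks(a, b)
    expect_equal(cmp$pct_diff_total, want)
    expect_equal(compare_networks(b, a)$pct_diff_total, want)
  }
})

test_that("disjoint node sets make comparison an error", {
  a <- make_labelled_net(cbind("x", "y"),
                         c(x = "rprotein", y = "rprotein"),
                         c(x = "50S", y = "50S"))
  b <- make_labelled_net(cbind("u", "v"),
                         c(u = "rprotein", v = "rprotein"),
                         c(u = "50S", v = "50S"))
  expect_error(compare_networks(a, b), "share")
})

test_that("TSV and GraphML exports round-trip the graph", {
  net <- generate_ribosome_like_network(seed = 9)
  pre <- tempfile()
  write_network_tsv(net, pre)
  back <- read_network_tsv(pre)
  expect_equal(igraph::vcount(back), igraph::vcount(net))
  expect_equal(igraph::ecount(back), igraph::ecount(net))
  key <- function(g) sort(apply(igraph::ends(g, igraph::E(g)), 1,
                                function(x) paste(sort(x), collapse = "|")))
  expect_equal(key(back), key(net))
  expect_equal(
    stats::setNames(igraph::V(back)$category, igraph::V(back)$name),
    stats::setNames(igraph::V(net)$category, igraph::V(net)$name)[
      igraph::V(back)$name])
  gml <- tempfile(fileext = ".graphml")
  write_network_graphml(net, gml)
  gback <- igraph::read_graph(gml, format = "graphml")
  expect_equal(key(gback), key(net))
})
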