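edge_file <- function(lines) {
  tf <- tempfile(fileext = ".tsv")
  writeLines(lines, tf)
  tf
}

test_that("edge-list loading deduplicates, drops self-loops, and is undirected", {
  tf <- edge_file(c("A\tB", "B\tA", "A\tA", "A\tC"))
  g <- suppressMessages(load_edge_list(tf))
  expect_equal(igraph::ecount(g), 2)
  expect_equal(igraph::vcount(g), 3)
  expect_true(igraph::are_adjacent(g, "A", "B"))
  expect_true(igraph::are_adjacent(g, "A", "C"))

  empty <- edge_file(character(0))
  expect_equal(igraph::vcount(suppressMessages(load_edge_list(empty))), 0)

  bad <- edge_file(c("A\tB", "A\tB\tC"))
  expect_error(suppressMessages(load_edge_list(bad)), "line 2")
})

test_that("random edge lists reduce to the set-based unique pair count", {
  set.seed(11)
  for (rep in 1:10) {
    a <- sample(LETTERS[1:8], 12, replace = TRUE)
    b <- sample(LETTERS[1:8], 12, replace = TRUE)
    tf <- edge_file(paste(a, b, sep = "\t"))
    g <- suppressMessages(load_edge_list(tf))
    keep <- a != b
    expected <- length(unique(paste(pmin(a[keep], b[keep]),
                                    pmax(a[keep], b[keep]))))
    expect_equal(igraph::ecount(g), expected)
    # handshake lemma
    expect_equal(sum(igraph::degree(g)), 2 * igraph::ecount(g))
  }
})

test_that("giant component picks the largest component and is idempotent", {
  tf <- edge_file(c("A\tB", "B\tC", "C\tD", "D\tE", "X\tY", "Y\tZ"))
  g <- suppressMessages(load_edge_list(tf))
  gc <- giant_component(g)
  expect_setequal(igraph::V(gc)$name, c("A", "B", "C", "D", "E"))
  gc2 <- giant_component(gc)
  expect_equal(sort(igraph::V(gc2)$name), sort(igraph::V(gc)$name))
  # a connected graph is returned whole
  ring <- igraph::make_ring(6)
  igraph::V(ring)$name <- letters[1:6]
  expect_equal(igraph::vcount(giant_component(ring)), 6)
  # equal-size ties resolve to the component with the smallest member name
  tf2 <- edge_file(c("M\tN", "A\tZ"))
  tie <- giant_component(suppressMessages(load_edge_list(tf2)))
  expect_setequal(igraph::V(tie)$name, c("A", "Z"))
})

test_that("giant component agrees with a BFS component oracle", {
  set.seed(23)
  for (rep in 1:8) {
    g <- random_named_gnp(50, 0.03)
    adj <- adj_matrix(g)
    comp <- brute_components(adj)
    biggest <- which(tabulate(comp) == max(tabulate(comp)))
    expected_sizes <- max(tabulate(comp))
    gc <- giant_component(g)
    expect_equal(igraph::vcount(gc), expected_sizes)
    # the extracted node set is one of the maximal components
    sets <- lapply(biggest, function(ci) rownames(adj)[comp == ci])
    expect_true(any(vapply(sets, function(s) {
      setequal(s, igraph::V(gc)$name)
    }, logical(1))))
  }
})

test_that("node metrics on canonical small graphs", {
  tri <- suppressMessages(load_edge_list(edge_file(c("A\tB", "B\tC", "A\tC"))))
  m <- node_metrics(tri, "A")
  expect_equal(m$degree, 2)
  expect_equal(m$clustering_coefficient, 1)
  expect_equal(m$avg_neighbor_degree, 2)
  expect_equal(m$closeness, 1)

  star <- suppressMessages(
    load_edge_list(edge_file(c("C\tL1", "C\tL2", "C\tL3"))))
  center <- node_metrics(star, "C")
  expect_equal(center$degree, 3)
  expect_equal(center$clustering_coefficient, 0)
  expect_equal(center$avg_neighbor_degree, 1)
  leaf <- node_metrics(star, "L1")
  expect_equal(leaf$avg_neighbor_degree, 3)

  expect_error(node_metrics(star, "missing"), "absent")
})

test_that("K1 equals k on k-regular graphs", {
  ring <- igraph::make_ring(8)
  igraph::V(ring)$name <- letters[1:8]
  expect_equal(node_metrics(ring)$avg_neighbor_degree, rep(2, 8))
  full <- igraph::make_full_graph(5)
  igraph::V(full)$name <- letters[1:5]
  expect_equal(node_metrics(full)$avg_neighbor_degree, rep(4, 5))
})

test_that("set statistics compose per-node metrics and drop absent genes", {
  tri <- suppressMessages(load_edge_list(edge_file(c("A\tB", "B\tC", "A\tC"))))
  s <- set_statistic(tri, c("A", "B", "C"), metric = "cc")
  expect_equal(s$value, 1)
  s1 <- set_statistic(tri, "A", metric = "degree")
  expect_equal(s1$value, 2)
  expect_warning(set_statistic(tri, c("A", "NOPE"), metric = "degree"),
                 "dropped")
  expect_error(suppressWarnings(set_statistic(tri, "NOPE", "degree")),
               "none")
  # composition against node_metrics on a random graph
  g <- random_named_gnp(30, 0.12, seed = 5)
  genes <- sample(igraph::V(g)$name, 8)
  for (metric in c("degree", "cc", "k1", "closeness")) {
    col <- c(degree = "degree", cc = "clustering_coefficient",
             k1 = "avg_neighbor_degree", closeness = "closeness")[[metric]]
    expect_equal(set_statistic(g, genes, metric)$value,
                 mean(node_metrics(g, genes)[[col]]))
    expect_equal(set_statistic(g, genes, metric, "median")$value,
                 median(node_metrics(g, genes)[[col]]))
  }
})

test_that("induced subnetworks keep exactly the internal edges", {
  path <- suppressMessages(load_edge_list(edge_file(c("A\tB", "B\tC"))))
  sub <- subnetwork(path, c("A", "C"))
  expect_equal(igraph::vcount(sub), 2)
  expect_equal(igraph::ecount(sub), 0)
  all_sub <- subnetwork(path, c("A", "B", "C"))
  expect_equal(igraph::ecount(all_sub), 2)
  none <- subnetwork(path, c("X", "Y"))
  expect_equal(igraph::vcount(none), 0)
})

test_that("subnetwork export writes Cytoscape-importable node and edge tables", {
  g <- random_named_gnp(10, 0.4, seed = 2)
  attrs <- data.frame(node = igraph::V(g)$name[1:5],
                      mutated = c("pre", "post", "both", "post", "pre"))
  sub <- subnetwork(g, igraph::V(g)$name[1:5], node_attrs = attrs)
  prefix <- file.path(tempdir(), "subnet_test")
  paths <- export_subnetwork(sub, prefix)
  edges <- read.delim(paths[["edges"]])
  nodes <- read.delim(paths[["nodes"]])
  expect_equal(nrow(edges), igraph::ecount(sub))
  expect_equal(nrow(nodes), 5)
  expect_true("mutated" %in% names(nodes))
})

test_that("group metric comparison separates leaves from hubs", {
  # a star of degree-1 leaves plus a 6-clique of degree-5 nodes
  clique_edges <- apply(combn(paste0("b", 1:6), 2), 2, paste, collapse = "\t")
  lines <- c(paste0("H1\t", paste0("a", 1:6)), clique_edges)
  g <- suppressMessages(load_edge_list(edge_file(lines)))
  same <- compare_group_metrics(g, c("a1", "a2"), c("a1", "a2"), "degree")
  expect_equal(same$p_value, 1)
  res <- compare_group_metrics(g, paste0("a", 1:6), paste0("b", 1:6),
                               "degree")
  expect_gt(res$mean_new, res$mean_old)
  expect_lt(res$p_value, 0.05)
  expect_error(suppressWarnings(
    compare_group_metrics(g, "nope", c("H1", "H2"), "degree")), "no members")
})
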