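test_that("generators are fully determined by the seed", {
  cfg <- sim_config(seed = 42, n_nodes = 200, mean_degree = 6)
  g1 <- suppressMessages(generate_ppi(cfg))
  g2 <- suppressMessages(generate_ppi(cfg))
  expect_identical(igraph::as_edgelist(g1), igraph::as_edgelist(g2))

  m1 <- generate_mutation_tables(cfg)
  m2 <- generate_mutation_tables(cfg)
  expect_identical(as.data.frame(m1$post), as.data.frame(m2$post))

  bg <- sprintf("B%03d", 1:200)
  q <- bg[1:20]
  a1 <- generate_annotations(cfg, bg, q)
  a2 <- generate_annotations(cfg, bg, q)
  expect_identical(a1$term_to_genes, a2$term_to_genes)

  gr1 <- suppressMessages(generate_growth_curves(cfg))
  gr2 <- suppressMessages(generate_growth_curves(cfg))
  expect_identical(gr1$volume_mm3, gr2$volume_mm3)
})

test_that("generated networks are simple, connected, and near the target density", {
  cfg <- sim_config(seed = 7)
  g <- suppressMessages(generate_ppi(cfg))
  expect_true(igraph::is_simple(g))
  expect_true(igraph::is_connected(g))
  expect_equal(sum(igraph::degree(g)), 2 * igraph::ecount(g))
  target <- cfg$n_nodes * cfg$mean_degree / 2
  expect_lt(abs(igraph::ecount(g) - target) / target, 0.15)
})

test_that("planted modules have the promised structure", {
  cfg <- sim_config(seed = 19, n_nodes = 400, mean_degree = 7)
  g <- suppressMessages(generate_ppi(cfg))
  mean_deg <- mean(igraph::degree(g))

  hub <- plant_module(g, 15, mode = "hub")
  expect_identical(hub$graph, g)
  expect_gt(set_statistic(g, hub$genes, "degree")$value, mean_deg)

  cl <- plant_module(g, 15, mode = "clustered", cc_margin = 0.2, seed = 4)
  mean_cc <- mean(node_metrics(cl$graph)$clustering_coefficient)
  expect_gt(set_statistic(cl$graph, cl$genes, "cc")$value, mean_cc + 0.15)
  expect_gte(igraph::ecount(cl$graph), igraph::ecount(g))

  rnd <- plant_module(g, 15, mode = "random", seed = 8)
  expect_true(all(rnd$genes %in% igraph::V(g)$name))
  expect_error(plant_module(g, igraph::vcount(g) + 1, mode = "hub"),
               "size")
})

test_that("generated catalogs encode VAFs exactly as read-count ratios", {
  sim <- generate_mutation_tables(sim_config(seed = 2))
  all_rec <- rbind(as.data.frame(sim$pre), as.data.frame(sim$post))
  expect_equal(all_rec$vaf, all_rec$mutant_reads / all_rec$coverage)
  expect_true(all(all_rec$mutant_reads <= all_rec$coverage))
  expect_true(all(all_rec$coverage >= 80 & all_rec$coverage <= 650))
  expect_equal(nrow(sim$pre), 9)
  expect_equal(nrow(sim$post), 62)
})

test_that("the subclonal VAF model reproduces a low new-mutation median", {
  medians <- vapply(1:500, function(s) {
    cfg <- sim_config(seed = 1000 + s)
    set.seed(cfg$seed)
    vaf <- rbeta(cfg$n_new, cfg$new_vaf_shape[1], cfg$new_vaf_shape[2])
    cov <- sample(seq(cfg$depth_range[1], cfg$depth_range[2]), cfg$n_new,
                  replace = TRUE)
    median(round(rbinom(cfg$n_new, cov, vaf) / cov, 2))
  }, numeric(1))
  expect_gte(median(medians), 0.04)
  expect_lte(median(medians), 0.09)
  expect_gt(mean(medians >= 0.04 & medians <= 0.09), 0.9)
})

test_that("persisting vs new VAFs separate at the study's sample sizes", {
  hits <- vapply(1:200, function(s) {
    sim <- generate_mutation_tables(sim_config(seed = 2000 + s))
    cmp <- classify_mutations(sim$pre, sim$post)
    summary <- cohort_vaf_summary(cmp, sim$post)
    summary$test$p_value < 0.01
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("annotation planting is feasible only when the overlap fits", {
  cfg <- sim_config(seed = 3, planted_overlap = 8)
  bg <- sprintf("B%03d", 1:300)
  expect_error(generate_annotations(cfg, bg, bg[1:5]), "overlap")
  ann <- generate_annotations(cfg, bg, bg[1:20])
  expect_equal(length(intersect(ann$term_to_genes$PLANTED, bg[1:20])), 8)
  expect_equal(length(ann$term_to_genes$PLANTED), cfg$planted_term_size)
  expect_equal(length(ann$term_to_genes), cfg$n_terms + 1)
  # zero planted overlap -> the planted term is not significant
  cfg0 <- sim_config(seed = 4, planted_overlap = 0)
  ann0 <- generate_annotations(cfg0, bg, bg[1:20])
  res0 <- enrich(bg[1:20], ann0, bg, alpha = 1.0)
  expect_false("PLANTED" %in% res0$term[res0$p_corrected < 0.05])
})

test_that("growth generator recovers the anchor treatment effects", {
  # no effect: TGI centred at 0; full arrest: centred at 100
  tgis <- vapply(1:30, function(s) {
    growth <- suppressMessages(generate_growth_curves(
      sim_config(seed = 3000 + s),
      groups = c(vehicle = 1, none = 1, arrest = 0)))
    tab <- tgi_table(growth, control = "vehicle")
    c(tab$tgi_percent[tab$group == "none"],
      tab$tgi_percent[tab$group == "arrest"])
  }, numeric(2))
  expect_lt(abs(mean(tgis[1, ])), 10)
  expect_lt(abs(mean(tgis[2, ]) - 100), 10)
  # volumes round-trip through the caliper axes exactly
  growth <- suppressMessages(generate_growth_curves(sim_config(seed = 5)))
  expect_equal(growth$volume_mm3,
               growth$length_mm * growth$width_mm^2 / 2, tolerance = 1e-12)
})
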