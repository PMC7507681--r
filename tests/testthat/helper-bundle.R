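write_synthetic_bundle <- function(dir, seed = 11) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- sim_config(seed = seed, n_nodes = 300, mean_degree = 6)
  g <- suppressMessages(generate_ppi(cfg))
  sim <- generate_mutation_tables(cfg, genes = igraph::V(g)$name)

  mut_path <- file.path(dir, "mutations.tsv")
  write.table(rbind(as.data.frame(sim$pre), as.data.frame(sim$post)),
              mut_path, sep = "\t", quote = FALSE, row.names = FALSE)
  edge_path <- file.path(dir, "edges.tsv")
  write.table(igraph::as_edgelist(g), edge_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  ann <- generate_annotations(cfg, igraph::V(g)$name,
                              unique(sim$truth$gene))
  ann_path <- file.path(dir, "annotations.tsv")
  pairs <- do.call(rbind, lapply(names(ann$term_to_genes), function(t) {
    data.frame(gene = ann$term_to_genes[[t]], term = t)
  }))
  write.table(pairs, ann_path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  rp_path <- file.path(dir, "read_pairs.tsv")
  write.table(data.frame(chrom = "chr4",
                         pos1 = c(1000, 1300, 1450, 9000, 9100, 50000),
                         pos2 = c(1100, 1400, 1550, 9100, 9200, 50100),
                         insert_size = c(2500, 3000, 0, 2200, 2600, 300)),
              rp_path, sep = "\t", quote = FALSE, row.names = FALSE)
  growth_path <- file.path(dir, "growth.tsv")
  growth <- suppressMessages(generate_growth_curves(
    cfg, groups = c(vehicle = 1, cisplatin = 0.2, pazopanib = 0.95)))
  write.table(as.data.frame(growth)[, c("group", "animal", "day",
                                        "length_mm", "width_mm",
                                        "body_weight_g")],
              growth_path, sep = "\t", quote = FALSE, row.names = FALSE)
  list(mutation_table = mut_path, edge_list = edge_path,
       annotations = ann_path, read_pairs = rp_path,
       growth_table = growth_path, sim = sim, graph = g)
}
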