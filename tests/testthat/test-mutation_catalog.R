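test_that("the packaged case fixture parses with the expected structure", {
  cat1 <- parse_mutation_table(fixture_path())
  expect_s3_class(cat1, "mutation_catalog")
  expect_setequal(attr(cat1, "assay_ids"), c("Panel1", "WES1", "WES2"))
  expect_equal(nrow(assay_slice(cat1, "WES1")), 12)
  expect_equal(unname(count_mutations_genes(cat1, "Panel1")), c(12, 12))
})

test_that("parsing rejects malformed and invalid tables", {
  header <- "gene\tcdna_change\taa_change\tassay_id\tmutant_reads\tcoverage\tvaf\tsignificance_class"

  tf <- withr::local_tempfile(lines = header)
  expect_equal(nrow(parse_mutation_table(tf)), 0)

  tf <- withr::local_tempfile(
    lines = c(header, "TP53\tc.1A>G\tX1Y\tWES1\t50\t40\t1.25\tunknown"))
  expect_error(parse_mutation_table(tf), "mutant_reads")

  tf <- withr::local_tempfile(
    lines = c(header,
              "TP53\tc.1A>G\tX1Y\tWES1\t5\t100\t0.05\tunknown",
              "TP53\tc.1A>G\tX1Y\tWES1\t6\t100\t0.06\tunknown"))
  expect_error(parse_mutation_table(tf), "duplicate")

  tf <- withr::local_tempfile(lines = c(header, "TP53\tc.1A>G"))
  expect_error(parse_mutation_table(tf), "line 2")

  tf <- withr::local_tempfile(
    lines = c(header, "TP53\tc.1A>G\tX1Y\tWES1\t5\t100\t0.50\tunknown"))
  expect_error(parse_mutation_table(tf), "tolerance")
})

test_that("compute_vaf matches read-count arithmetic and rejects bad input", {
  expect_equal(round(compute_vaf(137, 143), 2), 0.96)
  expect_equal(round(compute_vaf(260, 267), 2), 0.97)
  expect_equal(compute_vaf(0, 100), 0)
  expect_error(compute_vaf(1, 0), "positive")
  expect_error(compute_vaf(5, 4), "mutant_reads")
})

make_slice <- function(assay, gene, cdna, aa = NA_character_) {
  mutation_catalog(data.frame(
    gene = gene, cdna_change = cdna, aa_change = aa, assay_id = assay,
    mutant_reads = 10, coverage = 100, vaf = 0.1,
    significance_class = "unknown", stringsAsFactors = FALSE),
    assay_ids = assay)
}

test_that("classification matches on cDNA, rescues on amino acid, and partitions", {
  pre <- make_slice("A", c("TCF7L2", "ATM", "TERT"),
                    c("c.670G>A", "c.2395G>A", "c.1520A>T"),
                    c("V224I", "A799T", "E507V"))
  post <- make_slice("B", c("TCF7L2", "ARID1A", "TERT"),
                     c("c.670G>A", "c.352A>C", "c.2105C>T"),
                     c("S467A", "T118P", "E507V"))
  cmp <- classify_mutations(pre, post)
  expect_equal(sort(cmp$persisting$gene), c("TCF7L2", "TERT"))
  expect_equal(cmp$persisting$matched_on[cmp$persisting$gene == "TCF7L2"],
               "cdna")
  expect_equal(cmp$persisting$matched_on[cmp$persisting$gene == "TERT"], "aa")
  expect_equal(cmp$lost$gene, "ATM")
  expect_equal(cmp$new$gene, "ARID1A")
  # partitions
  expect_equal(nrow(cmp$persisting) + nrow(cmp$lost), nrow(pre))
  expect_equal(nrow(cmp$persisting) + nrow(cmp$new), nrow(post))
})

test_that("empty timepoints give empty persisting sets without error", {
  empty <- mutation_catalog(
    data.frame(gene = character(0), cdna_change = character(0),
               assay_id = character(0), stringsAsFactors = FALSE),
    assay_ids = "A")
  post <- make_slice("B", "TP53", "c.1A>G")
  cmp <- classify_mutations(empty, post)
  expect_equal(nrow(cmp$persisting), 0)
  expect_equal(nrow(cmp$new), 1)
})

test_that("summarize_vaf median agrees with a sort-based oracle", {
  set.seed(41)
  for (rep in 1:20) {
    n <- sample(1:30, 1)
    cov <- sample(50:500, n, replace = TRUE)
    reads <- rbinom(n, cov, runif(n, 0.01, 0.9))
    slice <- mutation_catalog(data.frame(
      gene = sprintf("G%02d", seq_len(n)),
      cdna_change = sprintf("c.%dA>G", seq_len(n)), aa_change = NA,
      assay_id = "X", mutant_reads = reads, coverage = cov,
      vaf = reads / cov, significance_class = "unknown",
      stringsAsFactors = FALSE), assay_ids = "X")
    keys <- data.frame(gene = slice$gene, cdna_change = slice$cdna_change)
    s <- summarize_vaf(keys, slice, threshold = 0.10)
    vafs <- sort(round(reads / cov, 2))
    med <- if (n %% 2 == 1) vafs[(n + 1) / 2] else
      (vafs[n / 2] + vafs[n / 2 + 1]) / 2
    expect_equal(s$median_vaf, med)
    expect_equal(s$n_above, sum(vafs >= 0.10))
    expect_equal(s$fraction_above, s$n_above / n)
  }
})

test_that("summarize_vaf handles singleton and empty key sets", {
  slice <- make_slice("X", "TP53", "c.1A>G")
  s1 <- summarize_vaf(data.frame(gene = "TP53", cdna_change = "c.1A>G"),
                      slice, threshold = 0.10)
  expect_equal(s1$median_vaf, 0.10)
  expect_equal(s1$fraction_above, 1)
  s0 <- summarize_vaf(data.frame(gene = character(0),
                                 cdna_change = character(0)), slice)
  expect_equal(s0$n, 0)
  expect_true(is.na(s0$median_vaf))
  expect_error(
    summarize_vaf(data.frame(gene = "KRAS", cdna_change = "c.2A>T"), slice),
    "absent")
})

test_that("VAF comparison test behaves at the extremes and matches exact enumeration", {
  same <- compare_vaf_distributions(c(0.1, 0.2, 0.3), c(0.1, 0.2, 0.3))
  expect_equal(same$p_value, 1)
  sep <- compare_vaf_distributions(c(0.9, 0.9, 0.9), c(0.01, 0.01, 0.01))
  expect_lt(sep$p_value, 0.11) # smallest attainable two-sided p at 3 vs 3 is 0.1
  expect_error(compare_vaf_distributions(numeric(0), 1), "non-empty")

  set.seed(7)
  for (rep in 1:15) {
    n_a <- sample(2:5, 1)
    n_b <- sample(2:5, 1)
    vals <- sample(seq(0.01, 0.99, by = 0.01), n_a + n_b) # tie-free
    a <- vals[seq_len(n_a)]
    b <- vals[-seq_len(n_a)]
    expect_equal(compare_vaf_distributions(a, b)$p_value,
                 brute_rank_p(a, b), tolerance = 1e-12)
  }
})

test_that("classification on generated catalogs recovers the planted truth", {
  for (seed in c(3, 17, 99)) {
    sim <- generate_mutation_tables(sim_config(seed = seed))
    cmp <- classify_mutations(sim$pre, sim$post)
    expect_equal(nrow(cmp$persisting) + nrow(cmp$new), nrow(sim$post))
    expect_equal(nrow(cmp$persisting) + nrow(cmp$lost), nrow(sim$pre))
    truth_pers <- sim$truth[sim$truth$class == "persisting", ]
    expect_setequal(cmp$persisting$gene, truth_pers$gene)
    expect_setequal(cmp$new$gene, sim$truth$gene[sim$truth$class == "new"])
    expect_equal(nrow(cmp$lost), 0)
  }
})
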