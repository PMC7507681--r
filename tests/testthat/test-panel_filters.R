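candidates <- function(reads, cov) {
  data.frame(gene = sprintf("G%d", seq_along(reads)), mutant_reads = reads,
             coverage = cov, vaf = reads / cov, stringsAsFactors = FALSE)
}

test_that("somatic candidate filter applies inclusive read and VAF floors", {
  cand <- candidates(c(5, 4, 50, 100), c(500, 8, 10000, 400))
  kept <- suppressMessages(filter_somatic_candidates(cand))
  # 5 reads at exactly 1% VAF kept; 4 reads rejected; VAF 0.005 rejected
  expect_equal(kept$gene, c("G1", "G4"))
  rejected <- attr(kept, "rejected")
  expect_equal(rejected$reason[rejected$gene == "G2"], "mutant_reads<5")
  expect_equal(rejected$reason[rejected$gene == "G3"], "vaf<0.01")
  # idempotence
  expect_equal(suppressMessages(filter_somatic_candidates(kept))$gene,
               kept$gene)
  empty <- cand[0, ]
  expect_equal(nrow(filter_somatic_candidates(empty)), 0)
})

test_that("copy-number calls use inclusive amplification and zero-deletion thresholds", {
  expect_equal(classify_cnv(c(4, 0, 2, 5.2, 1)),
               c("amplification", "homozygous_deletion", "neutral",
                 "amplification", "neutral"))
  expect_error(classify_cnv(-1), "non-negative")
})

test_that("log-ratios center at the median and recover planted gains", {
  expect_equal(compute_log_ratio(100, 100, center = FALSE), 0)
  expect_equal(compute_log_ratio(400, 100, center = FALSE), 2)
  expect_error(compute_log_ratio(0, 10), "positive")
  # one 2-fold gain among flat regions
  set.seed(31)
  normal <- runif(20, 80, 120)
  tumor <- normal * c(2, rep(1, 19)) * exp(rnorm(20, 0, 0.01))
  lr <- compute_log_ratio(tumor, normal)
  expect_equal(lr[1], 1, tolerance = 0.05)
  expect_equal(median(lr), 0)
})

test_that("discordant collection keeps abnormal inserts only", {
  rp <- data.frame(chrom = "chr4", pos1 = 1:4 * 100, pos2 = 1:4 * 100 + 75,
                   insert_size = c(2001, 0, 300, 2000))
  disc <- collect_discordant(rp)
  expect_equal(disc$insert_size, c(2001, 0))
  expect_equal(collect_discordant(disc)$insert_size, disc$insert_size)
})

test_that("breakpoint clustering follows single linkage with a minimum size", {
  rp <- data.frame(chrom = "chr4", pos1 = c(100, 400, 1200),
                   pos2 = c(150, 450, 1250), insert_size = 5000)
  cl <- cluster_discordant(rp)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$start, 100)
  expect_equal(cl$end, 400)
  expect_equal(cl$n_reads, 2)
  # chain case: every consecutive gap below the threshold gives one cluster
  chain <- data.frame(chrom = "chrX", pos1 = seq(1000, 3000, by = 400),
                      pos2 = seq(1000, 3000, by = 400) + 10,
                      insert_size = 0)
  cl2 <- cluster_discordant(chain)
  expect_equal(nrow(cl2), 1)
  expect_equal(cl2$start, 1000)
  expect_equal(cl2$end, 3000)
  expect_equal(nrow(cluster_discordant(rp[0, ])), 0)
})

test_that("clustering equals the connected-components oracle and ignores input order", {
  set.seed(17)
  for (rep in 1:10) {
    n <- sample(5:60, 1)
    pos <- sort(sample(1:20000, n))
    rp <- data.frame(chrom = "chr1", pos1 = pos, pos2 = pos + 50,
                     insert_size = 3000)
    cl <- cluster_discordant(rp)
    oracle <- brute_position_clusters(pos, max_gap = 500,
                                      min_cluster_size = 2)
    expect_equal(nrow(cl), length(oracle))
    if (length(oracle) > 0) {
      oracle_bounds <- t(vapply(oracle, range, numeric(2)))
      ord <- order(oracle_bounds[, 1])
      expect_equal(cl$start, oracle_bounds[ord, 1])
      expect_equal(cl$end, oracle_bounds[ord, 2])
      expect_equal(cl$n_reads, lengths(oracle)[ord])
    }
    shuffled <- rp[sample(nrow(rp)), ]
    expect_equal(cluster_discordant(shuffled), cl)
  }
})

test_that("TMB counts eligible coding mutations per megabase", {
  cand <- data.frame(is_coding = c(rep(TRUE, 8), FALSE, FALSE),
                     is_driver = c(rep(FALSE, 5), TRUE, TRUE, TRUE, FALSE,
                                   FALSE),
                     in_dbsnp_germline = c(TRUE, TRUE, rep(FALSE, 8)))
  est <- compute_tmb(cand, 5)
  # 10 candidates: 2 non-coding out, 3 drivers out, 2 germline out -> 3 left
  expect_equal(est$n_eligible, 3)
  expect_equal(est$tmb, 0.6)
  expect_equal(compute_tmb(cand[0, ], 50)$tmb, 0)
  expect_equal(compute_tmb(data.frame(is_coding = rep(TRUE, 192),
                                      is_driver = FALSE,
                                      in_dbsnp_germline = FALSE), 50)$tmb,
               3.84)
  expect_error(compute_tmb(cand, 0), "positive")
  # all-coding panel: 10 candidates, 3 drivers, 2 germline -> 5 eligible
  all_coding <- data.frame(is_coding = TRUE,
                           is_driver = c(rep(TRUE, 3), rep(FALSE, 7)),
                           in_dbsnp_germline = c(rep(FALSE, 3),
                                                 TRUE, TRUE, rep(FALSE, 5)))
  expect_equal(compute_tmb(all_coding, 5)$tmb, 1.0)
  # linear in count, inverse in region size
  base <- compute_tmb(cand, 5)$tmb
  expect_equal(compute_tmb(rbind(cand, cand), 5)$tmb, 2 * base)
  expect_equal(compute_tmb(cand, 10)$tmb, base / 2)
})
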