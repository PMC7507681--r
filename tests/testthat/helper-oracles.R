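# Independent brute-force oracles. These deliberately avoid the code paths
# (igraph transitivity/knn/distances, phyper, wilcox.test) that the package
# itself uses.

fixture_path <- function() {
  system.file("extdata", "pazopanib_case_mutations.tsv", package = "resistnet")
}

# adjacency matrix of a named igraph graph (data extraction only)
adj_matrix <- function(g) {
  igraph::as_adjacency_matrix(g, sparse = FALSE)
}

# local clustering coefficient by neighbor-pair enumeration
brute_cc <- function(adj) {
  n <- nrow(adj)
  vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] > 0)
    d <- length(nb)
    if (d < 2) return(0)
    links <- 0
    for (a in seq_len(d - 1)) {
      for (b in seq(a + 1, d)) {
        if (adj[nb[a], nb[b]] > 0) links <- links + 1
      }
    }
    2 * links / (d * (d - 1))
  }, numeric(1))
}

# average neighbor degree from row sums
brute_k1 <- function(adj) {
  deg <- rowSums(adj)
  vapply(seq_len(nrow(adj)), function(i) {
    nb <- which(adj[i, ] > 0)
    if (length(nb) == 0) return(0)
    mean(deg[nb])
  }, numeric(1))
}

# all-pairs shortest paths by Floyd-Warshall, then component-local closeness
brute_closeness <- function(adj) {
  n <- nrow(adj)
  d <- ifelse(adj > 0, 1, Inf)
  diag(d) <- 0
  for (k in seq_len(n)) {
    d <- pmin(d, outer(d[, k], d[k, ], "+"))
  }
  vapply(seq_len(n), function(i) {
    reach <- which(is.finite(d[i, ]) & seq_len(n) != i)
    if (length(reach) == 0) return(0)
    length(reach) / sum(d[i, reach])
  }, numeric(1))
}

# connected components by breadth-first search (for giant_component checks)
brute_components <- function(adj) {
  n <- nrow(adj)
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue) > 0) {
      v <- queue[1]
      queue <- queue[-1]
      nb <- which(adj[v, ] > 0 & is.na(comp))
      comp[nb] <- cid
      queue <- c(queue, nb)
    }
  }
  comp
}

# hypergeometric upper tail by direct summation over the support
brute_hyper_tail <- function(k, K, n, N) {
  support <- max(0, n - (N - K)):min(K, n)
  terms <- choose(K, support) * choose(N - K, n - support) / choose(N, n)
  sum(terms[support >= k])
}

# exact two-sided Mann-Whitney p by enumerating all group assignments
# (tie-free inputs only, matching wilcox.test's exact method)
brute_rank_p <- function(a, b) {
  pooled <- c(a, b)
  n_a <- length(a)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  mu <- n_a * length(b) / 2
  assignments <- utils::combn(length(pooled), n_a)
  ws <- apply(assignments, 2, function(idx) {
    sum(r[idx]) - n_a * (n_a + 1) / 2
  })
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}

# single-linkage clusters as connected components of the "gap < max_gap" graph
brute_position_clusters <- function(positions, max_gap, min_cluster_size) {
  n <- length(positions)
  if (n == 0) return(list())
  adj <- abs(outer(positions, positions, "-")) < max_gap
  diag(adj) <- FALSE
  comp <- brute_components(ifelse(adj, 1, 0))
  clusters <- split(positions, comp)
  clusters <- clusters[lengths(clusters) >= min_cluster_size]
  unname(lapply(clusters, sort))
}

random_named_gnp <- function(n, p, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("N%03d", seq_len(n))
  g
}

# small deterministic growth table used across PDX tests
toy_growth <- function(treat_ratio, control_ratio = 4, n = 3) {
  rows <- list()
  for (grp in c("vehicle", "treated")) {
    ratio <- if (grp == "vehicle") control_ratio else treat_ratio
    for (i in seq_len(n)) {
      v0 <- 200 + 10 * i
      for (day in c(0, 21)) {
        v <- if (day == 0) v0 else v0 * ratio
        w <- (2 * v / 1.25)^(1 / 3)
        rows[[length(rows) + 1L]] <- data.frame(
          group = grp, animal = paste0(grp, i), day = day,
          length_mm = 1.25 * w, width_mm = w, body_weight_g = 20,
          stringsAsFactors = FALSE)
      }
    }
  }
  growth_data(do.call(rbind, rows))
}
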