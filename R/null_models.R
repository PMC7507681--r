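.degree_bin <- function(d) {
  # geometric bins [2^i, 2^(i+1)); degree 0 gets its own bin
  ifelse(d == 0, -1L, as.integer(floor(log2(d))))
}

.candidate_pools <- function(g, gene_set, matching, min_candidates) {
  deg <- igraph::degree(g)
  names(deg) <- igraph::V(g)$name
  need <- table(deg[gene_set])
  pools <- list()
  binned <- character(0)
  for (d_chr in names(need)) {
    d <- as.numeric(d_chr)
    m <- as.integer(need[[d_chr]])
    exact_pool <- names(deg)[deg == d]
    use_bin <- matching == "auto" && length(exact_pool) < min_candidates
    pool <- if (use_bin) {
      names(deg)[.degree_bin(deg) == .degree_bin(d)]
    } else {
      exact_pool
    }
    if (use_bin) binned <- c(binned, d_chr)
    if (length(pool) < m) {
      stop("degree-matched sampling impossible for degree ", d_chr,
           ": need ", m, " candidate(s), found ", length(pool),
           if (matching == "exact") " (exact matching; try matching = \"auto\")",
           call. = FALSE)
    }
    pools[[d_chr]] <- list(pool = pool, m = m)
  }
  # draw scarce pools first so overlapping geometric bins cannot starve them
  pools <- pools[order(vapply(pools, function(p) length(p$pool), numeric(1)))]
  attr(pools, "binned_degrees") <- binned
  pools
}

#' Degree-matched random gene sets
#'
#' Draws random gene sets from the network with the same size and the same
#' degree multiset as an observed gene set — the resampling null model used
#' to ask whether a topology statistic of the observed set is extreme given
#' its degree distribution. Matching is exact per degree class; under
#' `matching = "auto"` (default) a degree class with fewer than
#' `min_candidates` candidate nodes falls back to a geometric degree bin
#' \eqn{[2^i, 2^{i+1})}, which keeps sampling feasible for sparse high-degree
#' classes. Observed-set members are themselves eligible. Within one sample
#' nodes are drawn without replacement, so every sample is a set.
#'
#' @param g an igraph graph with vertex names.
#' @param gene_set character vector of node names (must all be in `g`).
#' @param n_samples number of random sets to draw.
#' @param seed optional integer seed; identical seeds give identical samples.
#' @param matching `"auto"` (exact with geometric-bin fallback) or `"exact"`.
#' @param min_candidates pool size below which a degree class is binned
#'   (default 5).
#' @return List of `n_samples` character vectors, each of length
#'   `length(gene_set)`. The attribute `binned_degrees` names the degree
#'   classes for which the fallback was used (empty under exact matching).
#' @export
sample_degree_matched <- function(g, gene_set, n_samples, seed = NULL,
                                  matching = c("auto", "exact"),
                                  min_candidates = 5) {
  matching <- match.arg(matching)
  absent <- setdiff(gene_set, igraph::V(g)$name)
  if (length(absent) > 0) {
    stop("gene set member(s) absent from graph: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  pools <- .candidate_pools(g, gene_set, matching, min_candidates)
  samples <- vector("list", n_samples)
  for (s in seq_len(n_samples)) {
    chosen <- character(0)
    for (p in pools) {
      avail <- setdiff(p$pool, chosen)
      if (length(avail) < p$m) {
        stop("degree-matched sampling exhausted a candidate pool ",
             "(overlapping degree bins); graph too small for this set",
             call. = FALSE)
      }
      # sample() with a length-1 vector would misbehave; guard it
      take <- if (length(avail) == 1) avail else sample(avail, p$m)
      chosen <- c(chosen, take[seq_len(p$m)])
    }
    samples[[s]] <- chosen
  }
  attr(samples, "binned_degrees") <- attr(pools, "binned_degrees")
  samples
}

#' Empirical p-value of an observed statistic against resampled statistics
#'
#' With `direction = "ge"` the p-value is the fraction of resampled
#' statistics greater than or equal to the observed value (the
#' alternative-hypothesis side for a claim that the observed value is high);
#' `"le"` counts the fraction less than or equal to it. The optional
#' pseudo-count mode returns `(count + 1) / (n + 1)`, which avoids reporting
#' an exact zero; the plain fraction is the default.
#'
#' @param observed observed statistic.
#' @param samples non-empty numeric vector of resampled statistics.
#' @param direction `"ge"` or `"le"`.
#' @param pseudo_count logical; use the `(count + 1) / (n + 1)` estimator.
#' @return A single numeric p-value in \[0, 1\].
#' @export
empirical_p <- function(observed, samples, direction = c("ge", "le"),
                        pseudo_count = FALSE) {
  direction <- match.arg(direction)
  if (length(samples) == 0) stop("samples must be non-empty", call. = FALSE)
  count <- if (direction == "ge") sum(samples >= observed) else
    sum(samples <= observed)
  if (pseudo_count) (count + 1) / (length(samples) + 1) else
    count / length(samples)
}

#' Degree-matched null-model analysis of a gene set
#'
#' Draws one sequence of degree-matched random gene sets (see
#' [sample_degree_matched()]) and evaluates one or more set-level topology
#' statistics on every sample, yielding an empirical p-value per metric. All
#' metrics are evaluated on the same sample sequence. The default direction
#' (`"auto"`) tests the alternative-hypothesis side — the fraction of random
#' sets whose statistic is at least the observed value, appropriate for the
#' claim that the observed set has unusually high centrality, clustering, or
#' neighbor degree. `direction = "caption-literal"` instead reports the
#' fraction less than or equal to the observed value for every metric.
#'
#' @inheritParams sample_degree_matched
#' @param metrics character vector among `"degree"`, `"cc"`, `"k1"`,
#'   `"closeness"`.
#' @param n_samples number of random sets (default 10000).
#' @param aggregator `"mean"` (default) or `"median"` set-level aggregator.
#' @param direction `"auto"` or `"caption-literal"`.
#' @param pseudo_count see [empirical_p()].
#' @return List of `null_distribution` objects (one per metric), each with
#'   `metric`, `aggregator`, `observed`, `samples` (resampled statistics),
#'   `n_samples`, `direction`, `empirical_p`, `pseudo_count`, `seed`,
#'   `matching`, `binned_degrees`, `n_dropped`.
#' @export
run_null_analysis <- function(g, gene_set,
                              metrics = c("cc", "k1", "closeness"),
                              n_samples = 10000, seed = NULL,
                              aggregator = c("mean", "median"),
                              direction = c("auto", "caption-literal"),
                              matching = c("auto", "exact"),
                              min_candidates = 5, pseudo_count = FALSE) {
  aggregator <- match.arg(aggregator)
  direction <- match.arg(direction)
  matching <- match.arg(matching)
  metrics <- match.arg(metrics, c("degree", "cc", "k1", "closeness"),
                       several.ok = TRUE)
  present <- intersect(gene_set, igraph::V(g)$name)
  if (length(present) == 0) {
    stop("none of the genes are present in the graph", call. = FALSE)
  }
  n_dropped <- length(gene_set) - length(present)
  if (n_dropped > 0) {
    warning("dropped ", n_dropped, " gene(s) absent from the graph",
            call. = FALSE)
  }

  samples <- sample_degree_matched(g, present, n_samples, seed = seed,
                                   matching = matching,
                                   min_candidates = min_candidates)
  all_metrics <- node_metrics(g)
  agg_fun <- if (aggregator == "mean") mean else stats::median
  # index samples into the metric vectors once for speed
  idx <- matrix(match(unlist(samples), all_metrics$node),
                nrow = n_samples, byrow = TRUE)

  out <- lapply(metrics, function(metric) {
    vals <- .metric_values(all_metrics, metric)
    observed <- agg_fun(unname(vals[present]))
    sample_stats <- apply(matrix(vals[idx], nrow = n_samples), 1, agg_fun)
    dir <- if (direction == "caption-literal") "le" else "ge"
    p <- empirical_p(observed, sample_stats, direction = dir,
                     pseudo_count = pseudo_count)
    structure(list(metric = metric, aggregator = aggregator,
                   observed = observed, samples = sample_stats,
                   n_samples = n_samples, direction = dir, empirical_p = p,
                   pseudo_count = pseudo_count, seed = seed,
                   matching = matching,
                   binned_degrees = attr(samples, "binned_degrees"),
                   n_dropped = n_dropped),
              class = "null_distribution")
  })
  names(out) <- metrics
  out
}

#' @export
print.null_distribution <- function(x, ...) {
  cat("<null_distribution> ", x$aggregator, " ", x$metric, ": observed = ",
      formatC(x$observed, format = "fg"), ", null mean = ",
      formatC(mean(x$samples), format = "fg"), " (n = ", x$n_samples,
      "), empirical p (", x$direction, ") = ",
      formatC(x$empirical_p, format = "fg"), "\n", sep = "")
  invisible(x)
}

#' Tabulate null-model results
#'
#' @param nulls list of `null_distribution` objects from
#'   [run_null_analysis()].
#' @return data.frame with one row per metric: observed value, null mean and
#'   SD, direction, and empirical p-value.
#' @export
null_table <- function(nulls) {
  do.call(rbind, lapply(nulls, function(x) {
    data.frame(metric = x$metric, aggregator = x$aggregator,
               observed = x$observed, mean_null = mean(x$samples),
               sd_null = stats::sd(x$samples), direction = x$direction,
               empirical_p = x$empirical_p, n_samples = x$n_samples,
               stringsAsFactors = FALSE)
  }))
}
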