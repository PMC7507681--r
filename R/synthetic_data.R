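#' Simulation configuration
#'
#' Bundles the parameters of all synthetic-data generators. Defaults are
#' chosen to emulate the study conditions the analyses assume: a desk-scale
#' scale-free interaction network (1,000 nodes, mean degree 9, so roughly
#' 4,500 edges — a 1:10 stand-in for a full-scale giant component of around
#' 9,316 nodes / 42,102 edges); a two-timepoint catalog with 9 clonal
#' persisting mutations (VAF ~ Beta(4, 4) rescaled to \[0.05, 1\]) and 53
#' subclonal new mutations (VAF ~ Beta(1.2, 15), median near 0.06) read at
#' coverages uniform on \[80, 650\] with binomial mutant-read counts; an
#' annotation map with one planted enriched term (overlap 8 of a 20-gene
#' query, term size 30); and exponential tumor growth (V0 = 200 mm3, rate
#' 0.1/day, measured twice weekly for three weeks with 10% lognormal
#' measurement noise, 6 animals per group).
#'
#' @param seed integer seed driving every generator.
#' @param n_nodes,mean_degree,degree_exponent network size, target mean
#'   degree, and power-law tail exponent.
#' @param n_persisting,n_new catalog class sizes.
#' @param persisting_vaf_shape Beta shape parameters for persisting VAFs.
#' @param persisting_vaf_range rescaling interval for persisting VAFs.
#' @param new_vaf_shape Beta shape parameters for new-mutation VAFs.
#' @param depth_range inclusive integer coverage range.
#' @param n_terms,planted_term_size,planted_overlap annotation-map structure.
#' @param term_size_range size range of the random (non-planted) terms.
#' @param v0_mm3 baseline tumor volume in cubic millimeters.
#' @param growth_rate_per_day exponential growth rate of the vehicle arm.
#' @param treatment_effect growth-rate multiplier of the treated arm
#'   (1 = no effect, 0 = full arrest).
#' @param measurement_cv coefficient of variation of the lognormal
#'   measurement noise.
#' @param n_animals animals per group.
#' @param measurement_days measurement schedule in days.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_nodes = 1000, mean_degree = 9, degree_exponent = 2.5,
                       n_persisting = 9, n_new = 53,
                       persisting_vaf_shape = c(4, 4),
                       persisting_vaf_range = c(0.05, 1),
                       new_vaf_shape = c(1.2, 15),
                       depth_range = c(80, 650),
                       n_terms = 50, planted_term_size = 30,
                       planted_overlap = 8, term_size_range = c(10, 50),
                       v0_mm3 = 200, growth_rate_per_day = 0.1,
                       treatment_effect = 0.3, measurement_cv = 0.1,
                       n_animals = 6,
                       measurement_days = c(0, 3, 7, 10, 14, 17, 21)) {
  cfg <- list(seed = as.integer(seed), n_nodes = n_nodes,
              mean_degree = mean_degree, degree_exponent = degree_exponent,
              n_persisting = n_persisting, n_new = n_new,
              persisting_vaf_shape = persisting_vaf_shape,
              persisting_vaf_range = persisting_vaf_range,
              new_vaf_shape = new_vaf_shape, depth_range = depth_range,
              n_terms = n_terms, planted_term_size = planted_term_size,
              planted_overlap = planted_overlap,
              term_size_range = term_size_range, v0_mm3 = v0_mm3,
              growth_rate_per_day = growth_rate_per_day,
              treatment_effect = treatment_effect,
              measurement_cv = measurement_cv, n_animals = n_animals,
              measurement_days = measurement_days)
  counts <- c(cfg$n_nodes, cfg$n_persisting, cfg$n_new, cfg$n_terms,
              cfg$planted_term_size, cfg$n_animals)
  if (any(counts <= 0)) stop("all counts must be positive", call. = FALSE)
  if (cfg$planted_overlap > cfg$planted_term_size) {
    stop("planted_overlap cannot exceed planted_term_size", call. = FALSE)
  }
  if (cfg$n_nodes < 10) stop("n_nodes must be at least 10", call. = FALSE)
  structure(cfg, class = "sim_config")
}

#' Generate a scale-free interaction network
#'
#' Draws a simple undirected graph with a power-law-ish degree sequence
#' (static fitness model with the configured tail exponent and expected mean
#' degree), then extracts the giant component, which is what all topology
#' analyses operate on. Node and edge counts after extraction are reported in
#' a message. Fully determined by `config$seed`.
#'
#' @param config a [sim_config()].
#' @return A connected, simple igraph graph with vertex names `G0001`, ...
#' @export
generate_ppi <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  m <- round(config$n_nodes * config$mean_degree / 2)
  g <- igraph::sample_fitness_pl(config$n_nodes, m,
                                 exponent.out = config$degree_exponent,
                                 exponent.in = -1)
  igraph::V(g)$name <- sprintf("G%04d", seq_len(config$n_nodes))
  g <- igraph::simplify(g)
  g <- giant_component(g)
  message("generate_ppi: giant component has ", igraph::vcount(g),
          " node(s) and ", igraph::ecount(g), " edge(s)")
  g
}

#' Plant a gene module in a network
#'
#' Three planting modes for power and calibration studies of the
#' degree-matched null model:
#' \describe{
#'   \item{hub}{the `size` highest-degree nodes (graph unchanged).}
#'   \item{random}{a uniform random node sample (graph unchanged; the null
#'     configuration for calibration).}
#'   \item{clustered}{a seed node plus nearby nodes (neighbors and
#'     neighbors-of-neighbors), among which edges are added until the set's
#'     mean local clustering coefficient exceeds the graph mean by
#'     `cc_margin` — emulating a tightly woven mutated module.}
#' }
#' Because the clustered mode rewires a copy of the graph, the modified graph
#' is returned alongside the set.
#'
#' @param g an igraph graph with vertex names.
#' @param size module size.
#' @param mode `"clustered"`, `"hub"`, or `"random"`.
#' @param cc_margin required excess of the module's mean clustering
#'   coefficient over the graph mean (clustered mode, default 0.25).
#' @param seed optional integer seed.
#' @return List with `graph` (possibly modified) and `genes` (character
#'   vector of module members).
#' @export
plant_module <- function(g, size, mode = c("clustered", "hub", "random"),
                         cc_margin = 0.25, seed = NULL) {
  mode <- match.arg(mode)
  if (size > igraph::vcount(g)) {
    stop("module size exceeds the number of nodes", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  nodes <- igraph::V(g)$name
  if (mode == "hub") {
    deg <- igraph::degree(g)
    genes <- nodes[order(deg, nodes, decreasing = c(TRUE, FALSE),
                         method = "radix")][seq_len(size)]
    return(list(graph = g, genes = genes))
  }
  if (mode == "random") {
    return(list(graph = g, genes = sample(nodes, size)))
  }
  # clustered: grow from a seed whose 2-neighborhood is large enough
  ego2 <- igraph::ego(g, order = 2)
  big_enough <- which(lengths(ego2) >= size)
  if (length(big_enough) == 0) {
    stop("no node has a 2-neighborhood of size ", size,
         "; reduce the module size", call. = FALSE)
  }
  seed_node <- sample(big_enough, 1)
  genes <- nodes[as.integer(ego2[[seed_node]])][seq_len(size)]
  target <- mean(igraph::transitivity(g, type = "local", isolates = "zero")) +
    cc_margin
  missing_pairs <- function(gr) {
    pairs <- utils::combn(genes, 2)
    have <- igraph::are_adjacent
    keep <- !vapply(seq_len(ncol(pairs)),
                    function(i) have(gr, pairs[1, i], pairs[2, i]),
                    logical(1))
    pairs[, keep, drop = FALSE]
  }
  module_cc <- function(gr) {
    cc <- igraph::transitivity(gr, type = "local", isolates = "zero")
    names(cc) <- igraph::V(gr)$name
    mean(cc[genes])
  }
  gr <- g
  candidates <- missing_pairs(gr)
  while (module_cc(gr) < target && ncol(candidates) > 0) {
    pick <- sample.int(ncol(candidates), 1)
    gr <- igraph::add_edges(gr, candidates[, pick])
    candidates <- candidates[, -pick, drop = FALSE]
  }
  if (module_cc(gr) < target) {
    warning("clustered module saturated below the requested margin",
            call. = FALSE)
  }
  list(graph = gr, genes = genes)
}

.draw_vaf_records <- function(genes, vafs, depth_range, assay_id, tag) {
  coverage <- sample(seq(depth_range[1], depth_range[2]), length(genes),
                     replace = TRUE)
  reads <- stats::rbinom(length(genes), coverage, vafs)
  data.frame(gene = genes,
             cdna_change = sprintf("c.%d%s>%s", seq_along(genes) * 3 + 1,
                                   "A", "G"),
             aa_change = sprintf("%s%dX", tag, seq_along(genes)),
             assay_id = assay_id, mutant_reads = reads, coverage = coverage,
             vaf = reads / coverage, significance_class = "unknown",
             stringsAsFactors = FALSE)
}

#' Generate paired two-timepoint mutation catalogs
#'
#' Emulates the clonality structure of acquired resistance: persisting
#' mutations appear at both timepoints with high (clonal) VAFs, while new
#' mutations appear only post-resistance with low (subclonal) VAFs. Each
#' record's mutant read count is Binomial(coverage, VAF) with coverage drawn
#' uniformly from the configured depth range, and the recorded VAF is exactly
#' `mutant_reads / coverage`.
#'
#' @param config a [sim_config()].
#' @param genes optional character vector supplying gene symbols (e.g. nodes
#'   of a generated network); defaults to synthetic symbols. Must have at
#'   least `n_persisting + n_new` elements.
#' @return List with `pre` and `post` single-assay [mutation_catalog()]s
#'   (assays `"WES1"`, `"WES2"`) and `truth`, a data.frame labelling every
#'   (gene, cdna_change) as `persisting` or `new`.
#' @export
generate_mutation_tables <- function(config, genes = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_total <- config$n_persisting + config$n_new
  if (is.null(genes)) genes <- sprintf("MUT%04d", seq_len(n_total))
  if (length(genes) < n_total) {
    stop("need at least ", n_total, " gene symbols", call. = FALSE)
  }
  genes <- sample(genes, n_total)
  pers_genes <- genes[seq_len(config$n_persisting)]
  new_genes <- genes[config$n_persisting + seq_len(config$n_new)]

  rescale <- function(x, range) range[1] + x * (range[2] - range[1])
  pers_vaf_pre <- rescale(stats::rbeta(config$n_persisting,
                                       config$persisting_vaf_shape[1],
                                       config$persisting_vaf_shape[2]),
                          config$persisting_vaf_range)
  pers_vaf_post <- rescale(stats::rbeta(config$n_persisting,
                                        config$persisting_vaf_shape[1],
                                        config$persisting_vaf_shape[2]),
                           config$persisting_vaf_range)
  new_vaf <- stats::rbeta(config$n_new, config$new_vaf_shape[1],
                          config$new_vaf_shape[2])

  pre_pers <- .draw_vaf_records(pers_genes, pers_vaf_pre, config$depth_range,
                                "WES1", "P")
  post_pers <- .draw_vaf_records(pers_genes, pers_vaf_post,
                                 config$depth_range, "WES2", "P")
  post_new <- .draw_vaf_records(new_genes, new_vaf, config$depth_range,
                                "WES2", "N")
  # persisting keys must coincide across assays
  post_pers$cdna_change <- pre_pers$cdna_change
  post_pers$aa_change <- pre_pers$aa_change
  post_new$cdna_change <- sprintf("c.%dC>T", seq_len(config$n_new) * 7 + 2)

  truth <- data.frame(
    gene = c(pers_genes, new_genes),
    cdna_change = c(pre_pers$cdna_change, post_new$cdna_change),
    class = rep(c("persisting", "new"), c(config$n_persisting, config$n_new)),
    stringsAsFactors = FALSE)
  list(pre = mutation_catalog(pre_pers, assay_ids = "WES1"),
       post = mutation_catalog(rbind(post_pers, post_new),
                               assay_ids = "WES2"),
       truth = truth)
}

#' Generate an annotation map with one planted enriched term
#'
#' Builds `n_terms` random terms (uniform gene subsets of the background,
#' sizes uniform in the configured range) plus one planted term containing
#' `planted_overlap` query genes and `planted_term_size - planted_overlap`
#' non-query background genes — a known-truth oracle for enrichment tests.
#'
#' @param config a [sim_config()].
#' @param background character vector of background gene symbols.
#' @param query character vector of query gene symbols (subset of the
#'   background for the planted overlap to be meaningful).
#' @return An [annotation_map()]; the planted term has id `"PLANTED"`.
#' @export
generate_annotations <- function(config, background, query) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  background <- unique(as.character(background))
  query <- unique(as.character(query))
  if (config$planted_overlap > length(query)) {
    stop("planted_overlap exceeds the query size", call. = FALSE)
  }
  n_filler <- config$planted_term_size - config$planted_overlap
  non_query <- setdiff(background, query)
  if (n_filler > length(non_query)) {
    stop("background too small for the planted term", call. = FALSE)
  }
  planted <- c(if (config$planted_overlap > 0)
    sample(query, config$planted_overlap),
    sample(non_query, n_filler))
  t2g <- list(PLANTED = planted)
  sizes <- sample(seq(config$term_size_range[1], config$term_size_range[2]),
                  config$n_terms, replace = TRUE)
  for (i in seq_len(config$n_terms)) {
    t2g[[sprintf("T%04d", i)]] <- sample(background, sizes[i])
  }
  names_vec <- stats::setNames(
    c("planted enriched term", sprintf("random term %d",
                                       seq_len(config$n_terms))),
    names(t2g))
  annotation_map(t2g, term_names = names_vec)
}

#' Generate exponential PDX growth curves
#'
#' Per-animal tumor volumes follow `V(t) = V0 * exp(r * effect * t)` with
#' multiplicative lognormal measurement noise of the configured coefficient
#' of variation (mean-one noise, so the expected measured volume equals the
#' true curve). Caliper length and width are back-derived with a fixed 1.25
#' aspect ratio so that `length * width^2 / 2` reproduces the measured
#' volume exactly. Body weights are stable around 20 g.
#'
#' @param config a [sim_config()].
#' @param groups named numeric vector of growth-rate multipliers per group,
#'   e.g. `c(vehicle = 1, treated = 0.3)`; defaults to a vehicle arm plus one
#'   arm at `config$treatment_effect`.
#' @return A [growth_data()] table.
#' @export
generate_growth_curves <- function(config, groups = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(groups)) {
    groups <- c(vehicle = 1, treated = config$treatment_effect)
  }
  set.seed(config$seed)
  sdlog <- sqrt(log(1 + config$measurement_cv^2))
  aspect <- 1.25
  rows <- list()
  for (grp in names(groups)) {
    for (animal in seq_len(config$n_animals)) {
      true_v <- config$v0_mm3 *
        exp(config$growth_rate_per_day * groups[[grp]] *
              config$measurement_days)
      noise <- stats::rlnorm(length(true_v), meanlog = -sdlog^2 / 2,
                             sdlog = sdlog)
      v <- true_v * noise
      width <- (2 * v / aspect)^(1 / 3)
      rows[[length(rows) + 1L]] <- data.frame(
        group = grp, animal = sprintf("%s_%02d", grp, animal),
        day = config$measurement_days,
        length_mm = aspect * width, width_mm = width,
        body_weight_g = 20 + stats::rnorm(length(true_v), 0, 0.3),
        stringsAsFactors = FALSE)
    }
  }
  growth_data(do.call(rbind, rows))
}

#' Closed-form TGI of the noise-free exponential growth model
#'
#' For volumes `V(t) = V0 exp(r e t)` the TGI at day `t` of an arm with
#' multiplier `e` against a vehicle arm (`e = 1`) is
#' `(1 - (exp(r e t) - 1) / (exp(r t) - 1)) * 100`.
#'
#' @param config a [sim_config()].
#' @param effect growth-rate multiplier of the treated arm.
#' @param day evaluation day (default: last measurement day).
#' @return TGI percent of the noise-free curves.
#' @export
analytic_tgi <- function(config, effect, day = NULL) {
  if (is.null(day)) day <- max(config$measurement_days)
  r <- config$growth_rate_per_day
  (1 - (exp(r * effect * day) - 1) / (exp(r * day) - 1)) * 100
}
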