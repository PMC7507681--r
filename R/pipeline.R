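.default_pipeline_config <- function() {
  list(
    mutation_table = NULL, edge_list = NULL, annotations = NULL,
    annotation_term_meta = NULL, read_pairs = NULL, growth_table = NULL,
    pre_assay = "WES1", post_assay = "WES2", vaf_threshold = 0.10,
    n_samples = 10000, seed = NULL, direction = "auto", matching = "auto",
    alpha = 0.001, min_reads = 5, min_vaf = 0.01, cnv_amp = 4,
    max_insert = 2000, cluster_gap = 500, min_cluster_size = 2,
    region_mb = NULL, control_group = "vehicle", out_dir = "resistnet_out")
}

#' Pipeline configuration
#'
#' Assembles (and validates) the configuration of [run_pipeline()]. Values
#' can come from a YAML file, from `...` overrides, or both (overrides win).
#' Every analysis threshold is a named key with the package default:
#' `vaf_threshold` 0.10, `n_samples` 10000, `alpha` 0.001, `min_reads` 5,
#' `min_vaf` 0.01, `cnv_amp` 4, `max_insert` 2000, `cluster_gap` 500,
#' `min_cluster_size` 2. A `seed` is mandatory whenever the null-model stage
#' runs.
#'
#' @param file optional YAML file path.
#' @param ... named overrides of the defaults.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(file = NULL, ...) {
  cfg <- .default_pipeline_config()
  if (!is.null(file)) {
    from_file <- yaml::read_yaml(file)
    unknown <- setdiff(names(from_file), names(cfg))
    if (length(unknown) > 0) {
      stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    cfg[names(from_file)] <- from_file
  }
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(overrides)] <- overrides

  stopifnot(cfg$vaf_threshold >= 0, cfg$vaf_threshold <= 1,
            cfg$n_samples >= 1, cfg$alpha > 0, cfg$alpha <= 1,
            cfg$min_reads >= 0, cfg$min_vaf >= 0, cfg$min_vaf <= 1,
            cfg$cnv_amp > 0, cfg$max_insert > 0, cfg$cluster_gap > 0,
            cfg$min_cluster_size >= 1)
  if (!cfg$direction %in% c("auto", "caption-literal")) {
    stop("direction must be 'auto' or 'caption-literal'", call. = FALSE)
  }
  if (!cfg$matching %in% c("auto", "exact")) {
    stop("matching must be 'auto' or 'exact'", call. = FALSE)
  }
  structure(cfg, class = "pipeline_config")
}

.config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(deparse(cfg[order(names(unclass(cfg)))]),
                   collapse = ""), tmp)
  unname(tools::md5sum(tmp))
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the end-to-end resistance-genomics pipeline
#'
#' Orchestrates: (a) two-timepoint cohort comparison and VAF summary from the
#' mutation table; (b) network metrics and the mutated-gene subnetwork from
#' the edge list; (c) degree-matched null-model analyses of the pre ("old")
#' and newly mutated ("new") gene sets; (d) term enrichment of both sets
#' against the network background; (e) discordant read-pair clustering; (f)
#' TMB; (g) the PDX TGI table. Stages whose inputs are absent from the
#' configuration are skipped with a notice. Every run writes a
#' `manifest.json` embedding the configuration hash, seed, and package
#' version; outputs never overwrite inputs and all land under
#' `config$out_dir`. If any attempted stage fails, partial outputs and the
#' manifest are retained and an error naming the failed stage(s) is raised.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    version = as.character(utils::packageVersion("resistnet")),
    seed = config$seed, config_hash = .config_hash(config),
    stages = list(), outputs = character(0))
  status <- function(name, state, detail = NULL) {
    manifest$stages[[name]] <<- list(status = state, detail = detail)
  }
  run_stage <- function(name, enabled, fun) {
    if (!enabled) {
      message("run_pipeline: stage '", name, "' skipped (no input configured)")
      status(name, "skipped")
      return(NULL)
    }
    tryCatch({
      res <- fun()
      status(name, "ok")
      res
    }, error = function(e) {
      status(name, "failed", conditionMessage(e))
      message("run_pipeline: stage '", name, "' failed: ",
              conditionMessage(e))
      NULL
    })
  }
  out <- function(path) {
    manifest$outputs <<- c(manifest$outputs, path)
    path
  }

  catalog <- NULL
  comparison <- NULL
  cohort <- run_stage("cohort", !is.null(config$mutation_table), function() {
    catalog <<- parse_mutation_table(config$mutation_table)
    pre <- assay_slice(catalog, config$pre_assay)
    post <- assay_slice(catalog, config$post_assay)
    comparison <<- classify_mutations(pre, post)
    summary <- cohort_vaf_summary(comparison, post,
                                  threshold = config$vaf_threshold)
    .write_tsv(comparison$persisting,
               out(file.path(config$out_dir, "persisting.tsv")))
    .write_tsv(comparison$new, out(file.path(config$out_dir, "new.tsv")))
    .write_tsv(comparison$lost, out(file.path(config$out_dir, "lost.tsv")))
    report <- list(
      pre_assay = comparison$pre_assay, post_assay = comparison$post_assay,
      n_persisting = nrow(comparison$persisting),
      n_new = nrow(comparison$new), n_lost = nrow(comparison$lost),
      median_persisting_vaf = summary$persisting$median_vaf,
      persisting_fraction_above = summary$persisting$fraction_above,
      median_new_vaf = summary$new$median_vaf,
      new_fraction_above = summary$new$fraction_above,
      vaf_threshold = config$vaf_threshold,
      vaf_test_p = if (!is.null(summary$test)) summary$test$p_value,
      vaf_test = if (!is.null(summary$test)) summary$test$method)
    jsonlite::write_json(report,
                         out(file.path(config$out_dir, "cohort_report.json")),
                         auto_unbox = TRUE, digits = NA)
    list(comparison = comparison, summary = summary)
  })

  network <- NULL
  network_res <- run_stage("network", !is.null(config$edge_list), function() {
    g <- load_edge_list(config$edge_list)
    network <<- giant_component(g)
    metrics <- node_metrics(network)
    .write_tsv(metrics, out(file.path(config$out_dir, "node_metrics.tsv")))
    if (!is.null(comparison)) {
      mutated <- unique(c(comparison$persisting$gene, comparison$new$gene,
                          comparison$lost$gene))
      pre_genes <- unique(c(comparison$persisting$gene,
                            comparison$lost$gene))
      post_genes <- unique(c(comparison$persisting$gene,
                             comparison$new$gene))
      attrs <- data.frame(
        node = mutated,
        mutated = ifelse(mutated %in% pre_genes & mutated %in% post_genes,
                         "both",
                         ifelse(mutated %in% pre_genes, "pre", "post")),
        stringsAsFactors = FALSE)
      sub <- subnetwork(network, mutated, node_attrs = attrs)
      paths <- export_subnetwork(sub, file.path(config$out_dir,
                                                "mutated_subnetwork"))
      out(paths[["edges"]]); out(paths[["nodes"]])
    }
    network
  })

  run_stage("null_models",
            !is.null(network) && !is.null(comparison) &&
              !is.null(config$seed), function() {
    sets <- list(
      old = unique(c(comparison$persisting$gene, comparison$lost$gene)),
      new = unique(comparison$new$gene))
    for (label in names(sets)) {
      genes <- intersect(sets[[label]], igraph::V(network)$name)
      if (length(genes) == 0) next
      nulls <- run_null_analysis(
        network, genes, metrics = c("degree", "cc", "k1", "closeness"),
        n_samples = config$n_samples, seed = config$seed,
        direction = config$direction, matching = config$matching)
      .write_tsv(null_table(nulls),
                 out(file.path(config$out_dir,
                               paste0("null_", label, ".tsv"))))
    }
    invisible(NULL)
  })

  run_stage("enrichment",
            !is.null(config$annotations) && !is.null(network) &&
              !is.null(comparison), function() {
    ann <- read_annotation_map(config$annotations,
                               term_meta = config$annotation_term_meta)
    background <- igraph::V(network)$name
    sets <- list(
      old = unique(c(comparison$persisting$gene, comparison$lost$gene)),
      new = unique(comparison$new$gene))
    for (label in names(sets)) {
      res <- tryCatch(
        enrich(sets[[label]], ann, background, alpha = config$alpha),
        error = function(e) NULL)
      if (is.null(res)) next
      .write_tsv(res, out(file.path(config$out_dir,
                                    paste0("enrichment_", label, ".tsv"))))
    }
    invisible(NULL)
  })

  run_stage("rearrangements", !is.null(config$read_pairs), function() {
    pairs <- read_read_pairs(config$read_pairs)
    discordant <- collect_discordant(pairs, max_insert = config$max_insert)
    clusters <- cluster_discordant(discordant, max_gap = config$cluster_gap,
                                   min_cluster_size = config$min_cluster_size)
    .write_tsv(clusters,
               out(file.path(config$out_dir, "breakpoint_clusters.tsv")))
    clusters
  })

  run_stage("tmb",
            !is.null(config$region_mb) && !is.null(catalog), function() {
    estimates <- lapply(attr(catalog, "assay_ids"), function(aid) {
      slice <- assay_slice(catalog, aid)
      # coding point mutations only; the catalog carries no driver/dbSNP
      # flags, so none are excluded here
      cand <- data.frame(is_coding = rep(TRUE, nrow(slice)),
                         is_driver = FALSE, in_dbsnp_germline = FALSE)
      est <- compute_tmb(cand, config$region_mb)
      list(assay = aid, n_eligible = est$n_eligible, tmb = est$tmb)
    })
    jsonlite::write_json(estimates,
                         out(file.path(config$out_dir, "tmb.json")),
                         auto_unbox = TRUE, digits = NA)
    estimates
  })

  run_stage("pdx", !is.null(config$growth_table), function() {
    growth <- read_growth_table(config$growth_table)
    tab <- tgi_table(growth, control = config$control_group)
    .write_tsv(tab, out(file.path(config$out_dir, "tgi.tsv")))
    flags <- endpoint_flags(growth)
    .write_tsv(flags, out(file.path(config$out_dir, "endpoint_flags.tsv")))
    tab
  })

  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  failed <- names(Filter(function(s) identical(s$status, "failed"),
                         manifest$stages))
  if (length(failed) > 0) {
    stop("pipeline stage(s) failed: ", paste(failed, collapse = ", "),
         "; partial outputs and manifest retained in ", config$out_dir,
         call. = FALSE)
  }
  invisible(manifest)
}
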