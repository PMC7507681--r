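#' Load an undirected protein-protein interaction network from an edge list
#'
#' Reads a two-column tab-separated file of gene-symbol pairs and builds a
#' simple undirected graph: self-interactions are dropped, and redundant
#' interactions (including reversed duplicates, A-B vs B-A) are stored once.
#' A message reports how many self-loops and duplicate pairs were removed.
#'
#' @param path path to the edge list.
#' @return An undirected simple [igraph][igraph::igraph-package] graph with
#'   vertex names.
#' @export
load_edge_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(igraph::make_empty_graph(n = 0, directed = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 2)
  if (length(bad) > 0) {
    stop("malformed edge at line ", bad[1], " of ", path,
         ": expected 2 tab-separated columns, found ",
         lengths(fields)[bad[1]], call. = FALSE)
  }
  a <- vapply(fields, `[`, character(1), 1)
  b <- vapply(fields, `[`, character(1), 2)
  self <- a == b
  a2 <- pmin(a[!self], b[!self])
  b2 <- pmax(a[!self], b[!self])
  dup <- duplicated(paste(a2, b2, sep = "\r"))
  message("load_edge_list: ", sum(self), " self-loop(s) and ", sum(dup),
          " duplicate pair(s) removed; ", sum(!dup), " edge(s) kept")
  nodes <- sort(unique(c(a, b)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = a2[!dup], to = b2[!dup], stringsAsFactors = FALSE),
    directed = FALSE, vertices = nodes)
  g
}

#' Extract the giant connected component
#'
#' All topology statistics in this package are computed within the largest
#' connected component. Ties between equally sized components are broken
#' deterministically by the lexicographically smallest member node, so
#' repeated runs always select the same component.
#'
#' @param g an igraph graph.
#' @return The induced subgraph on the largest component (the empty graph is
#'   returned unchanged). Idempotent.
#' @export
giant_component <- function(g) {
  if (igraph::vcount(g) == 0) return(g)
  comps <- igraph::components(g)
  biggest <- which(comps$csize == max(comps$csize))
  if (length(biggest) > 1) {
    firsts <- vapply(biggest, function(ci) {
      min(igraph::V(g)$name[comps$membership == ci])
    }, character(1))
    biggest <- biggest[order(firsts)][1]
  }
  igraph::induced_subgraph(g, which(comps$membership == biggest))
}

.metric_names <- c(degree = "degree", cc = "clustering_coefficient",
                   k1 = "avg_neighbor_degree", closeness = "closeness")

#' Per-node topology metrics
#'
#' For each requested node computes:
#' \describe{
#'   \item{degree}{number of interaction partners.}
#'   \item{clustering_coefficient}{fraction of realized edges among all
#'     possible pairs of the node's direct neighbors, `2t / (d (d - 1))`;
#'     defined as 0 for degree < 2 so that set-level means are total.}
#'   \item{avg_neighbor_degree}{mean degree over the node's neighbors (K1
#'     centrality); 0 for isolated nodes.}
#'   \item{closeness}{`(n - 1) / sum of shortest-path distances` to the other
#'     `n - 1` nodes of the node's connected component (normalized,
#'     component-local closeness); 0 for isolated nodes.}
#' }
#'
#' @param g an igraph graph with vertex names.
#' @param nodes character vector of node names, default all nodes.
#' @return data.frame with columns `node`, `degree`,
#'   `clustering_coefficient`, `avg_neighbor_degree`, `closeness`.
#' @export
node_metrics <- function(g, nodes = NULL) {
  all_names <- igraph::V(g)$name
  if (is.null(nodes)) {
    nodes <- all_names
  } else {
    absent <- setdiff(nodes, all_names)
    if (length(absent) > 0) {
      stop("node(s) absent from graph: ", paste(absent, collapse = ", "),
           call. = FALSE)
    }
  }
  deg <- igraph::degree(g)
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  names(cc) <- all_names
  knn <- suppressWarnings(igraph::knn(g))$knn
  knn[is.nan(knn) | is.na(knn)] <- 0
  names(knn) <- all_names

  clo <- stats::setNames(numeric(length(all_names)), all_names)
  comps <- igraph::components(g)
  for (ci in seq_len(comps$no)) {
    members <- which(comps$membership == ci)
    nm <- all_names[members]
    if (length(members) == 1) {
      clo[nm] <- 0
      next
    }
    d <- igraph::distances(g, v = members, to = members)
    clo[nm] <- (length(members) - 1) / rowSums(d)
  }
  data.frame(node = nodes, degree = unname(deg[nodes]),
             clustering_coefficient = unname(cc[nodes]),
             avg_neighbor_degree = unname(knn[nodes]),
             closeness = unname(clo[nodes]),
             stringsAsFactors = FALSE)
}

.metric_values <- function(metrics_df, metric) {
  metric <- match.arg(metric, names(.metric_names))
  stats::setNames(metrics_df[[.metric_names[[metric]]]], metrics_df$node)
}

#' Set-level topology statistic
#'
#' Aggregates a per-node metric over a gene set. Genes absent from the graph
#' (e.g. fusion partners not covered by the interaction sources) are dropped
#' with a warning rather than treated as isolates, because the analysis is
#' defined on the giant component.
#'
#' @param g an igraph graph.
#' @param gene_set character vector of gene symbols.
#' @param metric one of `"degree"`, `"cc"`, `"k1"`, `"closeness"`.
#' @param aggregator `"mean"` (default) or `"median"`.
#' @return List of class `set_statistic`: `gene_set` (the members actually
#'   used), `metric`, `aggregator`, `value`, `n_dropped`.
#' @export
set_statistic <- function(g, gene_set,
                          metric = c("degree", "cc", "k1", "closeness"),
                          aggregator = c("mean", "median")) {
  metric <- match.arg(metric)
  aggregator <- match.arg(aggregator)
  present <- intersect(gene_set, igraph::V(g)$name)
  dropped <- setdiff(gene_set, present)
  if (length(present) == 0) {
    stop("none of the genes are present in the graph", call. = FALSE)
  }
  if (length(dropped) > 0) {
    warning("dropped ", length(dropped), " gene(s) absent from the graph: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  vals <- .metric_values(node_metrics(g, present), metric)
  value <- if (aggregator == "mean") mean(vals) else stats::median(vals)
  structure(list(gene_set = present, metric = metric, aggregator = aggregator,
                 value = value, n_dropped = length(dropped)),
            class = "set_statistic")
}

#' @export
print.set_statistic <- function(x, ...) {
  cat("<set_statistic> ", x$aggregator, " ", x$metric, " over ",
      length(x$gene_set), " gene(s): ", formatC(x$value, format = "fg"),
      "\n", sep = "")
  invisible(x)
}

#' Subnetwork induced by a gene set
#'
#' Returns the induced subgraph on `gene_set` intersected with the graph's
#' nodes, keeping every edge whose both endpoints are in the set. Optional
#' node attributes (e.g. mutated pre/post/both, mutation multiplicity) are
#' attached for downstream export and rendering.
#'
#' @param g an igraph graph.
#' @param gene_set character vector of gene symbols.
#' @param node_attrs optional data.frame with a `node` column plus attribute
#'   columns to attach to matching vertices.
#' @return An igraph graph.
#' @export
subnetwork <- function(g, gene_set, node_attrs = NULL) {
  present <- intersect(gene_set, igraph::V(g)$name)
  sub <- igraph::induced_subgraph(g, present)
  if (!is.null(node_attrs)) {
    stopifnot("node" %in% names(node_attrs))
    idx <- match(igraph::V(sub)$name, node_attrs$node)
    for (col in setdiff(names(node_attrs), "node")) {
      sub <- igraph::set_vertex_attr(sub, col, value = node_attrs[[col]][idx])
    }
  }
  sub
}

#' Export a subnetwork as Cytoscape-importable tables
#'
#' Writes `<prefix>_edges.tsv` (two columns, tab-separated) and
#' `<prefix>_nodes.tsv` (node name plus any vertex attributes).
#'
#' @param sub an igraph graph, typically from [subnetwork()].
#' @param prefix output path prefix.
#' @return Invisibly, the two file paths.
#' @export
export_subnetwork <- function(sub, prefix) {
  edge_path <- paste0(prefix, "_edges.tsv")
  node_path <- paste0(prefix, "_nodes.tsv")
  el <- igraph::as_edgelist(sub)
  utils::write.table(
    data.frame(node_a = el[, 1], node_b = el[, 2]), edge_path,
    sep = "\t", quote = FALSE, row.names = FALSE)
  nodes <- data.frame(node = igraph::V(sub)$name, stringsAsFactors = FALSE)
  for (attr_name in setdiff(igraph::vertex_attr_names(sub), "name")) {
    nodes[[attr_name]] <- igraph::vertex_attr(sub, attr_name)
  }
  utils::write.table(nodes, node_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(edges = edge_path, nodes = node_path))
}

#' Compare a topology metric between two gene sets
#'
#' Two-sided Mann-Whitney rank-sum test on the per-node metric values of two
#' gene sets (e.g. genes mutated before vs after resistance). Genes absent
#' from the graph are dropped with a warning.
#'
#' @param g an igraph graph.
#' @param set_old,set_new character vectors of gene symbols.
#' @param metric one of `"degree"`, `"cc"`, `"k1"`, `"closeness"`.
#' @return List with `statistic`, `p_value`, `method`, per-set `n` and means.
#' @export
compare_group_metrics <- function(g, set_old, set_new,
                                  metric = c("degree", "cc", "k1",
                                             "closeness")) {
  metric <- match.arg(metric)
  keep <- function(s, label) {
    present <- intersect(s, igraph::V(g)$name)
    if (length(present) == 0) {
      stop("gene set '", label, "' has no members in the graph",
           call. = FALSE)
    }
    dropped <- setdiff(s, present)
    if (length(dropped) > 0) {
      warning("dropped ", length(dropped), " ", label,
              " gene(s) absent from the graph", call. = FALSE)
    }
    present
  }
  old_p <- keep(set_old, "old")
  new_p <- keep(set_new, "new")
  vals_old <- .metric_values(node_metrics(g, old_p), metric)
  vals_new <- .metric_values(node_metrics(g, new_p), metric)
  if (length(unique(c(vals_old, vals_new))) == 1) {
    return(list(statistic = length(vals_old) * length(vals_new) / 2,
                p_value = 1, method = "Mann-Whitney rank-sum (two-sided)",
                metric = metric, n_old = length(old_p), n_new = length(new_p),
                mean_old = mean(vals_old), mean_new = mean(vals_new)))
  }
  ht <- suppressWarnings(
    stats::wilcox.test(vals_old, vals_new, alternative = "two.sided"))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       method = "Mann-Whitney rank-sum (two-sided)", metric = metric,
       n_old = length(old_p), n_new = length(new_p),
       mean_old = mean(vals_old), mean_new = mean(vals_new))
}
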