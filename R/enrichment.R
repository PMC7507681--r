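GO_NAMESPACES <- c("biological_process", "molecular_function",
                   "cellular_component")
.GAF_ASPECT <- c(P = "biological_process", F = "molecular_function",
                 C = "cellular_component")

#' Construct an annotation map
#'
#' @param term_to_genes named list mapping term ids to non-empty character
#'   vectors of gene symbols.
#' @param term_names optional named character vector of human-readable term
#'   labels.
#' @param namespaces optional named character vector assigning each term to
#'   `biological_process`, `molecular_function`, or `cellular_component`
#'   (default `biological_process`).
#' @return Object of class `annotation_map`.
#' @export
annotation_map <- function(term_to_genes, term_names = NULL,
                           namespaces = NULL) {
  stopifnot(is.list(term_to_genes), !is.null(names(term_to_genes)))
  if (any(lengths(term_to_genes) == 0)) {
    stop("every term must annotate at least one gene", call. = FALSE)
  }
  term_to_genes <- lapply(term_to_genes, function(g) unique(as.character(g)))
  ids <- names(term_to_genes)
  if (is.null(term_names)) term_names <- stats::setNames(ids, ids)
  if (is.null(namespaces)) {
    namespaces <- stats::setNames(rep("biological_process", length(ids)), ids)
  }
  bad <- !namespaces %in% GO_NAMESPACES
  if (any(bad)) {
    stop("invalid namespace(s): ", paste(unique(namespaces[bad]),
                                         collapse = ", "), call. = FALSE)
  }
  structure(list(term_to_genes = term_to_genes,
                 term_names = term_names[ids],
                 namespaces = namespaces[ids]),
            class = "annotation_map")
}

#' @export
print.annotation_map <- function(x, ...) {
  cat("<annotation_map> ", length(x$term_to_genes), " term(s), ",
      length(unique(unlist(x$term_to_genes))), " annotated gene(s)\n",
      sep = "")
  invisible(x)
}

#' Read a gene-to-term annotation map
#'
#' Supports a two-column tab-separated (gene, term) file with an optional
#' tab-separated sidecar of term metadata (columns `term`, `name`,
#' `namespace`), or GAF 2.x, from which the object identifier (column 2), GO
#' id (column 5) and aspect (column 9, P/F/C) are used. Comment lines
#' starting with `!` are skipped. Format is inferred from the number of
#' columns unless given.
#'
#' @param path annotation file path.
#' @param term_meta optional path to the term-metadata sidecar (TSV format
#'   only).
#' @param format `"auto"`, `"tsv"`, or `"gaf"`.
#' @return An [annotation_map()].
#' @export
read_annotation_map <- function(path, term_meta = NULL,
                                format = c("auto", "tsv", "gaf")) {
  format <- match.arg(format)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "!")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (format == "auto") {
    format <- if (all(lengths(fields) >= 15)) "gaf" else "tsv"
  }
  if (format == "gaf") {
    gene <- vapply(fields, `[`, character(1), 2)
    term <- vapply(fields, `[`, character(1), 5)
    aspect <- vapply(fields, `[`, character(1), 9)
    ns <- unname(.GAF_ASPECT[aspect])
    ns[is.na(ns)] <- "biological_process"
  } else {
    bad <- which(lengths(fields) < 2)
    if (length(bad) > 0) {
      stop("malformed annotation line ", bad[1], ": expected 2 columns",
           call. = FALSE)
    }
    gene <- vapply(fields, `[`, character(1), 1)
    term <- vapply(fields, `[`, character(1), 2)
    # drop a header line if present
    if (length(gene) > 0 && tolower(gene[1]) == "gene") {
      gene <- gene[-1]; term <- term[-1]
    }
    ns <- NULL
  }
  t2g <- split(gene, term)
  namespaces <- if (!is.null(ns)) {
    vapply(split(ns, term), `[`, character(1), 1)
  } else NULL
  term_names <- NULL
  if (!is.null(term_meta)) {
    meta <- utils::read.delim(term_meta, stringsAsFactors = FALSE)
    term_names <- stats::setNames(meta$name, meta$term)[names(t2g)]
    names(term_names) <- names(t2g)
    if ("namespace" %in% names(meta)) {
      namespaces <- stats::setNames(meta$namespace, meta$term)[names(t2g)]
      names(namespaces) <- names(t2g)
    }
  }
  annotation_map(t2g, term_names = term_names, namespaces = namespaces)
}

#' Hypergeometric upper-tail probability
#'
#' Probability of observing at least `k` annotated genes when drawing `n`
#' genes from a background of `N` of which `K` are annotated:
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`. Computed via the log-space
#' hypergeometric tail, so small p-values do not underflow.
#'
#' @param k observed overlap (query and term), `0 <= k <= min(K, n)`.
#' @param K annotated genes in the background.
#' @param n query size within the background.
#' @param N background size.
#' @return Upper-tail probability; 1 when `k = 0`.
#' @examples
#' hypergeometric_upper_tail(5, 5, 5, 10) # 1 / choose(10, 5)
#' @export
hypergeometric_upper_tail <- function(k, K, n, N) {
  ok <- k >= 0 & K >= 0 & n >= 0 & N >= 0 & K <= N & n <= N & k <= pmin(K, n)
  if (!all(ok)) {
    stop("inconsistent hypergeometric counts: need 0 <= k <= min(K, n) and ",
         "K, n <= N", call. = FALSE)
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values, capped at 1, returned in the input order.
#'
#' @param p_values numeric vector of raw p-values in (0, 1].
#' @return Adjusted p-values, each at least the corresponding raw value.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values <= 0 | p_values > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Hypergeometric term enrichment against a background
#'
#' Tests each annotated term for over-representation in a query gene set
#' relative to a background (here, typically all genes of the network giant
#' component rather than the genome). Query genes outside the background are
#' dropped with a message. Only terms with at least one background gene and
#' at least one query gene are tested; FDR correction is applied separately
#' within each namespace (mirroring standard GO practice of treating the
#' three ontologies as independent families), or pooled across all terms
#' with `by_namespace = FALSE`.
#'
#' @param query character vector of gene symbols.
#' @param annotations an [annotation_map()].
#' @param background character vector of background gene symbols.
#' @param alpha report only terms with corrected p below this threshold
#'   (default 0.001, a stringent cut; use `alpha = 1` to keep all tested
#'   terms).
#' @param by_namespace correct within namespaces (default `TRUE`).
#' @return data.frame sorted by ascending corrected p with columns `term`,
#'   `name`, `namespace`, `k`, `K`, `n`, `N`, `p_raw`, `p_corrected`. The
#'   attribute `n_tested` records how many terms entered the correction.
#' @export
enrich <- function(query, annotations, background, alpha = 0.001,
                   by_namespace = TRUE) {
  stopifnot(inherits(annotations, "annotation_map"))
  background <- unique(as.character(background))
  if (length(background) == 0) stop("background is empty", call. = FALSE)
  query_in <- intersect(unique(as.character(query)), background)
  n_dropped <- length(unique(query)) - length(query_in)
  if (n_dropped > 0) {
    message("enrich: dropped ", n_dropped,
            " query gene(s) outside the background")
  }
  if (length(query_in) == 0) {
    stop("query has no genes in the background", call. = FALSE)
  }
  N <- length(background)
  n <- length(query_in)
  rows <- lapply(names(annotations$term_to_genes), function(tid) {
    genes <- intersect(annotations$term_to_genes[[tid]], background)
    K <- length(genes)
    k <- length(intersect(genes, query_in))
    if (K < 1 || k < 1) return(NULL)
    data.frame(term = tid,
               name = unname(annotations$term_names[[tid]]),
               namespace = unname(annotations$namespaces[[tid]]),
               k = k, K = K, n = n, N = N,
               p_raw = hypergeometric_upper_tail(k, K, n, N),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    res <- data.frame(term = character(0), name = character(0),
                      namespace = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p_raw = numeric(0),
                      p_corrected = numeric(0), stringsAsFactors = FALSE)
    attr(res, "n_tested") <- 0L
    return(res)
  }
  res <- do.call(rbind, rows)
  if (by_namespace) {
    res$p_corrected <- NA_real_
    for (ns in unique(res$namespace)) {
      sel <- res$namespace == ns
      res$p_corrected[sel] <- bh_fdr(res$p_raw[sel])
    }
  } else {
    res$p_corrected <- bh_fdr(res$p_raw)
  }
  n_tested <- nrow(res)
  # alpha = 1 disables filtering (adjusted p-values can equal 1 exactly)
  keep <- if (alpha >= 1) rep(TRUE, nrow(res)) else res$p_corrected < alpha
  res <- res[keep, , drop = FALSE]
  res <- res[order(res$p_corrected, res$p_raw), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_tested") <- n_tested
  res
}
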