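SIGNIFICANCE_CLASSES <- c("clinical", "potential", "confirmed_somatic", "unknown")

#' Construct a mutation catalog
#'
#' A mutation catalog holds one somatic alteration per assay with its read
#' support: gene symbol, cDNA change (the identity key together with the
#' gene), optional amino-acid annotation, mutant read count, total coverage,
#' and variant allele frequency (VAF). Fusion calls may carry missing read
#' counts; for all other records the stated VAF is cross-checked against
#' `mutant_reads / coverage`.
#'
#' @param records data.frame with columns `gene`, `cdna_change`, `aa_change`,
#'   `assay_id`, `mutant_reads`, `coverage`, `vaf`, and optionally
#'   `significance_class` (one of clinical, potential, confirmed_somatic,
#'   unknown; defaults to unknown).
#' @param assay_ids ordered character vector of assay labels; defaults to the
#'   order of first appearance in `records`.
#' @param vaf_tolerance maximum allowed absolute difference between the stated
#'   VAF and `mutant_reads / coverage`. Default 0.006: published tables round
#'   VAF to two decimals and occasionally one count in the last place off, so
#'   half a rounding unit (0.005) plus a one-in-the-last-digit allowance is
#'   needed for real printed tables to validate.
#' @return An object of class `mutation_catalog`: the validated records
#'   data.frame with an `assay_ids` attribute.
#' @export
mutation_catalog <- function(records, assay_ids = NULL, vaf_tolerance = 0.006) {
  required <- c("gene", "cdna_change", "assay_id")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    stop("mutation table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  for (col in c("aa_change", "significance_class")) {
    if (!col %in% names(records)) {
      records[[col]] <- rep(NA_character_, nrow(records))
    }
  }
  for (col in c("mutant_reads", "coverage", "vaf")) {
    if (!col %in% names(records)) records[[col]] <- rep(NA_real_, nrow(records))
  }
  records$gene <- as.character(records$gene)
  records$cdna_change <- as.character(records$cdna_change)
  records$aa_change <- as.character(records$aa_change)
  records$assay_id <- as.character(records$assay_id)
  records$mutant_reads <- as.numeric(records$mutant_reads)
  records$coverage <- as.numeric(records$coverage)
  records$vaf <- as.numeric(records$vaf)
  records$significance_class[is.na(records$significance_class)] <- "unknown"

  bad_class <- !records$significance_class %in% SIGNIFICANCE_CLASSES
  if (any(bad_class)) {
    stop("unknown significance_class at row(s) ",
         paste(which(bad_class), collapse = ", "), ": expected one of ",
         paste(SIGNIFICANCE_CLASSES, collapse = ", "), call. = FALSE)
  }
  if (anyNA(records$gene) || anyNA(records$cdna_change) ||
      anyNA(records$assay_id)) {
    stop("gene, cdna_change and assay_id must be non-missing for every record",
         call. = FALSE)
  }

  has_reads <- !is.na(records$mutant_reads) & !is.na(records$coverage)
  bad_cov <- has_reads & records$coverage <= 0
  if (any(bad_cov)) {
    stop("coverage must be positive; violated at row(s) ",
         paste(which(bad_cov), collapse = ", "), call. = FALSE)
  }
  bad_reads <- has_reads &
    (records$mutant_reads < 0 | records$mutant_reads > records$coverage)
  if (any(bad_reads)) {
    stop("mutant_reads must lie in [0, coverage]; violated at row(s) ",
         paste(which(bad_reads), collapse = ", "), call. = FALSE)
  }
  check <- has_reads & !is.na(records$vaf)
  if (any(check)) {
    recomputed <- records$mutant_reads[check] / records$coverage[check]
    off <- abs(recomputed - records$vaf[check]) > vaf_tolerance
    if (any(off)) {
      stop("stated VAF disagrees with mutant_reads/coverage beyond tolerance ",
           vaf_tolerance, " at row(s) ",
           paste(which(check)[off], collapse = ", "), call. = FALSE)
    }
  }

  key <- paste(records$gene, records$cdna_change, records$assay_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)]
    stop("duplicate (gene, cdna_change, assay) record(s): ",
         paste(gsub("\r", " / ", unique(dup)), collapse = "; "),
         call. = FALSE)
  }

  if (is.null(assay_ids)) {
    assay_ids <- unique(records$assay_id)
  } else {
    stray <- setdiff(records$assay_id, assay_ids)
    if (length(stray) > 0) {
      stop("records reference assay(s) not in assay_ids: ",
           paste(stray, collapse = ", "), call. = FALSE)
    }
  }
  rownames(records) <- NULL
  structure(records, assay_ids = as.character(assay_ids),
            class = c("mutation_catalog", "data.frame"))
}

#' @export
print.mutation_catalog <- function(x, ...) {
  cat("<mutation_catalog> ", nrow(x), " record(s) across ",
      length(attr(x, "assay_ids")), " assay(s): ",
      paste(attr(x, "assay_ids"), collapse = ", "), "\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("... ", nrow(x) - 10, " more row(s)\n", sep = "")
  invisible(x)
}

#' Parse a two-timepoint mutation table
#'
#' Reads a tab-separated long-format mutation table (columns `gene`,
#' `cdna_change`, `aa_change`, `assay_id`, `mutant_reads`, `coverage`, `vaf`,
#' `significance_class`; `NA` marks values absent in an assay, e.g. read
#' counts of a fusion call) and validates it into a [mutation_catalog()].
#'
#' The packaged fixture `pazopanib_case_mutations.tsv` (see
#' `system.file("extdata", "pazopanib_case_mutations.tsv", package =
#' "resistnet")`) transcribes the somatic catalog of a bladder-cancer case
#' profiled by a 365-gene panel and WES at the pazopanib-naive baseline
#' ("Panel1", "WES1") and by WES again after acquired pazopanib resistance
#' ("WES2").
#'
#' @param path path to the tab-separated table.
#' @param assay_ids optional ordered character vector restricting/ordering the
#'   assay labels.
#' @inheritParams mutation_catalog
#' @return A [mutation_catalog()].
#' @examples
#' path <- system.file("extdata", "pazopanib_case_mutations.tsv",
#'                     package = "resistnet")
#' cat1 <- parse_mutation_table(path)
#' count_mutations_genes(cat1, "WES1")
#' @export
parse_mutation_table <- function(path, assay_ids = NULL,
                                 vaf_tolerance = 0.006) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (length(lines) == 0) stop("empty file (no header): ", path, call. = FALSE)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  n_fields <- length(header)
  body <- lines[-1]
  body <- body[nzchar(body)]
  fields <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != n_fields)
  if (length(bad) > 0) {
    stop("malformed row at line ", bad[1] + 1L, " of ", path, ": expected ",
         n_fields, " tab-separated fields, found ", lengths(fields)[bad[1]],
         call. = FALSE)
  }
  if (length(body) == 0) {
    records <- as.data.frame(
      stats::setNames(rep(list(character(0)), n_fields), header),
      stringsAsFactors = FALSE)
  } else {
    m <- do.call(rbind, fields)
    records <- as.data.frame(m, stringsAsFactors = FALSE)
    names(records) <- header
    records[records == "NA"] <- NA
  }
  mutation_catalog(records, assay_ids = assay_ids,
                   vaf_tolerance = vaf_tolerance)
}

#' Restrict a catalog to one assay
#'
#' @param catalog a [mutation_catalog()].
#' @param assay_id one assay label present in the catalog.
#' @return A single-assay `mutation_catalog`.
#' @export
assay_slice <- function(catalog, assay_id) {
  stopifnot(inherits(catalog, "mutation_catalog"))
  if (!assay_id %in% attr(catalog, "assay_ids")) {
    stop("unknown assay_id: ", assay_id, call. = FALSE)
  }
  rec <- as.data.frame(catalog)[catalog$assay_id == assay_id, , drop = FALSE]
  mutation_catalog(rec, assay_ids = assay_id)
}

#' Variant allele frequency from read counts
#'
#' VAF is the mutant read count divided by total coverage at the position.
#' The exact fraction is returned; rounding to two decimals happens only at
#' reporting time (see [summarize_vaf()]).
#'
#' @param mutant_reads non-negative integer vector.
#' @param coverage positive integer vector.
#' @return Numeric vector of fractions in \[0, 1\].
#' @examples
#' compute_vaf(137, 143) # 0.958..., reported as 0.96
#' @export
compute_vaf <- function(mutant_reads, coverage) {
  if (any(coverage <= 0, na.rm = TRUE)) {
    stop("coverage must be positive", call. = FALSE)
  }
  if (any(mutant_reads < 0, na.rm = TRUE) ||
      any(mutant_reads > coverage, na.rm = TRUE)) {
    stop("mutant_reads must lie in [0, coverage]", call. = FALSE)
  }
  mutant_reads / coverage
}

.mutation_keys <- function(slice) {
  data.frame(gene = slice$gene, cdna_change = slice$cdna_change,
             aa_change = slice$aa_change, stringsAsFactors = FALSE)
}

#' Classify mutations as persisting, new, or lost between two timepoints
#'
#' Compares the single-assay pre- and post-resistance views of a catalog.
#' Records are matched in two passes: first on exact (gene, cDNA change),
#' then unmatched records are reconciled on (gene, amino-acid change) when
#' both annotations are present. The second pass absorbs assay-specific
#' transcript numbering, where the same protein change is reported under
#' different cDNA coordinates by different pipelines; without it such calls
#' would be double-counted as one loss plus one gain.
#'
#' @param pre,post single-assay [mutation_catalog()] slices
#'   (see [assay_slice()]).
#' @return An object of class `cohort_comparison` with elements
#'   `persisting` (data.frame of matched pre/post key pairs and the matching
#'   pass that joined them), `new` (post-only keys), `lost` (pre-only keys),
#'   and `pre_assay` / `post_assay` labels. `persisting`/`lost` partition the
#'   pre keys; `persisting`/`new` partition the post keys.
#' @export
classify_mutations <- function(pre, post) {
  stopifnot(inherits(pre, "mutation_catalog"),
            inherits(post, "mutation_catalog"))
  if (length(attr(pre, "assay_ids")) != 1 ||
      length(attr(post, "assay_ids")) != 1) {
    stop("classify_mutations() expects single-assay slices; use assay_slice()",
         call. = FALSE)
  }
  pre_keys <- .mutation_keys(pre)
  post_keys <- .mutation_keys(post)
  pre_keys$.matched <- rep(FALSE, nrow(pre_keys))
  post_keys$.matched <- rep(FALSE, nrow(post_keys))

  pairs <- list()
  # pass 1: exact cDNA identity
  for (i in seq_len(nrow(pre_keys))) {
    j <- which(!post_keys$.matched &
                 post_keys$gene == pre_keys$gene[i] &
                 post_keys$cdna_change == pre_keys$cdna_change[i])
    if (length(j) > 0) {
      j <- j[1]
      pre_keys$.matched[i] <- TRUE
      post_keys$.matched[j] <- TRUE
      pairs[[length(pairs) + 1L]] <- data.frame(
        gene = pre_keys$gene[i],
        cdna_pre = pre_keys$cdna_change[i], cdna_post = post_keys$cdna_change[j],
        aa_pre = pre_keys$aa_change[i], aa_post = post_keys$aa_change[j],
        matched_on = "cdna", stringsAsFactors = FALSE)
    }
  }
  # pass 2: amino-acid rescue for unmatched records of the same gene
  for (i in which(!pre_keys$.matched)) {
    if (is.na(pre_keys$aa_change[i])) next
    j <- which(!post_keys$.matched &
                 post_keys$gene == pre_keys$gene[i] &
                 !is.na(post_keys$aa_change) &
                 post_keys$aa_change == pre_keys$aa_change[i])
    if (length(j) > 0) {
      j <- j[1]
      pre_keys$.matched[i] <- TRUE
      post_keys$.matched[j] <- TRUE
      pairs[[length(pairs) + 1L]] <- data.frame(
        gene = pre_keys$gene[i],
        cdna_pre = pre_keys$cdna_change[i], cdna_post = post_keys$cdna_change[j],
        aa_pre = pre_keys$aa_change[i], aa_post = post_keys$aa_change[j],
        matched_on = "aa", stringsAsFactors = FALSE)
    }
  }

  persisting <- if (length(pairs) > 0) do.call(rbind, pairs) else
    data.frame(gene = character(0), cdna_pre = character(0),
               cdna_post = character(0), aa_pre = character(0),
               aa_post = character(0), matched_on = character(0),
               stringsAsFactors = FALSE)
  lost <- pre_keys[!pre_keys$.matched, c("gene", "cdna_change", "aa_change")]
  new <- post_keys[!post_keys$.matched, c("gene", "cdna_change", "aa_change")]
  rownames(lost) <- rownames(new) <- NULL
  structure(list(persisting = persisting, new = new, lost = lost,
                 pre_assay = attr(pre, "assay_ids"),
                 post_assay = attr(post, "assay_ids")),
            class = "cohort_comparison")
}

#' @export
print.cohort_comparison <- function(x, ...) {
  cat("<cohort_comparison> ", x$pre_assay, " vs ", x$post_assay, ": ",
      nrow(x$persisting), " persisting, ", nrow(x$new), " new, ",
      nrow(x$lost), " lost\n", sep = "")
  invisible(x)
}

#' Summarize VAFs of a mutation set
#'
#' Recomputes each record's VAF from read counts (falling back to the stated
#' value when counts are unavailable), rounds to two decimals to match the
#' reporting precision of clinical sequencing tables, and reports the median
#' together with the count and fraction at or above a clonality threshold.
#' The threshold is inclusive (`vaf >= threshold`), so a mutation reported at
#' exactly the threshold counts as above it.
#'
#' @param keys data.frame with columns `gene` and `cdna_change` naming the
#'   mutations to summarize; all must be present in `slice`.
#' @param slice single-assay [mutation_catalog()] supplying the VAFs.
#' @param threshold clonality threshold on the rounded VAF (default 0.10).
#' @return List of class `vaf_summary`: `n`, `median_vaf` (`NA` when `n` is
#'   0), `threshold`, `n_above`, `fraction_above`, `vafs`.
#' @export
summarize_vaf <- function(keys, slice, threshold = 0.10) {
  stopifnot(inherits(slice, "mutation_catalog"))
  if (length(attr(slice, "assay_ids")) != 1) {
    stop("summarize_vaf() expects a single-assay slice", call. = FALSE)
  }
  keys <- as.data.frame(keys, stringsAsFactors = FALSE)
  if (nrow(keys) == 0) {
    return(structure(list(n = 0L, median_vaf = NA_real_, threshold = threshold,
                          n_above = 0L, fraction_above = NA_real_,
                          vafs = numeric(0)),
                     class = "vaf_summary"))
  }
  idx <- match(paste(keys$gene, keys$cdna_change, sep = "\r"),
               paste(slice$gene, slice$cdna_change, sep = "\r"))
  if (anyNA(idx)) {
    miss <- which(is.na(idx))
    stop("key(s) absent from assay ", attr(slice, "assay_ids"), ": ",
         paste(keys$gene[miss], keys$cdna_change[miss], collapse = "; "),
         call. = FALSE)
  }
  raw <- ifelse(!is.na(slice$mutant_reads[idx]) & !is.na(slice$coverage[idx]),
                slice$mutant_reads[idx] / slice$coverage[idx],
                slice$vaf[idx])
  vafs <- round(raw, 2)
  n_above <- sum(vafs >= threshold, na.rm = TRUE)
  structure(list(n = nrow(keys),
                 median_vaf = stats::median(vafs, na.rm = TRUE),
                 threshold = threshold, n_above = as.integer(n_above),
                 fraction_above = n_above / nrow(keys), vafs = vafs),
            class = "vaf_summary")
}

#' @export
print.vaf_summary <- function(x, ...) {
  cat("<vaf_summary> n = ", x$n, ", median VAF = ",
      formatC(x$median_vaf, format = "fg"), ", ", x$n_above, "/", x$n,
      " (", formatC(100 * x$fraction_above, format = "f", digits = 1),
      "%) at VAF >= ", x$threshold, "\n", sep = "")
  invisible(x)
}

#' Count distinct mutations and mutated genes in one assay
#'
#' Mutations are distinct (gene, cDNA change) pairs; fusions count as a
#' single mutation in a single gene.
#'
#' @param catalog a [mutation_catalog()].
#' @param assay_id assay label present in the catalog.
#' @return Named integer vector `c(n_mutations, n_genes)`.
#' @export
count_mutations_genes <- function(catalog, assay_id) {
  slice <- assay_slice(catalog, assay_id)
  c(n_mutations = length(unique(paste(slice$gene, slice$cdna_change,
                                      sep = "\r"))),
    n_genes = length(unique(slice$gene)))
}

#' Compare two VAF distributions
#'
#' Default test is the two-sided Mann-Whitney rank-sum test (Wilcoxon
#' rank-sum) with the usual tie handling; a Welch t-test is available as an
#' alternative. The test choice is recorded in the result.
#'
#' @param vafs_a,vafs_b non-empty numeric vectors of VAFs.
#' @param method `"wilcoxon"` (default) or `"t"`.
#' @return List with `statistic`, `p_value`, `method`, `n_a`, `n_b`.
#' @export
compare_vaf_distributions <- function(vafs_a, vafs_b,
                                      method = c("wilcoxon", "t")) {
  method <- match.arg(method)
  if (length(vafs_a) == 0 || length(vafs_b) == 0) {
    stop("both VAF vectors must be non-empty", call. = FALSE)
  }
  if (method == "wilcoxon") {
    if (length(unique(c(vafs_a, vafs_b))) == 1) {
      # constant data: no evidence of a shift; the rank test is degenerate
      return(list(statistic = length(vafs_a) * length(vafs_b) / 2,
                  p_value = 1, method = "Mann-Whitney rank-sum (two-sided)",
                  n_a = length(vafs_a), n_b = length(vafs_b)))
    }
    ht <- suppressWarnings(
      stats::wilcox.test(vafs_a, vafs_b, alternative = "two.sided"))
    label <- "Mann-Whitney rank-sum (two-sided)"
  } else {
    ht <- stats::t.test(vafs_a, vafs_b, alternative = "two.sided")
    label <- "Welch t-test (two-sided)"
  }
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       method = label, n_a = length(vafs_a), n_b = length(vafs_b))
}

#' VAF summaries for the persisting and new mutation classes
#'
#' Convenience wrapper: takes a [classify_mutations()] result and the
#' post-timepoint slice and returns the two [summarize_vaf()] summaries used
#' to contrast clonal persisting mutations with subclonal new ones, plus the
#' rank-test comparison of their VAFs.
#'
#' @param comparison a `cohort_comparison`.
#' @param post_slice the single-assay post-timepoint slice.
#' @param threshold clonality threshold, default 0.10.
#' @return List with `persisting` and `new` [summarize_vaf()] objects and
#'   `test` from [compare_vaf_distributions()].
#' @export
cohort_vaf_summary <- function(comparison, post_slice, threshold = 0.10) {
  stopifnot(inherits(comparison, "cohort_comparison"))
  pers_keys <- data.frame(gene = comparison$persisting$gene,
                          cdna_change = comparison$persisting$cdna_post,
                          stringsAsFactors = FALSE)
  pers <- summarize_vaf(pers_keys, post_slice, threshold)
  new <- summarize_vaf(comparison$new, post_slice, threshold)
  test <- if (pers$n > 0 && new$n > 0) {
    compare_vaf_distributions(pers$vafs, new$vafs)
  } else NULL
  list(persisting = pers, new = new, test = test)
}
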