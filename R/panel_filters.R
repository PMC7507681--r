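#' Filter somatic variant candidates by read support
#'
#' Ultra-deep panel post-processing: a reliable somatic call requires at
#' least `min_reads` mutant reads and a variant allele frequency of at least
#' `min_vaf` (both thresholds inclusive, so a candidate at exactly 5 reads
#' and 1% VAF is kept). Rejected candidates and their reasons are attached as
#' the `rejected` attribute.
#'
#' @param candidates data.frame with at least `mutant_reads` and `vaf`
#'   columns.
#' @param min_reads minimum mutant read count (default 5).
#' @param min_vaf minimum VAF (default 0.01).
#' @return The retained rows; idempotent.
#' @export
filter_somatic_candidates <- function(candidates, min_reads = 5,
                                      min_vaf = 0.01) {
  if (nrow(candidates) == 0) return(candidates)
  low_reads <- candidates$mutant_reads < min_reads
  low_vaf <- candidates$vaf < min_vaf
  keep <- !low_reads & !low_vaf
  rejected <- candidates[!keep, , drop = FALSE]
  if (nrow(rejected) > 0) {
    rejected$reason <- paste0(
      ifelse(low_reads[!keep], paste0("mutant_reads<", min_reads), ""),
      ifelse(low_reads[!keep] & low_vaf[!keep], ";", ""),
      ifelse(low_vaf[!keep], paste0("vaf<", min_vaf), ""))
    message("filter_somatic_candidates: rejected ", nrow(rejected),
            " of ", nrow(candidates), " candidate(s)")
  }
  out <- candidates[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  out
}

#' Classify a copy-number call
#'
#' Focal amplification at 4 or more copies (inclusive), homozygous deletion
#' at exactly 0 copies, neutral otherwise.
#'
#' @param copy_number non-negative numeric vector of estimated copies.
#' @return Character vector among `"amplification"`, `"homozygous_deletion"`,
#'   `"neutral"`.
#' @export
classify_cnv <- function(copy_number) {
  if (any(copy_number < 0, na.rm = TRUE)) {
    stop("copy_number must be non-negative", call. = FALSE)
  }
  ifelse(copy_number >= 4, "amplification",
         ifelse(copy_number == 0, "homozygous_deletion", "neutral"))
}

#' Tumor/normal depth log-ratio
#'
#' `log2(tumor_depth / normal_depth)`, by default median-centered across the
#' supplied regions so that a predominantly diploid panel sits at 0 and focal
#' gains/losses stand out (set `center = FALSE` for the raw ratio).
#'
#' @param tumor_depth,normal_depth positive numeric vectors (parallel
#'   regions).
#' @param center subtract the median log-ratio across regions (default
#'   `TRUE`).
#' @return Numeric vector of (centered) log2 ratios.
#' @export
compute_log_ratio <- function(tumor_depth, normal_depth, center = TRUE) {
  if (any(tumor_depth <= 0) || any(normal_depth <= 0)) {
    stop("depths must be positive", call. = FALSE)
  }
  lr <- log2(tumor_depth / normal_depth)
  if (center) lr - stats::median(lr) else lr
}

#' Collect discordant read pairs
#'
#' A read pair is discordant — candidate evidence for a rearrangement — when
#' its insert size is abnormal: strictly greater than `max_insert` base
#' pairs, or exactly zero (the unmapped-mate convention).
#'
#' @param read_pairs data.frame with at least an `insert_size` column (and
#'   typically `chrom`, `pos1`, `pos2`).
#' @param max_insert largest normal insert size (default 2000; the threshold
#'   is exclusive, so 2000 itself is concordant).
#' @return The discordant rows; idempotent.
#' @export
collect_discordant <- function(read_pairs, max_insert = 2000) {
  if (nrow(read_pairs) == 0) return(read_pairs)
  keep <- read_pairs$insert_size > max_insert | read_pairs$insert_size == 0
  out <- read_pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a read-pair table
#'
#' Tab-separated columns `chrom`, `pos1`, `pos2`, `insert_size` (header
#' required). `insert_size` 0 marks an unmapped mate.
#'
#' @param path file path.
#' @return data.frame of read pairs.
#' @export
read_read_pairs <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("chrom", "pos1", "pos2", "insert_size")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("read-pair table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(df$pos1 <= 0 | df$pos2 <= 0)) {
    stop("read positions must be positive 1-based coordinates", call. = FALSE)
  }
  df
}

#' Cluster discordant reads into candidate breakpoints
#'
#' Single-linkage clustering of discordant read positions per chromosome:
#' reads are placed at their leftmost mapped coordinate, sorted, and
#' consecutive reads closer than `max_gap` base pairs (strict) join one
#' cluster. Clusters with fewer than `min_cluster_size` reads are discarded —
#' a single discordant pair never forms a reported breakpoint. The result is
#' independent of input order.
#'
#' @param discordant data.frame with columns `chrom`, `pos1`, `pos2` (see
#'   [collect_discordant()]).
#' @param max_gap clustering distance in bp (default 500, strict `<`).
#' @param min_cluster_size smallest reported cluster (default 2).
#' @return data.frame of class `breakpoint_clusters` with columns `chrom`,
#'   `start`, `end` (closed interval of member positions), `n_reads`.
#' @export
cluster_discordant <- function(discordant, max_gap = 500,
                               min_cluster_size = 2) {
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), n_reads = integer(0),
                      stringsAsFactors = FALSE)
  if (nrow(discordant) == 0) return(empty)
  pos <- pmin(discordant$pos1, discordant$pos2)
  out <- lapply(split(pos, discordant$chrom), function(p) {
    p <- sort(p)
    cluster_id <- cumsum(c(1, diff(p) >= max_gap))
    sizes <- table(cluster_id)
    keep <- names(sizes)[sizes >= min_cluster_size]
    if (length(keep) == 0) return(NULL)
    do.call(rbind, lapply(keep, function(cid) {
      members <- p[cluster_id == as.integer(cid)]
      data.frame(start = min(members), end = max(members),
                 n_reads = length(members), stringsAsFactors = FALSE)
    }))
  })
  chroms <- names(out)[!vapply(out, is.null, logical(1))]
  out <- out[chroms]
  if (length(out) == 0) return(empty)
  res <- do.call(rbind, Map(function(chrom, df) {
    cbind(data.frame(chrom = rep(chrom, nrow(df)), stringsAsFactors = FALSE),
          df)
  }, chroms, out))
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Tumor mutational burden
#'
#' Somatic coding mutations per megabase of examined sequence. Eligible
#' mutations are coding, not known driver mutations, and not known germline
#' variants in dbSNP.
#'
#' @param candidates data.frame with logical columns `is_coding`,
#'   `is_driver`, `in_dbsnp_germline`.
#' @param region_mb examined region size in megabases (positive; a
#'   whole-exome capture is about 50 Mb).
#' @return List of class `tmb_estimate`: `n_eligible`, `region_mb`, `tmb`
#'   (mutations per megabase).
#' @export
compute_tmb <- function(candidates, region_mb) {
  if (!is.numeric(region_mb) || length(region_mb) != 1 || region_mb <= 0) {
    stop("region_mb must be a single positive number", call. = FALSE)
  }
  n_eligible <- if (nrow(candidates) == 0) 0L else
    sum(candidates$is_coding & !candidates$is_driver &
          !candidates$in_dbsnp_germline)
  structure(list(n_eligible = as.integer(n_eligible), region_mb = region_mb,
                 tmb = n_eligible / region_mb),
            class = "tmb_estimate")
}

#' @export
print.tmb_estimate <- function(x, ...) {
  cat("<tmb_estimate> ", x$n_eligible, " eligible mutation(s) over ",
      x$region_mb, " Mb = ", formatC(x$tmb, format = "fg"), " mut/Mb\n",
      sep = "")
  invisible(x)
}
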