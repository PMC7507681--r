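#' Caliper tumor volume
#'
#' `volume = length * width^2 / 2`, with length the longest axis. If a width
#' larger than its length is supplied the two are swapped with a warning.
#'
#' @param length,width caliper measurements in mm (non-negative).
#' @return Volume in cubic millimeters.
#' @examples
#' tumor_volume(10, 10) # 500
#' tumor_volume(12, 8)  # 384
#' @export
tumor_volume <- function(length, width) {
  if (any(length < 0, na.rm = TRUE) || any(width < 0, na.rm = TRUE)) {
    stop("length and width must be non-negative", call. = FALSE)
  }
  swapped <- !is.na(length) & !is.na(width) & width > length
  if (any(swapped)) {
    warning("width exceeded length for ", sum(swapped),
            " measurement(s); axes swapped", call. = FALSE)
    tmp <- length[swapped]
    length[swapped] <- width[swapped]
    width[swapped] <- tmp
  }
  length * width^2 / 2
}

#' Read a long-format PDX growth table
#'
#' Tab-separated columns `group`, `animal`, `day`, `length_mm`, `width_mm`,
#' `body_weight_g`. Tumor volumes are computed from the caliper measurements
#' and days must be strictly increasing within each animal.
#'
#' @param path file path.
#' @return data.frame of class `growth_data` with an added `volume_mm3`
#'   column.
#' @export
read_growth_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  growth_data(df)
}

#' Validate a growth measurement table
#'
#' @param df data.frame with columns `group`, `animal`, `day`, `length_mm`,
#'   `width_mm`, `body_weight_g` (and optionally a precomputed `volume_mm3`,
#'   which is checked against the caliper formula to within 1e-9).
#' @return The validated data.frame of class `growth_data`.
#' @export
growth_data <- function(df) {
  required <- c("group", "animal", "day", "length_mm", "width_mm",
                "body_weight_g")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("growth table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  vol <- tumor_volume(df$length_mm, df$width_mm)
  if ("volume_mm3" %in% names(df)) {
    if (any(abs(df$volume_mm3 - vol) > 1e-9, na.rm = TRUE)) {
      stop("volume_mm3 disagrees with length * width^2 / 2", call. = FALSE)
    }
  }
  df$volume_mm3 <- vol
  by_animal <- split(df$day, paste(df$group, df$animal, sep = "/"))
  bad <- names(by_animal)[vapply(by_animal, function(d) any(diff(d) <= 0),
                                 logical(1))]
  if (length(bad) > 0) {
    stop("days must be strictly increasing within animal ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  class(df) <- c("growth_data", "data.frame")
  df
}

.group_median_volume <- function(growth, group, day) {
  sel <- growth$group == group & growth$day == day
  if (!any(sel)) {
    stop("group '", group, "' has no measurement at day ", day,
         call. = FALSE)
  }
  stats::median(growth$volume_mm3[sel])
}

#' Percent tumor growth inhibition
#'
#' `TGI (%) = (1 - (Tt - T0) / (Ct - C0)) * 100`, where `Tt`/`T0` are the
#' treatment group's median tumor volumes at day `t` / day 0 and `Ct`/`C0`
#' the control group's. Group medians (not means) enter the formula. A TGI
#' above 50% is flagged as meaningful; static treated tumors give 100% and
#' regressing ones exceed 100%.
#'
#' @param growth a [growth_data()] table.
#' @param treatment,control group labels.
#' @param day evaluation day; defaults to the last day measured in both
#'   groups.
#' @param baseline_day day-0 label (default 0).
#' @param meaningful_threshold TGI percent above which the effect is flagged
#'   (default 50).
#' @return List of class `tgi_result`: `group`, `day`, `t0_volume`,
#'   `tt_volume`, `c0_volume`, `ct_volume`, `tgi_percent`, `meaningful`.
#' @export
tgi <- function(growth, treatment, control, day = NULL, baseline_day = 0,
                meaningful_threshold = 50) {
  stopifnot(inherits(growth, "growth_data"))
  if (is.null(day)) {
    day <- max(intersect(growth$day[growth$group == treatment],
                         growth$day[growth$group == control]))
  }
  t0 <- .group_median_volume(growth, treatment, baseline_day)
  tt <- .group_median_volume(growth, treatment, day)
  c0 <- .group_median_volume(growth, control, baseline_day)
  ct <- .group_median_volume(growth, control, day)
  if (ct == c0) {
    stop("degenerate control: median control volume did not change between ",
         "day ", baseline_day, " and day ", day, call. = FALSE)
  }
  tgi_percent <- (1 - (tt - t0) / (ct - c0)) * 100
  structure(list(group = treatment, day = day, t0_volume = t0,
                 tt_volume = tt, c0_volume = c0, ct_volume = ct,
                 tgi_percent = tgi_percent,
                 meaningful = tgi_percent > meaningful_threshold),
            class = "tgi_result")
}

#' @export
print.tgi_result <- function(x, ...) {
  cat("<tgi_result> ", x$group, " day ", x$day, ": TGI = ",
      formatC(x$tgi_percent, format = "f", digits = 1), "%",
      if (x$meaningful) " (meaningful, > 50%)", "\n", sep = "")
  invisible(x)
}

#' TGI table for all treatment groups against a control
#'
#' @inheritParams tgi
#' @param control control (vehicle) group label.
#' @return data.frame with one row per non-control group: volumes, TGI
#'   percent, and the meaningful flag.
#' @export
tgi_table <- function(growth, control = "vehicle", day = NULL,
                      baseline_day = 0, meaningful_threshold = 50) {
  groups <- setdiff(unique(growth$group), control)
  do.call(rbind, lapply(groups, function(grp) {
    r <- tgi(growth, grp, control, day = day, baseline_day = baseline_day,
             meaningful_threshold = meaningful_threshold)
    data.frame(group = r$group, day = r$day, t0_volume = r$t0_volume,
               tt_volume = r$tt_volume, c0_volume = r$c0_volume,
               ct_volume = r$ct_volume, tgi_percent = r$tgi_percent,
               meaningful = r$meaningful, stringsAsFactors = FALSE)
  }))
}

#' Mean and sample standard deviation of a measurement group
#'
#' Reporting helper for "mean ± SD" summaries; the SD uses the `n - 1`
#' denominator and is `NA` for singleton groups.
#'
#' @param values numeric vector.
#' @return Named numeric vector `c(mean, sd)`.
#' @export
group_summary <- function(values) {
  if (length(values) == 0) stop("no values supplied", call. = FALSE)
  s <- if (length(values) < 2) {
    message("group_summary: n < 2, sd reported as missing")
    NA_real_
  } else {
    stats::sd(values)
  }
  c(mean = mean(values), sd = s)
}

#' Randomize animals into balanced treatment groups
#'
#' Uniformly random balanced assignment of `n_groups * group_size` animals;
#' surplus animals are flagged unassigned (`NA`). Reproducible given a seed.
#'
#' @param animal_ids character vector of animal identifiers.
#' @param n_groups number of groups (default 8).
#' @param group_size animals per group (default 6).
#' @param seed optional integer seed.
#' @param group_labels optional labels (default `group1`, `group2`, ...).
#' @return Named character vector mapping each animal to its group (`NA` for
#'   unassigned surplus animals).
#' @export
randomize_cohort <- function(animal_ids, n_groups = 8, group_size = 6,
                             seed = NULL, group_labels = NULL) {
  needed <- n_groups * group_size
  if (length(animal_ids) < needed) {
    stop("need at least ", needed, " animals for ", n_groups, " group(s) of ",
         group_size, "; got ", length(animal_ids), call. = FALSE)
  }
  if (anyDuplicated(animal_ids)) {
    stop("animal_ids must be unique", call. = FALSE)
  }
  if (is.null(group_labels)) group_labels <- paste0("group", seq_len(n_groups))
  stopifnot(length(group_labels) == n_groups)
  if (!is.null(seed)) set.seed(seed)
  shuffled <- sample(animal_ids, length(animal_ids))
  assignment <- rep(NA_character_, length(animal_ids))
  names(assignment) <- shuffled
  assignment[seq_len(needed)] <- rep(group_labels, each = group_size)
  assignment[animal_ids]
}

#' Humane-endpoint flags for a growth curve
#'
#' Flags, per animal, the first day its tumor volume reaches `volume_limit`
#' cubic millimeters (inclusive) and/or the first day its relative body
#' weight loss from day 0 exceeds `weight_loss_limit` (strict).
#'
#' @param growth a [growth_data()] table (one or more animals).
#' @param volume_limit endpoint volume in cubic millimeters (default 1500,
#'   the lower bound of the usual 1500-2000 range).
#' @param weight_loss_limit fractional weight loss endpoint (default 0.15).
#' @param baseline_day day whose body weight is the reference (default 0).
#' @return data.frame with columns `animal`, `day`, `reason` (one row per
#'   flag; zero rows when no endpoint is hit).
#' @export
endpoint_flags <- function(growth, volume_limit = 1500,
                           weight_loss_limit = 0.15, baseline_day = 0) {
  stopifnot(inherits(growth, "growth_data"))
  flags <- list()
  for (a in unique(growth$animal)) {
    sub <- growth[growth$animal == a, , drop = FALSE]
    sub <- sub[order(sub$day), , drop = FALSE]
    hit_vol <- which(sub$volume_mm3 >= volume_limit)
    if (length(hit_vol) > 0) {
      flags[[length(flags) + 1L]] <- data.frame(
        animal = a, day = sub$day[hit_vol[1]],
        reason = sprintf("tumor volume >= %g mm3", volume_limit),
        stringsAsFactors = FALSE)
    }
    w0 <- sub$body_weight_g[sub$day == baseline_day]
    if (length(w0) == 1 && !is.na(w0) && w0 > 0) {
      loss <- 1 - sub$body_weight_g / w0
      hit_w <- which(loss > weight_loss_limit)
      if (length(hit_w) > 0) {
        flags[[length(flags) + 1L]] <- data.frame(
          animal = a, day = sub$day[hit_w[1]],
          reason = sprintf("body weight loss > %g%%",
                           100 * weight_loss_limit),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(flags) == 0) {
    return(data.frame(animal = character(0), day = numeric(0),
                      reason = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, flags)
  rownames(out) <- NULL
  out
}
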