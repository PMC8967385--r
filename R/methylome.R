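## Per-copy methylation quantification, three-class labels and two-donor
## concordance classes, with the depth / CpG-count filters used for all
## copy-level statistics.

#' Filter thresholds for copy-level methylation analysis
#'
#' Bundles the constants governing every methylation filter: per-site
#' minimum read depth, minimum analyzable CpG count per copy, the
#' low/medium/high class boundaries, and the full-length consensus
#' fraction.
#'
#' @param low_max Levels strictly below this are `low` (default 0.20).
#' @param high_min Levels at or above this are `high` (default 0.60).
#' @param min_depth Minimum reads at a CpG site for it to be analyzable
#'   (default 5).
#' @param min_cpgs Minimum analyzable CpG sites for a copy to be
#'   analyzable (default 10).
#' @param full_length_fraction Minimum copy length / consensus length
#'   (default 0.9).
#' @return A list of class `meth_thresholds`.
#' @export
meth_thresholds <- function(low_max = 0.20, high_min = 0.60, min_depth = 5,
                            min_cpgs = 10, full_length_fraction = 0.9) {
  stopifnot(low_max > 0, low_max < high_min, high_min < 1,
            min_depth >= 1, min_cpgs >= 1)
  structure(list(low_max = low_max, high_min = high_min,
                 min_depth = min_depth, min_cpgs = min_cpgs,
                 full_length_fraction = full_length_fraction),
            class = "meth_thresholds")
}

#' Per-site methylation level with depth filter
#'
#' `meth_reads / total_reads` for sites with at least `min_depth` reads;
#' `NA` (filtered) otherwise. Filtering is a value, not an error.
#'
#' @param meth_reads,total_reads Count vectors.
#' @param min_depth Minimum read depth (default 5).
#' @return Numeric vector of levels in `[0, 1]`, `NA` where filtered.
#' @export
site_level <- function(meth_reads, total_reads, min_depth = 5) {
  ifelse(total_reads >= min_depth, meth_reads / total_reads, NA_real_)
}

#' Per-copy mean methylation
#'
#' Collects the CpG sites whose position falls inside each copy's span
#' (0-based half-open), applies the per-site depth filter, and takes the
#' unweighted mean of the surviving site levels. A copy with fewer than
#' `min_cpgs` analyzable sites is not analyzable (`mean_level = NA`).
#'
#' @param copies Repeat copy table.
#' @param cpgs CpG table (`chrom`, `pos`, `meth_reads`, `total_reads`).
#' @param thresholds A [meth_thresholds()] object.
#' @return A `data.frame` with `copy_id`, `mean_level`,
#'   `n_cpgs_analyzable`, plus the copy coordinates and `subtype`.
#' @export
copy_methylation <- function(copies, cpgs, thresholds = meth_thresholds()) {
  lev <- site_level(cpgs$meth_reads, cpgs$total_reads, thresholds$min_depth)
  n <- integer(nrow(copies))
  mean_level <- rep(NA_real_, nrow(copies))
  if (nrow(copies) > 0L && nrow(cpgs) > 0L) {
    site_df <- data.frame(chrom = cpgs$chrom, start = cpgs$pos,
                          end = cpgs$pos + 1L)
    hits <- interval_overlaps(copies, site_df)
    ok <- !is.na(lev[hits$subject])
    qi <- hits$query[ok]
    lv <- lev[hits$subject][ok]
    if (length(qi) > 0L) {
      n_tab <- tapply(lv, qi, length)
      m_tab <- tapply(lv, qi, mean)
      idx <- as.integer(names(n_tab))
      n[idx] <- as.integer(n_tab)
      mean_level[idx] <- as.numeric(m_tab)
    }
  }
  mean_level[n < thresholds$min_cpgs] <- NA_real_
  data.frame(copy_id = copies$copy_id, chrom = copies$chrom,
             start = copies$start, end = copies$end,
             strand = copies$strand, subtype = copies$subtype,
             mean_level = mean_level, n_cpgs_analyzable = n,
             stringsAsFactors = FALSE)
}

#' Three-class methylation label
#'
#' `low` for levels below 20%, `medium` for 20% up to (not including)
#' 60%, `high` for 60% and above. The boundaries are closed exactly as
#' printed: 0.20 is `medium`, 0.60 is `high`.
#'
#' @param level Numeric vector of methylation levels in `[0, 1]`;
#'   `NA` passes through as `NA`.
#' @param thresholds A [meth_thresholds()] object.
#' @return Character vector of `low` / `medium` / `high`.
#' @export
classify_methylation <- function(level, thresholds = meth_thresholds()) {
  ok <- is.na(level) | (level >= 0 & level <= 1)
  if (!all(ok)) stop("methylation level outside [0, 1]")
  out <- rep(NA_character_, length(level))
  out[!is.na(level) & level < thresholds$low_max] <- "low"
  out[!is.na(level) & level >= thresholds$low_max &
        level < thresholds$high_min] <- "medium"
  out[!is.na(level) & level >= thresholds$high_min] <- "high"
  out
}

#' Two-donor concordance class
#'
#' Joint methylation label across two donors: `common_high` when both
#' levels are high, `common_low` when both are below the low boundary,
#' `high_and_low` when donor 1 is high and donor 2 is low (directional,
#' as printed), and `other` for every remaining combination. With
#' `mirrored = TRUE` the donor-2-high / donor-1-low combination is also
#' reported as `high_and_low`.
#'
#' @param level_d1,level_d2 Numeric vectors of per-copy levels for donors
#'   1 and 2; `NA` (non-analyzable) yields `NA`.
#' @param thresholds A [meth_thresholds()] object.
#' @param mirrored Also label the reversed direction (default `FALSE`).
#' @return Character vector of concordance classes.
#' @export
concordance_class <- function(level_d1, level_d2,
                              thresholds = meth_thresholds(),
                              mirrored = FALSE) {
  stopifnot(length(level_d1) == length(level_d2))
  hi <- thresholds$high_min
  lo <- thresholds$low_max
  out <- rep("other", length(level_d1))
  out[level_d1 >= hi & level_d2 >= hi] <- "common_high"
  out[level_d1 < lo & level_d2 < lo] <- "common_low"
  out[level_d1 >= hi & level_d2 < lo] <- "high_and_low"
  if (mirrored) out[level_d2 >= hi & level_d1 < lo] <- "high_and_low"
  out[is.na(level_d1) | is.na(level_d2)] <- NA_character_
  out
}

#' Per-subtype methylation summary
#'
#' For each repeat subtype: the number of analyzable copies, the median
#' per-copy level, and the fraction of copies in each of the three
#' methylation classes. Subtypes with fewer analyzable copies than
#' `reporting_floor` are flagged (`below_floor`), mirroring the practice
#' of only displaying subtypes with at least 30 full-length copies.
#'
#' @param copy_meth Output of [copy_methylation()] (only analyzable rows
#'   are used).
#' @param thresholds A [meth_thresholds()] object.
#' @param reporting_floor Minimum copy count for unflagged reporting
#'   (default 30).
#' @return A `data.frame` with `subtype`, `n`, `median_level`,
#'   `frac_low`, `frac_medium`, `frac_high`, `below_floor`.
#' @export
family_summary <- function(copy_meth, thresholds = meth_thresholds(),
                           reporting_floor = 30) {
  cm <- copy_meth[!is.na(copy_meth$mean_level), , drop = FALSE]
  cls <- classify_methylation(cm$mean_level, thresholds)
  subtypes <- sort(unique(cm$subtype))
  rows <- lapply(subtypes, function(st) {
    sel <- cm$subtype == st
    data.frame(subtype = st, n = sum(sel),
               median_level = median(cm$mean_level[sel]),
               frac_low = mean(cls[sel] == "low"),
               frac_medium = mean(cls[sel] == "medium"),
               frac_high = mean(cls[sel] == "high"),
               below_floor = sum(sel) < reporting_floor,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(subtype = character(0), n = integer(0),
                      median_level = numeric(0), frac_low = numeric(0),
                      frac_medium = numeric(0), frac_high = numeric(0),
                      below_floor = logical(0))
  }
  out
}
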