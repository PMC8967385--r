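## Two-sample DMR calling: a sliding-window candidate stage (plumbing —
## any external candidate BED can be substituted) followed by the
## normative refinement filter (>= min_successive consecutive analyzable
## CpGs in both samples, candidate-level mean difference >= min_diff),
## and repeat-family overlap annotation.

#' Candidate differentially methylated regions
#'
#' Sliding windows of `window_cpgs` CpG positions that are analyzable in
#' both samples (depth >= `min_depth` in each); windows whose mean
#' per-site absolute level difference reaches `seed_diff` are merged when
#' they overlap; each merged span is then trimmed to the first and last
#' CpG whose per-site difference and 3-site smoothed difference both
#' reach `seed_diff`, so flat flanks swept in by partially overlapping
#' windows do not dilute the candidate-level means. This stage is deliberate plumbing — a permissive seed detector whose output feeds
#' [refine_dmrs()]; candidates from any external caller can be used
#' instead.
#'
#' @param cpgs_d1,cpgs_d2 CpG tables for the two samples.
#' @param window_cpgs Window size in shared analyzable CpGs (default 10).
#' @param step Window step in CpGs (default 1).
#' @param seed_diff Minimum window mean |level1 - level2| (default 0.25).
#' @param min_depth Per-sample depth for a shared CpG to count
#'   (default 5).
#' @return Interval table (`chrom`, `start`, `end`) of merged candidate
#'   spans; empty when the samples share no analyzable CpGs.
#' @export
candidate_dmrs <- function(cpgs_d1, cpgs_d2, window_cpgs = 10L, step = 1L,
                           seed_diff = 0.25, min_depth = 5L) {
  sh <- shared_analyzable(cpgs_d1, cpgs_d2, min_depth)
  out <- data.frame(chrom = character(0), start = integer(0),
                    end = integer(0), stringsAsFactors = FALSE)
  if (nrow(sh) == 0L) return(out)
  for (chrom in unique(sh$chrom)) {
    s <- sh[sh$chrom == chrom, , drop = FALSE]
    n <- nrow(s)
    if (n < window_cpgs) next
    adiff <- abs(s$level1 - s$level2)
    csum <- cumsum(c(0, adiff))
    starts <- seq.int(1L, n - window_cpgs + 1L, by = step)
    wmean <- (csum[starts + window_cpgs] - csum[starts]) / window_cpgs
    hit <- which(wmean >= seed_diff)
    if (length(hit) == 0L) next
    # merge overlapping windows (in CpG index space)
    i1 <- starts[hit]
    i2 <- starts[hit] + window_cpgs - 1L
    merged_s <- i1[1L]
    merged_e <- i2[1L]
    spans <- list()
    for (k in seq_along(hit)[-1]) {
      if (i1[k] <= merged_e) {
        merged_e <- max(merged_e, i2[k])
      } else {
        spans[[length(spans) + 1L]] <- c(merged_s, merged_e)
        merged_s <- i1[k]
        merged_e <- i2[k]
      }
    }
    spans[[length(spans) + 1L]] <- c(merged_s, merged_e)
    # a site is "strong" when its own difference and its 3-site running
    # mean both reach seed_diff: damps isolated noisy flank sites without
    # eroding true block edges
    adiff_s <- (c(adiff[1L], adiff[-n]) + adiff +
                  c(adiff[-1L], adiff[n])) / 3
    for (sp in spans) {
      idx <- sp[1L]:sp[2L]
      strong <- idx[adiff[idx] >= seed_diff & adiff_s[idx] >= seed_diff]
      if (length(strong) == 0L) strong <- idx[which.max(adiff[idx])]
      out <- rbind(out, data.frame(chrom = chrom,
                                   start = s$pos[min(strong)],
                                   end = s$pos[max(strong)] + 1L,
                                   stringsAsFactors = FALSE))
    }
  }
  reset_rownames(out)
}

## CpG positions with depth >= min_depth in BOTH samples, with levels
shared_analyzable <- function(cpgs_d1, cpgs_d2, min_depth) {
  k1 <- paste(cpgs_d1$chrom, cpgs_d1$pos)
  k2 <- paste(cpgs_d2$chrom, cpgs_d2$pos)
  i2 <- match(k1, k2)
  keep <- !is.na(i2) &
    cpgs_d1$total_reads >= min_depth &
    cpgs_d2$total_reads[i2] >= min_depth
  df <- data.frame(chrom = cpgs_d1$chrom[keep], pos = cpgs_d1$pos[keep],
                   level1 = cpgs_d1$meth_reads[keep] /
                     cpgs_d1$total_reads[keep],
                   level2 = cpgs_d2$meth_reads[i2[keep]] /
                     cpgs_d2$total_reads[i2[keep]],
                   stringsAsFactors = FALSE)
  df[order(df$chrom, df$pos), , drop = FALSE] |> reset_rownames()
}

#' Refine candidate DMRs with the depth / run-length / difference filter
#'
#' For each candidate: a CpG is analyzable when covered by at least
#' `min_depth` reads in *both* samples. The candidate is kept when (a) it
#' contains a run of at least `min_successive` consecutive analyzable CpG
#' positions, uninterrupted by any non-analyzable CpG observed in either
#' sample (`successive = "strict"`; `"total"` relaxes this to a simple
#' analyzable-CpG count), and (b) the absolute difference of the two
#' candidate-level mean methylation levels, each averaged over the
#' analyzable CpGs, is at least `min_diff`.
#'
#' @param candidates Interval table of candidate regions (disjoint).
#' @param cpgs_d1,cpgs_d2 CpG tables for the two samples.
#' @param min_depth Per-sample depth filter (default 5).
#' @param min_successive Required run length (default 10).
#' @param min_diff Required mean-level difference (default 0.40).
#' @param successive `"strict"` (consecutive run) or `"total"` (count).
#' @return A `data.frame` of refined DMRs: `chrom`, `start`, `end`,
#'   `mean_d1`, `mean_d2`, `n_cpgs_both`, `direction`
#'   (`d1_hyper`/`d2_hyper`).
#' @export
refine_dmrs <- function(candidates, cpgs_d1, cpgs_d2, min_depth = 5L,
                        min_successive = 10L, min_diff = 0.40,
                        successive = c("strict", "total")) {
  successive <- match.arg(successive)
  rows <- list()
  for (i in seq_len(nrow(candidates))) {
    chrom <- candidates$chrom[i]
    from <- candidates$start[i]
    to <- candidates$end[i]
    in1 <- cpgs_d1[cpgs_d1$chrom == chrom & cpgs_d1$pos >= from &
                     cpgs_d1$pos < to, , drop = FALSE]
    in2 <- cpgs_d2[cpgs_d2$chrom == chrom & cpgs_d2$pos >= from &
                     cpgs_d2$pos < to, , drop = FALSE]
    pos_union <- sort(unique(c(in1$pos, in2$pos)))
    if (length(pos_union) == 0L) next
    d1 <- in1$total_reads[match(pos_union, in1$pos)]
    m1 <- in1$meth_reads[match(pos_union, in1$pos)]
    d2 <- in2$total_reads[match(pos_union, in2$pos)]
    m2 <- in2$meth_reads[match(pos_union, in2$pos)]
    analyzable <- !is.na(d1) & !is.na(d2) & d1 >= min_depth & d2 >= min_depth
    n_ok <- sum(analyzable)
    if (n_ok == 0L) next
    run_ok <- if (successive == "strict") {
      r <- rle(analyzable)
      any(r$values & r$lengths >= min_successive)
    } else {
      n_ok >= min_successive
    }
    if (!run_ok) next
    mean_d1 <- mean(m1[analyzable] / d1[analyzable])
    mean_d2 <- mean(m2[analyzable] / d2[analyzable])
    if (abs(mean_d1 - mean_d2) < min_diff) next
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = chrom, start = from, end = to,
      mean_d1 = mean_d1, mean_d2 = mean_d2, n_cpgs_both = n_ok,
      direction = if (mean_d1 > mean_d2) "d1_hyper" else "d2_hyper",
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), mean_d1 = numeric(0),
                      mean_d2 = numeric(0), n_cpgs_both = integer(0),
                      direction = character(0), stringsAsFactors = FALSE)
  }
  reset_rownames(out)
}

#' Annotate DMRs with repeat-family overlap
#'
#' Flags each DMR that intersects (>= 1 bp, half-open coordinates) any
#' repeat of the given family, and summarizes counts and overlap
#' fractions per direction.
#'
#' @param dmrs Refined DMR table from [refine_dmrs()].
#' @param repeats Repeat copy table with a `family` column.
#' @param family Repeat family to test overlap against (default
#'   `"SVA"`).
#' @return A list with `dmrs` (input plus `overlaps_family` flag) and
#'   `summary` (`data.frame`: `direction`, `n`, `n_overlapping`,
#'   `fraction`).
#' @export
annotate_dmrs <- function(dmrs, repeats, family = "SVA") {
  fam <- repeats[repeats$family == family, , drop = FALSE]
  flag <- rep(FALSE, nrow(dmrs))
  if (nrow(dmrs) > 0L && nrow(fam) > 0L) {
    hits <- interval_overlaps(dmrs, fam)
    flag[unique(hits$query)] <- TRUE
  }
  dmrs$overlaps_family <- flag
  dirs <- c("d1_hyper", "d2_hyper")
  summ <- do.call(rbind, lapply(dirs, function(d) {
    sel <- dmrs$direction == d
    n <- sum(sel)
    data.frame(direction = d, n = n, n_overlapping = sum(flag[sel]),
               fraction = if (n > 0L) sum(flag[sel]) / n else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(dmrs = dmrs, summary = reset_rownames(summ))
}
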