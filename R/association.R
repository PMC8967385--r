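## Class-wise peak-overlap fractions, the figure-level statistical tests,
## length-normalized metaprofiles, and expression association.

#' Peak-overlap fraction per methylation class
#'
#' For each methylation class, the number and fraction of copies
#' intersected by at least one peak by `min_overlap_bp` or more.
#'
#' @param copies_by_class Named list mapping class label to a repeat copy
#'   table (`chrom`, `start`, `end`).
#' @param peaks Interval table (`chrom`, `start`, `end`), 0-based
#'   half-open.
#' @param min_overlap_bp Minimum intersection in bp (default 1).
#' @return A `data.frame` with `class`, `n_copies`, `n_overlapping`,
#'   `fraction` (`NA` for empty classes).
#' @export
overlap_fraction <- function(copies_by_class, peaks, min_overlap_bp = 1L) {
  rows <- lapply(names(copies_by_class), function(cl) {
    copies <- copies_by_class[[cl]]
    n <- nrow(copies)
    n_ov <- 0L
    if (n > 0L && nrow(peaks) > 0L) {
      hits <- interval_overlaps(copies, peaks,
                                min_overlap_bp = min_overlap_bp)
      n_ov <- length(unique(hits$query))
    }
    data.frame(class = cl, n_copies = n, n_overlapping = n_ov,
               fraction = if (n > 0L) n_ov / n else NA_real_,
               stringsAsFactors = FALSE)
  })
  reset_rownames(do.call(rbind, rows))
}

#' Test association between class and peak overlap
#'
#' For two classes, a two-proportion test (`prop.test`, i.e. the
#' chi-square form of the two-proportion z-test); for three or more, a
#' Pearson chi-square test on the class x overlap contingency table.
#' Continuity correction is off by default and only applies to the
#' two-class case.
#'
#' @param counts Matrix (or `data.frame`) with one row per class and two
#'   columns: overlapping and non-overlapping copy counts. An
#'   [overlap_fraction()] table is also accepted.
#' @param correct Apply Yates continuity correction in the 2x2 case
#'   (default `FALSE`).
#' @return A list with `statistic`, `df`, `p_value`, `method`, and
#'   `low_expected` (`TRUE` when any expected cell is below 1, flagging a
#'   degenerate table).
#' @export
class_association_test <- function(counts, correct = FALSE) {
  if (is.data.frame(counts) && all(c("n_overlapping", "n_copies") %in%
                                   names(counts))) {
    counts <- cbind(counts$n_overlapping,
                    counts$n_copies - counts$n_overlapping)
  }
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) >= 2L, ncol(counts) == 2L, all(counts >= 0))
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  low_expected <- any(expected < 1)
  if (low_expected) warning("expected cell count below 1; test degenerate")
  if (nrow(counts) == 2L) {
    ht <- suppressWarnings(
      prop.test(counts[, 1L], rowSums(counts), correct = correct))
    method <- "two_proportion"
  } else {
    ht <- suppressWarnings(chisq.test(counts, correct = FALSE))
    method <- "chi_square"
  }
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, method = method, low_expected = low_expected)
}

#' Length-normalized signal metaprofile over copies
#'
#' Divides each copy's span into `n_bins` equal bins, computes the mean
#' per-base signal (coverage by the supplied intervals) in each bin,
#' reverses minus-strand copies so bin 1 is always the element's 5' end,
#' and averages across copies.
#'
#' @param copies Repeat copy table with `strand`.
#' @param signal Interval table (`chrom`, `start`, `end`); per-base
#'   signal is the number of intervals covering the base.
#' @param n_bins Number of bins (default 100). Copies shorter than
#'   `n_bins` bp are skipped with a warning.
#' @return Numeric vector of length `n_bins`: mean binned signal.
#' @export
metaprofile <- function(copies, signal, n_bins = 100L) {
  stopifnot(n_bins >= 1L)
  short <- (copies$end - copies$start) < n_bins
  if (any(short)) {
    warning(sum(short), " copies shorter than n_bins skipped")
    copies <- copies[!short, , drop = FALSE]
  }
  if (nrow(copies) == 0L) return(rep(NaN, n_bins))
  prof <- matrix(0, nrow(copies), n_bins)
  hits <- if (nrow(signal) > 0L) interval_overlaps(copies, signal) else
    list(query = integer(0), subject = integer(0))
  for (ci in seq_len(nrow(copies))) {
    len <- copies$end[ci] - copies$start[ci]
    cov <- numeric(len)
    for (si in hits$subject[hits$query == ci]) {
      a <- max(signal$start[si], copies$start[ci]) - copies$start[ci]
      b <- min(signal$end[si], copies$end[ci]) - copies$start[ci]
      cov[(a + 1L):b] <- cov[(a + 1L):b] + 1
    }
    bin <- floor((seq_len(len) - 1L) * n_bins / len) + 1L
    means <- tapply(cov, bin, mean)
    v <- as.numeric(means)
    if (copies$strand[ci] == "-") v <- rev(v)
    prof[ci, ] <- v
  }
  colMeans(prof)
}

#' Per-cell-type mean RPM expression
#'
#' Reads per million mapped reads per cell (`count / cell total x 1e6`),
#' then the unweighted mean over the cells of each type.
#'
#' @param gene_counts Numeric matrix, genes x cells (row and column
#'   names required).
#' @param cell_types Named character vector mapping cell name to type.
#' @return Numeric matrix genes x types of mean RPM.
#' @export
expression_rpm <- function(gene_counts, cell_types) {
  gene_counts <- as.matrix(gene_counts)
  stopifnot(!is.null(colnames(gene_counts)),
            all(colnames(gene_counts) %in% names(cell_types)))
  totals <- colSums(gene_counts)
  if (any(totals == 0)) {
    stop("cell with zero total count: ",
         colnames(gene_counts)[which(totals == 0)[1L]])
  }
  rpm <- sweep(gene_counts, 2L, totals, `/`) * 1e6
  types <- cell_types[colnames(gene_counts)]
  out <- vapply(sort(unique(types)), function(tp) {
    rowMeans(rpm[, types == tp, drop = FALSE])
  }, numeric(nrow(gene_counts)))
  out
}

#' Multiple-group comparison with family-wise adjustment
#'
#' `all_pairs` runs Tukey's HSD over all pairwise group differences
#' (studentized-range adjustment); `vs_control` runs Dunnett's
#' many-to-one comparisons against the first (or named) group, with
#' p-values from the multivariate-t distribution.
#'
#' @param values_by_group Named list of numeric vectors, one per group
#'   (each of length >= 2; at least two groups).
#' @param style `"all_pairs"` (Tukey) or `"vs_control"` (Dunnett).
#' @param control Control group name for `vs_control` (default: first).
#' @return A `data.frame` with `comparison`, `estimate`, `p_adj`;
#'   attribute `method` records the procedure used.
#' @export
group_comparison <- function(values_by_group,
                             style = c("all_pairs", "vs_control"),
                             control = NULL) {
  style <- match.arg(style)
  stopifnot(length(values_by_group) >= 2L)
  if (any(lengths(values_by_group) < 2L)) {
    stop("every group needs at least 2 values")
  }
  df <- data.frame(
    value = unlist(values_by_group, use.names = FALSE),
    group = factor(rep(names(values_by_group), lengths(values_by_group)),
                   levels = names(values_by_group)))
  if (style == "all_pairs") {
    tk <- TukeyHSD(aov(value ~ group, data = df))$group
    out <- data.frame(comparison = rownames(tk),
                      estimate = tk[, "diff"], p_adj = tk[, "p adj"],
                      stringsAsFactors = FALSE)
    attr(out, "method") <- "tukey_hsd"
  } else {
    if (is.null(control)) control <- names(values_by_group)[1L]
    df$group <- stats::relevel(df$group, ref = control)
    fit <- aov(value ~ group, data = df)
    gl <- multcomp::glht(fit, linfct = multcomp::mcp(group = "Dunnett"))
    sm <- summary(gl)
    out <- data.frame(comparison = names(sm$test$coefficients),
                      estimate = unname(sm$test$coefficients),
                      p_adj = unname(as.numeric(sm$test$pvalues)),
                      stringsAsFactors = FALSE)
    attr(out, "method") <- "dunnett_mvt"
  }
  reset_rownames(out)
}
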