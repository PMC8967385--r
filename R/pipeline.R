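## Orchestration of the two composite analyses: single-methylome
## demethylation-resistance association (catalog -> per-copy methylation
## -> classes -> peak/motif/mappability association) and the two-donor
## sperm analysis (concordance -> genomic context -> expression -> DMR
## census). Both are pure functions of their inputs; when `out_dir` is
## given every table is written as TSV and a manifest of content hashes
## is returned.

#' Demethylation-resistance association analysis (single methylome)
#'
#' Runs the full copy-level pipeline on one methylome: full-length copy
#' selection, per-copy methylation with the depth / CpG-count filters,
#' three-class labels, per-subtype summary, class-wise peak-overlap
#' fractions with the association test, motif counts per class, and
#' simulated-read mappability.
#'
#' @param cpgs CpG table (one sample).
#' @param repeats Repeat copy table.
#' @param consensus_lengths Named subtype -> consensus length vector.
#' @param peaks Named list of peak interval tables (one per factor), or
#'   a single table.
#' @param pwms Named list of [new_pwm()] objects (may be empty).
#' @param genome Named character vector of chromosome sequences
#'   (required for motif counts and mappability; may be `NULL` to skip
#'   both).
#' @param thresholds A [meth_thresholds()] object.
#' @param p_threshold Motif-hit exact p-value threshold.
#' @param read_length,mappability_step Mappability read tiling.
#' @param out_dir Optional output directory for TSVs + manifest.
#' @return A list of tables: `copies_full_length`, `copy_meth` (with
#'   `class` column), `family_summary`, `peak_overlap` (per factor, with
#'   test results), `motif_counts` (per copy x motif), `mappability`,
#'   and `manifest` when `out_dir` is given.
#' @export
run_resistance_analysis <- function(cpgs, repeats, consensus_lengths,
                                    peaks = list(), pwms = list(),
                                    genome = NULL,
                                    thresholds = meth_thresholds(),
                                    p_threshold = 1e-4,
                                    read_length = 100L,
                                    mappability_step = 25L,
                                    out_dir = NULL) {
  full <- select_full_length(repeats, consensus_lengths,
                             thresholds$full_length_fraction)
  message("catalog: ", nrow(repeats), " copies in, ", nrow(full),
          " full-length")
  cm <- copy_methylation(full, cpgs, thresholds)
  cm$class <- classify_methylation(cm$mean_level, thresholds)
  analyzable <- cm[!is.na(cm$mean_level), , drop = FALSE]
  message("methylome: ", nrow(analyzable), " of ", nrow(cm),
          " copies analyzable")
  fam <- family_summary(cm, thresholds)

  if (is.data.frame(peaks)) peaks <- list(peaks = peaks)
  by_class <- split(merge_copy_class(full, cm), analyzable_classes(cm))
  peak_overlap <- lapply(peaks, function(pk) {
    tab <- overlap_fraction(by_class, pk)
    # degeneracy is carried in the low_expected flag, not as a warning
    test <- if (nrow(tab) >= 2L && all(tab$n_copies > 0))
      suppressWarnings(class_association_test(tab)) else NULL
    list(table = tab, test = test)
  })

  motif_counts <- NULL
  if (!is.null(genome) && length(pwms) > 0L) {
    seqs <- get_copy_seq(genome, analyzable)
    motif_counts <- data.frame(copy_id = analyzable$copy_id,
                               class = analyzable$class,
                               stringsAsFactors = FALSE)
    for (nm in names(pwms)) {
      motif_counts[[nm]] <- vapply(seqs, motif_count_per_copy, integer(1),
                                   pwm = pwms[[nm]],
                                   p_threshold = p_threshold,
                                   USE.NAMES = FALSE)
    }
  }

  mapp <- NULL
  if (!is.null(genome)) {
    ok <- analyzable$end - analyzable$start >= read_length
    mapp <- copy_mappability(analyzable[ok, , drop = FALSE], genome,
                             read_length = read_length,
                             step = mappability_step)
  }

  res <- list(copies_full_length = full, copy_meth = cm,
              family_summary = fam, peak_overlap = peak_overlap,
              motif_counts = motif_counts, mappability = mapp)
  maybe_write(res, out_dir)
}

## class labels of analyzable copies, for splitting
analyzable_classes <- function(cm) {
  cm$class[!is.na(cm$mean_level)]
}

merge_copy_class <- function(full, cm) {
  full[!is.na(cm$mean_level), , drop = FALSE]
}

#' Two-donor sperm analysis: concordance, context, expression, DMRs
#'
#' Quantifies per-copy methylation in two donors, types each analyzable
#' copy by its two-donor concordance class, classifies genomic context
#' and summarizes context fractions per class, compares host-gene
#' expression (mean RPM) across concordance classes, and runs the DMR
#' candidate + refinement + repeat-overlap census.
#'
#' @param cpgs_d1,cpgs_d2 CpG tables for donors 1 and 2 (donor order as
#'   configured).
#' @param repeats Repeat copy table.
#' @param consensus_lengths Named subtype -> consensus length vector.
#' @param genes Gene interval table (stranded), or `NULL` to skip
#'   context/expression stages.
#' @param expression List with `counts` (genes x cells) and
#'   `cell_types`, or `NULL`.
#' @param thresholds A [meth_thresholds()] object.
#' @param dmr_family Repeat family for the DMR overlap census.
#' @param window_cpgs,seed_diff,min_successive,min_diff DMR parameters,
#'   see [candidate_dmrs()] and [refine_dmrs()].
#' @param out_dir Optional output directory for TSVs + manifest.
#' @return A list: `concordance` (per-copy table), `concordance_fractions`
#'   (per subtype), `context_fractions` (per concordance class),
#'   `expression_comparison` (mean host-gene RPM per class +
#'   [group_comparison()] table, or `NULL`), `dmrs`, `dmr_summary`, and
#'   `manifest` when `out_dir` is given.
#' @export
run_sperm_analysis <- function(cpgs_d1, cpgs_d2, repeats,
                               consensus_lengths, genes = NULL,
                               expression = NULL,
                               thresholds = meth_thresholds(),
                               dmr_family = "SVA",
                               window_cpgs = 10L, seed_diff = 0.25,
                               min_successive = 10L, min_diff = 0.40,
                               out_dir = NULL) {
  full <- select_full_length(repeats, consensus_lengths,
                             thresholds$full_length_fraction)
  cm1 <- copy_methylation(full, cpgs_d1, thresholds)
  cm2 <- copy_methylation(full, cpgs_d2, thresholds)
  conc <- data.frame(copy_id = full$copy_id, subtype = full$subtype,
                     level_d1 = cm1$mean_level, level_d2 = cm2$mean_level,
                     stringsAsFactors = FALSE)
  conc$concordance <- concordance_class(conc$level_d1, conc$level_d2,
                                        thresholds)
  ok <- !is.na(conc$concordance)
  message("concordance: ", sum(ok), " of ", nrow(conc),
          " copies analyzable in both donors")
  conc_frac <- concordance_fractions(conc[ok, , drop = FALSE])

  context_frac <- NULL
  expr_cmp <- NULL
  if (!is.null(genes) && nrow(genes) > 0L) {
    ctx <- classify_genomic_context(full, genes)
    context_frac <- context_fraction_by_class(ctx[ok, , drop = FALSE],
                                              conc$concordance[ok])
    if (!is.null(expression)) {
      expr_cmp <- host_expression_comparison(ctx, conc, expression)
    }
  }

  cands <- candidate_dmrs(cpgs_d1, cpgs_d2, window_cpgs = window_cpgs,
                          seed_diff = seed_diff,
                          min_depth = thresholds$min_depth)
  dmrs <- refine_dmrs(cands, cpgs_d1, cpgs_d2,
                      min_depth = thresholds$min_depth,
                      min_successive = min_successive,
                      min_diff = min_diff)
  message("dmr: ", nrow(cands), " candidates, ", nrow(dmrs), " refined")
  ann <- annotate_dmrs(dmrs, repeats, family = dmr_family)

  res <- list(concordance = conc, concordance_fractions = conc_frac,
              context_fractions = context_frac,
              expression_comparison = expr_cmp,
              dmrs = ann$dmrs, dmr_summary = ann$summary)
  maybe_write(res, out_dir)
}

concordance_fractions <- function(conc) {
  labels <- c("common_high", "common_low", "high_and_low", "other")
  rows <- lapply(sort(unique(conc$subtype)), function(st) {
    cl <- conc$concordance[conc$subtype == st]
    out <- data.frame(subtype = st, n = length(cl),
                      stringsAsFactors = FALSE)
    for (lb in labels) out[[lb]] <- mean(cl == lb)
    out
  })
  reset_rownames(do.call(rbind, rows))
}

## mean host-gene RPM per concordance class of the hosted antisense copy
host_expression_comparison <- function(ctx, conc, expression) {
  rpm <- expression_rpm(expression$counts, expression$cell_types)
  mean_rpm <- rowMeans(rpm)
  sel <- ctx$context == "genic_antisense" & !is.na(conc$concordance) &
    ctx$host_gene %in% names(mean_rpm)
  groups <- split(mean_rpm[ctx$host_gene[sel]], conc$concordance[sel])
  groups <- groups[lengths(groups) >= 2L]
  cmp <- if (length(groups) >= 2L) group_comparison(groups, "all_pairs")
  else NULL
  list(group_means = vapply(groups, mean, numeric(1)), comparison = cmp)
}

## write each data.frame as TSV + manifest of md5 hashes
maybe_write <- function(res, out_dir) {
  if (is.null(out_dir)) return(res)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  flat <- flatten_tables(res)
  for (nm in names(flat)) {
    path <- file.path(out_dir, paste0(nm, ".tsv"))
    write_table(flat[[nm]], path)
    written <- c(written, path)
  }
  res$manifest <- data.frame(file = basename(written),
                             md5 = unname(tools::md5sum(written)),
                             stringsAsFactors = FALSE)
  write_table(res$manifest, file.path(out_dir, "manifest.tsv"))
  res
}

flatten_tables <- function(res, prefix = "") {
  out <- list()
  for (nm in names(res)) {
    x <- res[[nm]]
    key <- paste0(prefix, nm)
    if (is.data.frame(x)) {
      out[[key]] <- x
    } else if (is.list(x)) {
      out <- c(out, flatten_tables(x, paste0(key, "_")))
    }
  }
  out
}
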