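## Full-length copy selection and genomic-context classification.

#' Select nearly full-length repeat copies
#'
#' A copy is retained when its genomic length is at least `min_fraction`
#' (default 90%) of the consensus length of its subtype. Solo-LTR copies
#' (flagged `is_solo_ltr`) are measured against the LTR consensus length
#' supplied for their subtype under the name `<subtype>_LTR` when present,
#' otherwise the subtype's own entry. The boundary is inclusive: a copy at
#' exactly 90% of consensus is kept.
#'
#' @param copies Repeat copy table as returned by
#'   [read_repeat_annotation()].
#' @param consensus_lengths Named numeric vector mapping subtype to
#'   consensus length in bp.
#' @param min_fraction Minimum copy length / consensus length (default
#'   0.9).
#' @return The subset of `copies` passing the filter, input order
#'   preserved, with an added `consensus_fraction` column.
#' @export
select_full_length <- function(copies, consensus_lengths, min_fraction = 0.9) {
  if (nrow(copies) == 0L) {
    copies$consensus_fraction <- numeric(0)
    return(copies)
  }
  key <- copies$subtype
  solo <- copies$is_solo_ltr
  ltr_key <- paste0(key, "_LTR")
  key[solo & ltr_key %in% names(consensus_lengths)] <-
    ltr_key[solo & ltr_key %in% names(consensus_lengths)]
  missing <- setdiff(unique(key), names(consensus_lengths))
  if (length(missing) > 0L) {
    stop("no consensus length for subtype(s): ",
         paste(missing, collapse = ", "))
  }
  cons <- consensus_lengths[key]
  frac <- (copies$end - copies$start) / cons
  out <- copies[frac >= min_fraction, , drop = FALSE]
  out$consensus_fraction <- frac[frac >= min_fraction]
  reset_rownames(out)
}

#' Classify the genomic context of repeat copies
#'
#' A copy is genic when it overlaps any gene body (full transcript span,
#' introns included) by at least 1 bp; it is `genic_antisense` when its
#' strand is opposite to the host gene's, `genic_sense` when equal, and
#' `non_genic` otherwise. When several genes overlap a copy, the gene with
#' the largest overlap wins; ties go to the gene with the smaller start.
#'
#' @param copies Repeat copy table (0-based half-open, strand `+`/`-`).
#' @param genes A `data.frame` with `chrom`, `start`, `end`, `strand`
#'   (`+`/`-`) and `name` columns (e.g. BED-derived gene bodies).
#' @return `copies` with added columns `context` (one of
#'   `genic_antisense`, `genic_sense`, `non_genic`) and `host_gene`
#'   (`NA` for non-genic copies).
#' @export
classify_genomic_context <- function(copies, genes) {
  context <- rep("non_genic", nrow(copies))
  host <- rep(NA_character_, nrow(copies))
  if (nrow(copies) > 0L && nrow(genes) > 0L) {
    stopifnot(all(genes$strand %in% c("+", "-")))
    hits <- interval_overlaps(copies, genes)
    if (length(hits$query) > 0L) {
      ov_start <- pmax(copies$start[hits$query], genes$start[hits$subject])
      ov_end <- pmin(copies$end[hits$query], genes$end[hits$subject])
      width <- ov_end - ov_start
      # per copy: largest overlap, ties to smaller gene start
      ord <- order(hits$query, -width, genes$start[hits$subject])
      first <- !duplicated(hits$query[ord])
      qi <- hits$query[ord][first]
      gi <- hits$subject[ord][first]
      if (any(copies$strand[qi] == ".")) {
        stop("copy with strand '.' overlaps a gene; orientation undefined")
      }
      context[qi] <- ifelse(copies$strand[qi] == genes$strand[gi],
                            "genic_sense", "genic_antisense")
      host[qi] <- genes$name[gi]
    }
  }
  copies$context <- context
  copies$host_gene <- host
  copies
}

## 0-based half-open overlap via IRanges; returns query/subject index pairs
interval_overlaps <- function(a, b, min_overlap_bp = 1L) {
  gr_a <- GenomicRanges::GRanges(a$chrom,
                                 IRanges::IRanges(a$start + 1L, a$end))
  gr_b <- GenomicRanges::GRanges(b$chrom,
                                 IRanges::IRanges(b$start + 1L, b$end))
  hits <- GenomicRanges::findOverlaps(gr_a, gr_b,
                                      minoverlap = min_overlap_bp)
  list(query = S4Vectors::queryHits(hits),
       subject = S4Vectors::subjectHits(hits))
}

#' Genomic-context fractions per methylation class
#'
#' For each class label, the fraction of copies falling in each context
#' category; fractions per class sum to 1. Classes with no copies are
#' omitted with a warning.
#'
#' @param copies_with_context Output of [classify_genomic_context()].
#' @param class_labels Character vector of class labels, parallel to the
#'   rows of `copies_with_context`.
#' @return A `data.frame` with columns `class`, `n`, `genic_antisense`,
#'   `genic_sense`, `non_genic`.
#' @export
context_fraction_by_class <- function(copies_with_context, class_labels) {
  stopifnot(length(class_labels) == nrow(copies_with_context),
            !is.null(copies_with_context$context))
  cls <- unique(class_labels)
  empty <- cls[!cls %in% class_labels]  # defensive; unique() precludes this
  rows <- lapply(cls, function(cl) {
    ctx <- copies_with_context$context[class_labels == cl]
    n <- length(ctx)
    if (n == 0L) return(NULL)
    data.frame(class = cl, n = n,
               genic_antisense = mean(ctx == "genic_antisense"),
               genic_sense = mean(ctx == "genic_sense"),
               non_genic = mean(ctx == "non_genic"),
               stringsAsFactors = FALSE)
  })
  keep <- !vapply(rows, is.null, logical(1))
  if (!all(keep)) warning("classes with no copies omitted")
  do.call(rbind, rows[keep])
}
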