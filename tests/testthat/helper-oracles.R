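# Independent brute-force oracles and small fixture builders shared by
# the unit and acceptance tests. The oracles deliberately avoid the code
# paths they check: motif p-values come from full word enumeration (not
# the DP convolution), occurrence counts from a vectorized window census
# (not Biostrings pattern matching), and per-copy methylation from a
# naive per-CpG loop (not the interval-overlap join).

BASES4 <- c("A", "C", "G", "T")

rand_dna <- function(n) paste(sample(BASES4, n, replace = TRUE),
                              collapse = "")

revcomp_str <- function(s) {
  chartr("ACGT", "TGCA",
         paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
}

# near-deterministic PWM spelling a consensus word
consensus_pwm_for_test <- function(consensus, major = 0.94) {
  ch <- strsplit(consensus, "", fixed = TRUE)[[1]]
  mat <- matrix((1 - major) / 3, length(ch), 4,
                dimnames = list(NULL, BASES4))
  mat[cbind(seq_along(ch), match(ch, BASES4))] <- major
  new_pwm(consensus, mat)
}

rand_pwm <- function(w) {
  mat <- matrix(runif(4 * w, 0.05, 1), w, 4)
  mat <- mat / rowSums(mat)
  colnames(mat) <- BASES4
  new_pwm("rand", mat)
}

# enumerate every window on both strands; exact p-values by enumerating
# all 4^w words under the background (integer-scaled scores, as the
# operation defines them)
oracle_scan_motifs <- function(sequence, pwm, p_threshold) {
  w <- nrow(pwm$matrix)
  n <- nchar(sequence)
  if (n < w) return(NULL)
  bg <- pwm$background
  res <- list()
  for (strand in c("+", "-")) {
    mat <- pwm$matrix
    if (strand == "-") {
      mat <- mat[rev(seq_len(w)), c("T", "G", "C", "A"), drop = FALSE]
      colnames(mat) <- BASES4
    }
    si <- round(1000 * sweep(log2(mat), 2, log2(bg), `-`))
    # all-word score/probability vectors by direct enumeration
    sc_all <- 0
    pr_all <- 1
    for (i in seq_len(w)) {
      sc_all <- as.vector(outer(sc_all, si[i, ], `+`))
      pr_all <- as.vector(outer(pr_all, bg, `*`))
    }
    ord <- order(sc_all)
    sc_sorted <- sc_all[ord]
    tail_from <- rev(cumsum(rev(pr_all[ord])))  # P(score >= sc_sorted[i])
    pv_at <- function(k) {
      idx <- findInterval(k - 0.5, sc_sorted)  # words scoring < k
      if (idx >= length(sc_sorted)) 0 else tail_from[idx + 1]
    }
    for (o in 0:(n - w)) {
      ch <- strsplit(substr(sequence, o + 1, o + w), "")[[1]]
      k <- sum(si[cbind(seq_len(w), match(ch, BASES4))])
      p <- pv_at(k)
      if (p <= p_threshold) {
        res[[length(res) + 1]] <- data.frame(
          offset = o, strand = strand, p_value = p,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(res) == 0) return(NULL)
  out <- do.call(rbind, res)
  out[order(out$offset, out$strand), , drop = FALSE]
}

# exact-occurrence census over every genome window, both strands
oracle_count_occurrences <- function(read, genome_str) {
  L <- nchar(read)
  n <- nchar(genome_str)
  if (n < L) return(0L)
  wins <- substring(genome_str, 1:(n - L + 1), L:n)
  rcr <- revcomp_str(read)
  if (read == rcr) sum(wins == read)
  else sum(wins == read) + sum(wins == rcr)
}

oracle_copy_mappability <- function(copy, genome_str, read_length) {
  reads <- substring(genome_str,
                     (copy$start + 1):(copy$end - read_length + 1),
                     (copy$start + read_length):copy$end)
  occ <- vapply(reads, oracle_count_occurrences, numeric(1),
                genome_str = genome_str, USE.NAMES = FALSE)
  mean(occ == 1)
}

# naive per-copy mean: loop every CpG, test membership, filter, average
oracle_copy_methylation <- function(copy, cpgs, min_depth = 5,
                                    min_cpgs = 10) {
  levels <- c()
  for (i in seq_len(nrow(cpgs))) {
    if (cpgs$chrom[i] == copy$chrom && cpgs$pos[i] >= copy$start &&
        cpgs$pos[i] < copy$end && cpgs$total_reads[i] >= min_depth) {
      levels <- c(levels, cpgs$meth_reads[i] / cpgs$total_reads[i])
    }
  }
  if (length(levels) < min_cpgs) return(NA_real_)
  mean(levels)
}

# minimal copy table row
copy_row <- function(chrom = "chr1", start, end, strand = "+",
                     subtype = "SVA_A", family = "SVA") {
  data.frame(chrom = chrom, start = start, end = end, strand = strand,
             subtype = subtype, family = family,
             copy_id = paste0(chrom, ":", start, "-", end),
             is_solo_ltr = FALSE, stringsAsFactors = FALSE)
}

cpg_table <- function(pos, meth, total, chrom = "chr1") {
  data.frame(chrom = rep_len(chrom, length(pos)), pos = as.integer(pos),
             meth_reads = meth, total_reads = total,
             stringsAsFactors = FALSE)
}

interval_table <- function(start, end, chrom = "chr1", strand = NULL,
                           name = NULL) {
  out <- data.frame(chrom = rep_len(chrom, length(start)),
                    start = as.integer(start),
                    end = as.integer(end), stringsAsFactors = FALSE)
  if (!is.null(strand)) out$strand <- strand
  if (!is.null(name)) out$name <- name
  out
}

# reciprocal-overlap (>= frac both ways) match of detected vs true spans
reciprocal_hits <- function(truth, found, frac = 0.5) {
  hit <- logical(nrow(truth))
  matched <- logical(nrow(found))
  for (i in seq_len(nrow(truth))) {
    for (j in seq_len(nrow(found))) {
      ov <- max(0, min(truth$end[i], found$end[j]) -
                  max(truth$start[i], found$start[j]))
      if (ov >= frac * (truth$end[i] - truth$start[i]) &&
          ov >= frac * (found$end[j] - found$start[j])) {
        hit[i] <- TRUE
        matched[j] <- TRUE
      }
    }
  }
  list(recall = if (nrow(truth)) mean(hit) else NA_real_,
       n_unmatched = sum(!matched))
}
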