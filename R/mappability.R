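## Simulated-read mappability of repeat copies: tile the copy with
## fixed-length reads, count exact occurrences of each read on both
## strands of the whole genome, and score the fraction of reads that map
## uniquely. Exact search is a stricter stand-in for a -m 1 style unique
## aligner; a Hamming-distance-tolerant mode is exposed for sensitivity
## checks.

#' Simulate reads tiling a repeat copy
#'
#' One read per start offset fully contained in the copy span, taken from
#' the genome plus strand.
#'
#' @param copy One-row repeat copy table (or list with `chrom`, `start`,
#'   `end`).
#' @param genome Named character vector of chromosome sequences.
#' @param read_length Read length in bp (default 100).
#' @param step Stride between read start offsets (default 1: one read
#'   per position; larger strides thin the tiling for large runs).
#' @return Character vector of reads; `end - start - read_length + 1` of
#'   them at `step = 1`.
#' @export
simulate_reads <- function(copy, genome, read_length = 100L, step = 1L) {
  chrom_seq <- genome[[copy$chrom]]
  stopifnot(!is.null(chrom_seq), copy$start >= 0,
            copy$end <= nchar(chrom_seq), step >= 1L)
  len <- copy$end - copy$start
  if (len < read_length) {
    stop("copy length ", len, " shorter than read length ", read_length)
  }
  starts <- copy$start + seq.int(0L, len - read_length, by = step)
  substring(chrom_seq, starts + 1L, starts + read_length)
}

#' Count genome-wide occurrences of a read
#'
#' Exact occurrences of the read on either strand of the whole genome:
#' plus-strand matches of the read plus plus-strand matches of its
#' reverse complement. A read equal to its own reverse complement is
#' counted once per locus. With `max_mismatch > 0`, matches within that
#' Hamming distance are counted instead (no indels).
#'
#' @param read Read sequence (`N` never matches).
#' @param genome Named character vector of chromosome sequences.
#' @param max_mismatch Maximum Hamming distance (default 0, exact).
#' @return Integer occurrence count.
#' @export
count_occurrences <- function(read, genome, max_mismatch = 0L) {
  stopifnot(nzchar(read))
  pat <- Biostrings::DNAString(read)
  rc <- Biostrings::reverseComplement(pat)
  palindromic <- as.character(rc) == as.character(pat)
  total <- 0L
  for (subject in as_dna_list(genome)) {
    total <- total + Biostrings::countPattern(
      pat, subject, max.mismatch = max_mismatch, fixed = TRUE)
    if (!palindromic) {
      total <- total + Biostrings::countPattern(
        rc, subject, max.mismatch = max_mismatch, fixed = TRUE)
    }
  }
  total
}

## character chromosomes -> list of DNAString, done once per genome
as_dna_list <- function(genome) {
  if (is.list(genome) &&
      all(vapply(genome, inherits, logical(1), "DNAString"))) {
    return(genome)
  }
  lapply(as.list(genome), Biostrings::DNAString)
}

#' Simulated-read mappability of repeat copies
#'
#' Tiles each copy with `read_length` bp reads at every contained start
#' position, counts each read's exact occurrences over both genome
#' strands, and reports the fraction of reads occurring exactly once
#' ("properly mapped") as the copy's mappability.
#'
#' @param copies Repeat copy table (one or more rows).
#' @param genome Named character vector of chromosome sequences.
#' @param read_length Read length in bp (default 100).
#' @param max_mismatch Hamming tolerance passed to
#'   [count_occurrences()] (default 0).
#' @param step Read-start stride, see [simulate_reads()] (default 1).
#' @return A `data.frame` with `copy_id`, `n_reads`, `n_unique`,
#'   `mappability`.
#' @export
copy_mappability <- function(copies, genome, read_length = 100L,
                             max_mismatch = 0L, step = 1L) {
  dna <- as_dna_list(genome)
  rows <- lapply(seq_len(nrow(copies)), function(i) {
    copy <- copies[i, ]
    reads <- simulate_reads(copy, genome, read_length, step = step)
    occ <- vapply(reads, count_occurrences, integer(1), genome = dna,
                  max_mismatch = max_mismatch, USE.NAMES = FALSE)
    data.frame(copy_id = copy$copy_id, n_reads = length(reads),
               n_unique = sum(occ == 1L),
               mappability = mean(occ == 1L),
               stringsAsFactors = FALSE)
  })
  reset_rownames(do.call(rbind, rows))
}
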