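## PWM log-odds scanning with exact p-values, non-overlapping hit
## counting, and VNTR unit-number estimation.
##
## Scores are log2(p/background) summed over motif positions, discretized
## to integer units of 1/SCORE_SCALE bits. The p-value of a window score
## is the exact probability, under the i.i.d. background model, that a
## random word scores at least as high; it is computed by dynamic
## programming over the integer score distribution (the lattice
## convolution FIMO uses), so the only approximation is the score
## discretization itself.

SCORE_SCALE <- 1000L

BASES <- c("A", "C", "G", "T")

## integer log-odds score matrix: w x 5, column 5 = N (scores 0)
pwm_int_scores <- function(mat, background) {
  s <- sweep(log2(mat), 2L, log2(background[BASES]), `-`)
  si <- round(s * SCORE_SCALE)
  cbind(si, N = 0)
}

## reverse complement of a PWM matrix (scan minus strand on forward coords)
pwm_revcomp <- function(mat) {
  out <- mat[rev(seq_len(nrow(mat))), c("T", "G", "C", "A"), drop = FALSE]
  colnames(out) <- BASES
  out
}

## exact null distribution of the integer score under the background:
## list(min, probs) with probs[k] = P(score == min + k - 1)
score_null_distribution <- function(si, background) {
  w <- nrow(si)
  bg <- background[BASES]
  lo <- sum(apply(si[, BASES, drop = FALSE], 1L, min))
  hi <- sum(apply(si[, BASES, drop = FALSE], 1L, max))
  probs <- numeric(hi - lo + 1L)
  # DP over positions; offset tracks the attainable minimum so far
  cur <- 1
  cur_lo <- 0L
  for (i in seq_len(w)) {
    row <- si[i, BASES]
    row_lo <- min(row)
    nxt_len <- length(cur) + (max(row) - row_lo)
    nxt <- numeric(nxt_len)
    for (b in 1:4) {
      sh <- row[b] - row_lo
      idx <- seq_along(cur) + sh
      nxt[idx] <- nxt[idx] + cur * bg[b]
    }
    cur <- nxt
    cur_lo <- cur_lo + row_lo
  }
  stopifnot(cur_lo == lo, length(cur) == hi - lo + 1L)
  list(min = lo, probs = cur)
}

## tail p-value lookup: p(k) = P(score >= k); returns a function
score_tail_pvalue <- function(null_dist) {
  tail <- rev(cumsum(rev(null_dist$probs)))
  lo <- null_dist$min
  hi <- lo + length(tail) - 1L
  function(k) {
    p <- rep(1, length(k))
    p[k > hi] <- 0
    inside <- k >= lo & k <= hi
    p[inside] <- tail[k[inside] - lo + 1L]
    p
  }
}

encode_seq <- function(sequence) {
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  code <- match(chars, c(BASES, "N"))
  if (anyNA(code)) stop("sequence contains characters outside {A,C,G,T,N}")
  code
}

## integer window scores at every offset for one strand's score matrix
window_scores <- function(code, si) {
  w <- nrow(si)
  n_win <- length(code) - w + 1L
  if (n_win <= 0L) return(integer(0))
  total <- numeric(n_win)
  for (i in seq_len(w)) {
    total <- total + si[i, ][code[i:(i + n_win - 1L)]]
  }
  as.integer(round(total))
}

#' Scan a sequence for PWM motif occurrences
#'
#' Scores every window on both strands with the log2 odds of the PWM
#' against its background model (`N` bases contribute zero log-odds) and
#' reports windows whose exact match p-value — the probability that a
#' random background word scores at least as high, computed by dynamic
#' programming over the integer-scaled score distribution — is at most
#' `p_threshold`. This mirrors FIMO's scoring; the q-value thresholding
#' FIMO applies can be reproduced downstream with
#' [motif_hits_bh()].
#'
#' @param sequence Nucleotide string over `{A,C,G,T,N}` (case
#'   insensitive).
#' @param pwm A [new_pwm()] / [read_pwm()] object.
#' @param p_threshold Maximum exact p-value for a reported hit.
#' @return A `data.frame` with columns `offset` (0-based window start on
#'   the forward sequence), `strand` (`+`/`-`), `score` (log2 odds, in
#'   bits), `p_value`; sorted by offset. Empty for sequences shorter than
#'   the motif.
#' @export
scan_motifs <- function(sequence, pwm, p_threshold = 1e-4) {
  stopifnot(inherits(pwm, "pwm"), p_threshold > 0, p_threshold <= 1)
  code <- encode_seq(sequence)
  w <- nrow(pwm$matrix)
  if (length(code) < w) return(empty_hits())
  hits <- list()
  for (strand in c("+", "-")) {
    mat <- if (strand == "+") pwm$matrix else pwm_revcomp(pwm$matrix)
    si <- pwm_int_scores(mat, pwm$background)
    pval <- score_tail_pvalue(score_null_distribution(si, pwm$background))
    sc <- window_scores(code, si)
    p <- pval(sc)
    keep <- which(p <= p_threshold)
    if (length(keep) > 0L) {
      hits[[strand]] <- data.frame(offset = keep - 1L, strand = strand,
                                   score = sc[keep] / SCORE_SCALE,
                                   p_value = p[keep],
                                   stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0L) return(empty_hits())
  out <- do.call(rbind, hits)
  out <- out[order(out$offset, out$strand), , drop = FALSE]
  reset_rownames(out)
}

empty_hits <- function() {
  data.frame(offset = integer(0), strand = character(0),
             score = numeric(0), p_value = numeric(0))
}

#' Benjamini-Hochberg q-values for motif hits
#'
#' Converts exact p-values from one or more [scan_motifs()] runs into BH
#' q-values across the whole scanned universe, given the total number of
#' windows scanned (both strands), reproducing FIMO's q-value procedure.
#'
#' @param hits A hit table from [scan_motifs()] (or several, row-bound).
#' @param n_windows_scanned Total number of (window, strand) tests.
#' @return `hits` with an added `q_value` column.
#' @export
motif_hits_bh <- function(hits, n_windows_scanned) {
  stopifnot(n_windows_scanned >= nrow(hits))
  q <- p.adjust(hits$p_value, method = "BH", n = n_windows_scanned)
  hits$q_value <- q
  hits
}

#' Count non-overlapping motif occurrences in a copy sequence
#'
#' Scans with [scan_motifs()] and resolves overlaps greedily left to
#' right: hits are visited in order of offset (best score first at equal
#' offset) and accepted when they do not overlap a previously accepted
#' hit. Tandem-repeat motifs are thereby counted once per occupied site
#' rather than once per overlapping window.
#'
#' @inheritParams scan_motifs
#' @param copy_seq Nucleotide sequence of the copy.
#' @return Integer hit count.
#' @export
motif_count_per_copy <- function(copy_seq, pwm, p_threshold = 1e-4) {
  hits <- scan_motifs(copy_seq, pwm, p_threshold)
  if (nrow(hits) == 0L) return(0L)
  w <- nrow(pwm$matrix)
  hits <- hits[order(hits$offset, -hits$score), , drop = FALSE]
  count <- 0L
  last_end <- -1L
  for (i in seq_len(nrow(hits))) {
    if (hits$offset[i] >= last_end) {
      count <- count + 1L
      last_end <- hits$offset[i] + w
    }
  }
  count
}

#' Estimate the number of VNTR units in a copy
#'
#' Greedy left-to-right consensus tiling: at each position, if the window
#' of one unit length matches the unit consensus with identity at least
#' `min_identity`, a unit is counted and the scan jumps one unit length;
#' otherwise it advances 1 bp. This is the package's operational
#' definition of VNTR unit number; no alignment is performed, so unit
#' indels register as reduced identity.
#'
#' @param copy_seq Nucleotide sequence of the copy.
#' @param unit_consensus Consensus sequence of one tandem-repeat unit
#'   (length >= 10).
#' @param min_identity Minimum per-unit identity (default 0.8).
#' @return Integer unit count.
#' @export
estimate_vntr_units <- function(copy_seq, unit_consensus, min_identity = 0.8) {
  stopifnot(nchar(unit_consensus) >= 10)
  seqc <- strsplit(toupper(copy_seq), "", fixed = TRUE)[[1L]]
  unitc <- strsplit(toupper(unit_consensus), "", fixed = TRUE)[[1L]]
  L <- length(unitc)
  n <- length(seqc)
  count <- 0L
  pos <- 1L
  while (pos + L - 1L <= n) {
    ident <- sum(seqc[pos:(pos + L - 1L)] == unitc) / L
    if (ident >= min_identity) {
      count <- count + 1L
      pos <- pos + L
    } else {
      pos <- pos + 1L
    }
  }
  count
}
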