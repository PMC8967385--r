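## Readers and writers for the external file formats consumed by the
## pipeline. Every reader normalizes to the package-wide convention:
## 0-based half-open intervals; CpGs keyed by the position of the C.

#' Read a per-CpG methylation call table
#'
#' Parses per-CpG methylated/unmethylated read counts. The canonical input
#' is the Bismark coverage format (`<chrom> <start 1-based> <end>
#' <percent> <count methylated> <count unmethylated>`); the percent column
#' is ignored and methylation levels are always recomputed from the counts,
#' which are authoritative. A `bedgraph_counts` dialect (`<chrom> <start
#' 0-based> <end> <percent> <meth> <unmeth>`) is accepted for pipelines
#' that emit 0-based tracks.
#'
#' @param path Path to the coverage file (plain text, tab-separated).
#' @param dialect `"bismark_cov"` (default) or `"bedgraph_counts"`.
#' @return A `data.frame` with columns `chrom`, `pos` (0-based position of
#'   the C of the CpG), `meth_reads`, `total_reads`, sorted by
#'   `(chrom, pos)`.
#' @examples
#' f <- tempfile(fileext = ".cov")
#' writeLines("chr1\t101\t101\t80.0\t8\t2", f)
#' read_cpg_table(f)  # pos 100, meth 8, total 10
#' @export
read_cpg_table <- function(path, dialect = c("bismark_cov", "bedgraph_counts")) {
  dialect <- match.arg(dialect)
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(empty_cpg_table())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 6L)
  if (length(bad) > 0L) {
    stop("malformed coverage line ", bad[1L], ": expected >= 6 fields, got ",
         nf[bad[1L]])
  }
  m <- matrix(unlist(lapply(fields, `[`, 1:6)), ncol = 6L, byrow = TRUE)
  chrom <- m[, 1L]
  start <- suppressWarnings(as.integer(m[, 2L]))
  meth <- suppressWarnings(as.numeric(m[, 5L]))
  unmeth <- suppressWarnings(as.numeric(m[, 6L]))
  bad <- which(is.na(start) | is.na(meth) | is.na(unmeth))
  if (length(bad) > 0L) {
    stop("malformed coverage line ", bad[1L], ": non-numeric field")
  }
  pos <- if (dialect == "bismark_cov") start - 1L else start
  rec <- data.frame(chrom = chrom, pos = pos,
                    meth_reads = meth, total_reads = meth + unmeth,
                    stringsAsFactors = FALSE)
  validate_cpg_table(rec)
  rec[order(rec$chrom, rec$pos), , drop = FALSE] |> reset_rownames()
}

empty_cpg_table <- function() {
  data.frame(chrom = character(0), pos = integer(0),
             meth_reads = numeric(0), total_reads = numeric(0),
             stringsAsFactors = FALSE)
}

validate_cpg_table <- function(rec) {
  bad <- which(rec$meth_reads < 0 | rec$total_reads < rec$meth_reads |
                 rec$pos < 0)
  if (length(bad) > 0L) {
    stop("invalid CpG record at line ", bad[1L],
         ": need 0 <= meth_reads <= total_reads and pos >= 0")
  }
  invisible(rec)
}

reset_rownames <- function(df) { rownames(df) <- NULL; df }

#' Write a CpG table as a Bismark coverage file
#'
#' Inverse of [read_cpg_table()] for the `bismark_cov` dialect; the percent
#' column is recomputed from the counts.
#'
#' @param records CpG table (`chrom`, `pos`, `meth_reads`, `total_reads`).
#' @param path Output path.
#' @export
write_cpg_bismark <- function(records, path) {
  pct <- ifelse(records$total_reads > 0,
                100 * records$meth_reads / records$total_reads, 0)
  out <- data.frame(records$chrom, records$pos + 1L, records$pos + 1L,
                    formatC(pct, format = "f", digits = 6),
                    records$meth_reads,
                    records$total_reads - records$meth_reads)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a repeat annotation into a copy table
#'
#' Supports RepeatMasker `.out` files (header lines tolerated, 1-based
#' inclusive coordinates converted to 0-based half-open, strand `"C"`
#' mapped to `"-"`) and BED6 (passthrough, `name` taken as subtype).
#'
#' @param path Path to the annotation file.
#' @param dialect `"repeatmasker_out"` or `"bed6"`.
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `strand`,
#'   `subtype`, `family`, `copy_id`, `is_solo_ltr`. For BED6 input `family`
#'   is derived from the subtype prefix (`SVA_*` -> `SVA`, `L1*` -> `L1`,
#'   `LTR*`/`MER*`/`HERV*` -> `LTR`, `Alu*` -> `Alu`, otherwise the subtype
#'   itself); for RepeatMasker input the repeat class/family column is used.
#' @export
read_repeat_annotation <- function(path,
                                   dialect = c("repeatmasker_out", "bed6")) {
  dialect <- match.arg(dialect)
  stopifnot(file.exists(path))
  if (dialect == "repeatmasker_out") {
    lines <- readLines(path)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    # header: two banner lines starting with "SW"/"score" then a blank
    keep <- grepl("^[0-9]", lines)
    lines <- lines[keep]
    if (length(lines) == 0L) return(empty_repeat_table())
    fields <- strsplit(lines, "[[:space:]]+")
    get <- function(i) vapply(fields, `[`, "", i)
    chrom <- get(5L)
    start1 <- as.integer(get(6L))
    end1 <- as.integer(get(7L))
    strand <- get(9L)
    strand[strand == "C"] <- "-"
    subtype <- get(10L)
    family <- sub("/.*$", "", get(11L))
    start <- start1 - 1L
    end <- end1
    if (any(end <= start)) stop("repeat with end <= start after conversion")
    rep_table(chrom, start, end, strand, subtype, family)
  } else {
    bed <- read.table(path, sep = "\t", stringsAsFactors = FALSE,
                      col.names = c("chrom", "start", "end", "name",
                                    "score", "strand")[1:6])
    if (nrow(bed) == 0L) return(empty_repeat_table())
    if (any(bed$end <= bed$start)) stop("repeat with end <= start")
    rep_table(bed$chrom, bed$start, bed$end, bed$strand,
              bed$name, family_from_subtype(bed$name))
  }
}

family_from_subtype <- function(subtype) {
  out <- subtype
  out[grepl("^SVA", subtype)] <- "SVA"
  out[grepl("^L1", subtype)] <- "L1"
  out[grepl("^(LTR|MER|HERV)", subtype)] <- "LTR"
  out[grepl("^Alu", subtype)] <- "Alu"
  out
}

rep_table <- function(chrom, start, end, strand, subtype, family,
                      is_solo_ltr = FALSE) {
  data.frame(chrom = chrom, start = as.integer(start), end = as.integer(end),
             strand = strand, subtype = subtype, family = family,
             copy_id = paste0(chrom, ":", start, "-", end, ":", subtype),
             is_solo_ltr = rep_len(is_solo_ltr, length(chrom)),
             stringsAsFactors = FALSE)
}

empty_repeat_table <- function() {
  rep_table(character(0), integer(0), integer(0), character(0),
            character(0), character(0), logical(0))
}

#' Read position weight matrices in MEME minimal format
#'
#' Parses the letter-probability matrix blocks of a MEME minimal motif
#' file. A background letter frequency line is honoured when present;
#' otherwise a uniform background (0.25 each) is used. A pseudocount is
#' mixed into every position so that all probabilities are strictly
#' positive before log-odds scoring.
#'
#' @param path Path to the MEME minimal file.
#' @param pseudocount Small positive mass mixed with each position's
#'   probabilities (default 0.001).
#' @return A list of PWM objects (class `pwm`), each a list with elements
#'   `name`, `matrix` (positions x `A,C,G,T` probabilities), `background`
#'   (length-4 named numeric), `pseudocount`.
#' @export
read_pwm <- function(path, pseudocount = 0.001) {
  stopifnot(file.exists(path), pseudocount > 0)
  lines <- readLines(path)
  bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  bg_at <- grep("^Background letter frequencies", lines)
  if (length(bg_at) == 1L && bg_at < length(lines)) {
    toks <- strsplit(trimws(lines[bg_at + 1L]), "[[:space:]]+")[[1L]]
    vals <- suppressWarnings(as.numeric(toks[c(2, 4, 6, 8)]))
    if (!anyNA(vals)) bg <- setNames(vals, toks[c(1, 3, 5, 7)])[c("A", "C", "G", "T")]
  }
  if (abs(sum(bg) - 1) > 1e-6) stop("background frequencies do not sum to 1")
  motif_at <- grep("^MOTIF", lines)
  if (length(motif_at) == 0L) stop("no MOTIF block found in ", path)
  pwms <- vector("list", length(motif_at))
  for (k in seq_along(motif_at)) {
    i <- motif_at[k]
    name <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1L]][2L]
    j <- i + 1L
    while (j <= length(lines) &&
           !grepl("^letter-probability matrix", lines[j])) j <- j + 1L
    if (j > length(lines)) stop("MOTIF ", name, ": no letter-probability matrix")
    rows <- list()
    j <- j + 1L
    while (j <= length(lines)) {
      tok <- strsplit(trimws(lines[j]), "[[:space:]]+")[[1L]]
      vals <- suppressWarnings(as.numeric(tok))
      if (length(vals) != 4L || anyNA(vals)) break
      rows[[length(rows) + 1L]] <- vals
      j <- j + 1L
    }
    if (length(rows) == 0L) stop("MOTIF ", name, ": empty probability matrix")
    mat <- do.call(rbind, rows)
    colnames(mat) <- c("A", "C", "G", "T")
    bad <- which(abs(rowSums(mat) - 1) > 0.01)
    if (length(bad) > 0L) {
      stop("MOTIF ", name, ": probability row ", bad[1L], " sums to ",
           format(rowSums(mat)[bad[1L]]), " (must be 1 +/- 0.01)")
    }
    pwms[[k]] <- new_pwm(name, mat, bg, pseudocount)
  }
  pwms
}

#' Construct a PWM object
#'
#' @param name Motif name.
#' @param matrix Numeric matrix, positions x 4 (`A,C,G,T`), rows summing
#'   to 1 (before pseudocount).
#' @param background Length-4 background probabilities, summing to 1.
#' @param pseudocount Mass mixed uniformly into each row.
#' @return An object of class `pwm`.
#' @export
new_pwm <- function(name, matrix,
                    background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                    pseudocount = 0.001) {
  stopifnot(ncol(matrix) == 4L, all(abs(rowSums(matrix) - 1) < 0.011),
            abs(sum(background) - 1) < 1e-6, pseudocount > 0)
  mat <- matrix / rowSums(matrix)
  mat <- (1 - pseudocount) * mat + pseudocount / 4
  colnames(mat) <- c("A", "C", "G", "T")
  structure(list(name = name, matrix = mat,
                 background = setNames(as.numeric(background),
                                       c("A", "C", "G", "T")),
                 pseudocount = pseudocount),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("PWM", x$name, "-", nrow(x$matrix), "positions\n")
  print(round(x$matrix, 3))
  invisible(x)
}

#' Write a tabular result as TSV
#'
#' Tab-separated with a header row, floats formatted at 6 decimals, rows
#' in input order, so that repeated runs on the same data produce
#' byte-identical files.
#'
#' @param records A `data.frame`.
#' @param path Output path.
#' @export
write_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  out <- records
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      out[[j]] <- formatC(out[[j]], format = "f", digits = 6)
    }
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}
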