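## Seeded synthetic-data generator with known truth. It emulates the
## statistical structure the analysis assumes: a random background genome
## with embedded repeat copies built from per-subtype consensus sequences
## (VNTR unit counts coupled to a latent methylation class), two-donor
## binomial CpG methylomes driven by latent per-copy classes, ChIP peaks
## placed with a logistic model on motif count, host-gene expression
## coupled to antisense-copy concordance class, and implanted DMR blocks.
## Every artifact is a pure function of (config, seed).

DNA_BASES <- c("A", "C", "G", "T")

## 40 bp VNTR unit; its first 12 bp are the implanted KRAB-ZFP-like motif
VNTR_UNIT <- "GCTGAGGCAGGAGAATCGCTTGAACCCGGGAGGCGGAGGT"

#' Configuration for the synthetic-data generator
#'
#' Defaults define the package's reference simulation: four repeat
#' subtypes (two SVA-like with a class-coupled VNTR, an L1-like and an
#' LTR12-like body), 200 copies total, 2% sequence divergence, 15%
#' truncated copies to exercise the full-length filter, a three-class
#' latent methylation mixture, Poisson read depth with binomial
#' methylation calls, logistic peak placement on motif count, and
#' negative-binomial expression coupled to antisense-copy concordance.
#'
#' @param seed Integer seed; every generated artifact is a pure function
#'   of the configuration including this seed.
#' @param subtypes `data.frame` with `subtype`, `family`, `n_copies`,
#'   `head_len`, `tail_len`, `vntr_units_consensus` (0 = no VNTR).
#' @param vntr_unit Tandem-repeat unit sequence for VNTR subtypes.
#' @param vntr_count_by_class List of integer ranges for the VNTR unit
#'   count drawn per latent class.
#' @param class_mixture Probabilities of the latent classes
#'   (low/medium/high) for donor 1.
#' @param donor_concordance Probability that donor 2 shares donor 1's
#'   latent class (otherwise redrawn from `class_mixture`).
#' @param identical_donors When `TRUE`, donor 2 receives exactly donor
#'   1's class and level (used for flat-background DMR runs).
#' @param level_ranges Per-class uniform ranges the true per-copy mean
#'   level is drawn from.
#' @param divergence Per-base substitution rate applied to each embedded
#'   copy.
#' @param truncate_frac Fraction of copies truncated to 50-85% of
#'   consensus (excluded by the full-length filter).
#' @param gap_range Range of background gap lengths between copies (bp).
#' @param background_level Background (non-repeat) methylation level for
#'   both donors.
#' @param read_depth Mean Poisson read depth per CpG.
#' @param n_dmrs Number of implanted DMR blocks in background sequence.
#' @param dmr_cpgs Range of CpG counts spanned by each implanted DMR.
#' @param dmr_levels Length-2 vector: true levels of donors 1 and 2
#'   inside implanted DMRs.
#' @param context_fractions Probabilities that a copy is genic-antisense,
#'   genic-sense, or non-genic.
#' @param peak_logistic `c(intercept, slope)` of the logistic model for
#'   peak placement on motif count.
#' @param expression_coupling log2 expression shift of genes hosting an
#'   antisense `common_high` copy relative to `common_low` hosts.
#' @param n_cells Cells per cell type in the expression table.
#' @param n_background_genes Genes with no hosted copy, appended after
#'   the repeat region.
#' @param genome_length Optional hard cap on genome length; generation
#'   errors if the requested content does not fit.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         subtypes = data.frame(
                           subtype = c("SVA_A", "SVA_B", "L1PA4", "LTR12C"),
                           family = c("SVA", "SVA", "L1", "LTR"),
                           n_copies = c(60L, 60L, 40L, 40L),
                           head_len = c(440L, 400L, 1200L, 700L),
                           tail_len = c(440L, 400L, 1200L, 700L),
                           vntr_units_consensus = c(3L, 3L, 0L, 0L),
                           stringsAsFactors = FALSE),
                         vntr_unit = VNTR_UNIT,
                         vntr_count_by_class = list(low = c(2L, 4L),
                                                    medium = c(5L, 8L),
                                                    high = c(9L, 12L)),
                         class_mixture = c(low = 0.3, medium = 0.3,
                                           high = 0.4),
                         donor_concordance = 0.6,
                         identical_donors = FALSE,
                         level_ranges = list(low = c(0.02, 0.12),
                                             medium = c(0.30, 0.50),
                                             high = c(0.70, 0.95)),
                         divergence = 0.02,
                         truncate_frac = 0.15,
                         gap_range = c(800L, 1500L),
                         background_level = 0.75,
                         read_depth = 20,
                         n_dmrs = 0L,
                         dmr_cpgs = c(15L, 20L),
                         dmr_levels = c(0.85, 0.15),
                         context_fractions = c(genic_antisense = 0.4,
                                               genic_sense = 0.1,
                                               non_genic = 0.5),
                         peak_logistic = c(intercept = -4, slope = 0.6),
                         expression_coupling = 2,
                         n_cells = 30L,
                         n_background_genes = 20L,
                         genome_length = NULL) {
  stopifnot(abs(sum(class_mixture) - 1) < 1e-9,
            abs(sum(context_fractions) - 1) < 1e-9,
            all(subtypes$n_copies > 0), read_depth > 0, n_cells > 0)
  cfg <- as.list(environment())
  class(cfg) <- "synth_config"
  cfg
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  hit <- which(runif(length(chars)) < rate)
  for (i in hit) {
    chars[i] <- sample(setdiff(DNA_BASES, chars[i]), 1L)
  }
  paste(chars, collapse = "")
}

revcomp_chr <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Generate a synthetic genome, repeat catalog and truth table
#'
#' Builds per-subtype consensus sequences, embeds diverged copies (with
#' class-coupled VNTR unit counts for VNTR subtypes, a fraction truncated
#' below the full-length boundary), places host genes so that configured
#' fractions of copies are genic antisense / sense / non-genic, appends
#' background genes, and implants `n_dmrs` DMR blocks in copy-free
#' background sequence. Deterministic given the config (including its
#' seed).
#'
#' @param config A [synth_config()] object.
#' @return A list with `genome` (named character vector, one
#'   chromosome), `repeats` (copy table as from
#'   [read_repeat_annotation()]), `genes` (interval table), `truth`
#'   (list: `copies` data frame with latent classes, levels, VNTR and
#'   motif truth, context; `dmrs` interval table with per-donor levels),
#'   `consensus_lengths` (named vector), `consensus_seqs`, and
#'   `motif_pwm` (the implanted motif as a [new_pwm()] object).
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  st <- config$subtypes
  unit_len <- nchar(config$vntr_unit)
  cons_len <- st$head_len + st$tail_len + st$vntr_units_consensus * unit_len
  names(cons_len) <- st$subtype
  cons_seq <- lapply(seq_len(nrow(st)), function(i) {
    list(head = random_dna(st$head_len[i]), tail = random_dna(st$tail_len[i]))
  })
  names(cons_seq) <- st$subtype

  n_total <- sum(st$n_copies)
  subtype_of <- rep(st$subtype, st$n_copies)
  fam_of <- rep(st$family, st$n_copies)
  classes <- names(config$class_mixture)

  pieces <- character(0)
  cursor <- 0L
  copy_rows <- list()
  truth_rows <- list()
  gene_rows <- list()
  for (i in seq_len(n_total)) {
    sub <- subtype_of[i]
    si <- match(sub, st$subtype)
    class_d1 <- sample(classes, 1L, prob = config$class_mixture)
    if (config$identical_donors) {
      class_d2 <- class_d1
    } else if (runif(1) < config$donor_concordance) {
      class_d2 <- class_d1
    } else {
      class_d2 <- sample(classes, 1L, prob = config$class_mixture)
    }
    lr1 <- config$level_ranges[[class_d1]]
    lr2 <- config$level_ranges[[class_d2]]
    level_d1 <- runif(1, lr1[1L], lr1[2L])
    level_d2 <- if (config$identical_donors) level_d1 else
      runif(1, lr2[1L], lr2[2L])
    has_vntr <- st$vntr_units_consensus[si] > 0L
    k <- if (has_vntr) {
      rng <- config$vntr_count_by_class[[class_d1]]
      sample(seq.int(rng[1L], rng[2L]), 1L)
    } else 0L
    body <- paste0(cons_seq[[sub]]$head,
                   paste(rep(config$vntr_unit, k), collapse = ""),
                   cons_seq[[sub]]$tail)
    body <- mutate_seq(body, config$divergence)
    truncated <- runif(1) < config$truncate_frac
    if (truncated) {
      cut <- round(runif(1, 0.5, 0.85) * cons_len[sub])
      body <- substr(body, 1L, min(cut, nchar(body)))
    }
    strand <- sample(c("+", "-"), 1L)
    genomic <- if (strand == "+") body else revcomp_chr(body)

    gap <- sample(seq.int(config$gap_range[1L], config$gap_range[2L]), 1L)
    pieces <- c(pieces, random_dna(gap))
    cursor <- cursor + gap
    start <- cursor
    end <- start + nchar(genomic)
    pieces <- c(pieces, genomic)
    cursor <- end

    # element-oriented VNTR span, then genomic coordinates
    vntr_start <- vntr_end <- NA_integer_
    if (has_vntr && !truncated) {
      e_from <- st$head_len[si]
      e_to <- e_from + k * unit_len
      if (strand == "+") {
        vntr_start <- start + e_from
        vntr_end <- start + e_to
      } else {
        vntr_start <- end - e_to
        vntr_end <- end - e_from
      }
    }

    context <- sample(names(config$context_fractions), 1L,
                      prob = config$context_fractions)
    host <- NA_character_
    if (context != "non_genic") {
      flank5 <- sample(100:300, 1L)
      flank3 <- sample(100:300, 1L)
      gstrand <- if (context == "genic_sense") strand else
        setdiff(c("+", "-"), strand)
      host <- sprintf("gene_%04d", i)
      gene_rows[[length(gene_rows) + 1L]] <- data.frame(
        chrom = "chrS", start = max(0L, start - flank5), end = end + flank3,
        strand = gstrand, name = host, stringsAsFactors = FALSE)
    }

    copy_rows[[length(copy_rows) + 1L]] <- data.frame(
      chrom = "chrS", start = start, end = end, strand = strand,
      subtype = sub, family = fam_of[i], stringsAsFactors = FALSE)
    truth_rows[[length(truth_rows) + 1L]] <- data.frame(
      subtype = sub, family = fam_of[i], chrom = "chrS",
      start = start, end = end, strand = strand,
      is_truncated = truncated,
      consensus_fraction = nchar(genomic) / cons_len[sub],
      vntr_units = if (has_vntr && !truncated) k else 0L,
      motif_count = if (has_vntr && !truncated) k else 0L,
      vntr_start = vntr_start, vntr_end = vntr_end,
      class_d1 = class_d1, class_d2 = class_d2,
      level_d1 = level_d1, level_d2 = level_d2,
      context = context, host_gene = host, stringsAsFactors = FALSE)
  }
  # trailing gap, then a background-gene region
  gap <- sample(seq.int(config$gap_range[1L], config$gap_range[2L]), 1L)
  pieces <- c(pieces, random_dna(gap))
  cursor <- cursor + gap
  if (config$n_background_genes > 0L) {
    for (g in seq_len(config$n_background_genes)) {
      glen <- sample(300:600, 1L)
      gene_rows[[length(gene_rows) + 1L]] <- data.frame(
        chrom = "chrS", start = cursor, end = cursor + glen,
        strand = sample(c("+", "-"), 1L),
        name = sprintf("bg_gene_%04d", g), stringsAsFactors = FALSE)
      pieces <- c(pieces, random_dna(glen + 200L))
      cursor <- cursor + glen + 200L
    }
  }
  genome_seq <- paste(pieces, collapse = "")
  if (!is.null(config$genome_length) &&
      nchar(genome_seq) > config$genome_length) {
    stop("requested copies exceed genome capacity (",
         nchar(genome_seq), " > ", config$genome_length, " bp)")
  }
  genome <- c(chrS = genome_seq)

  copies <- do.call(rbind, copy_rows)
  repeats <- rep_table(copies$chrom, copies$start, copies$end,
                       copies$strand, copies$subtype, copies$family)
  truth_copies <- do.call(rbind, truth_rows)
  truth_copies$copy_id <- repeats$copy_id

  truth_dmrs <- implant_dmrs(genome_seq, repeats, config)
  genes <- if (length(gene_rows) > 0L) do.call(rbind, gene_rows) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               strand = character(0), name = character(0))

  motif_pwm <- consensus_to_pwm("implanted_motif",
                                substr(config$vntr_unit, 1L, 12L))
  list(genome = genome, repeats = repeats, genes = reset_rownames(genes),
       truth = list(copies = reset_rownames(truth_copies),
                    dmrs = truth_dmrs),
       consensus_lengths = cons_len,
       consensus_seqs = cons_seq,
       motif_pwm = motif_pwm)
}

## choose n_dmrs runs of consecutive background CpGs, well separated
implant_dmrs <- function(genome_seq, repeats, config) {
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), level_d1 = numeric(0),
                      level_d2 = numeric(0), n_cpgs = integer(0),
                      stringsAsFactors = FALSE)
  if (config$n_dmrs <= 0L) return(empty)
  cg <- cpg_positions(genome_seq)
  in_copy <- rep(FALSE, length(cg))
  for (i in seq_len(nrow(repeats))) {
    in_copy[cg >= repeats$start[i] - 100L & cg < repeats$end[i] + 100L] <- TRUE
  }
  # background runs: indices of consecutive background CpGs
  bg <- !in_copy
  runs <- rle(bg)
  run_end <- cumsum(runs$lengths)
  run_start <- run_end - runs$lengths + 1L
  ok <- which(runs$values & runs$lengths >= max(config$dmr_cpgs) + 10L)
  if (length(ok) < config$n_dmrs) {
    stop("not enough background CpG runs to implant ", config$n_dmrs,
         " DMRs")
  }
  chosen <- sample(ok, config$n_dmrs)
  rows <- lapply(chosen, function(r) {
    m <- sample(seq.int(config$dmr_cpgs[1L], config$dmr_cpgs[2L]), 1L)
    i0 <- run_start[r] + sample.int(runs$lengths[r] - m + 1L, 1L) - 1L
    data.frame(chrom = "chrS", start = cg[i0], end = cg[i0 + m - 1L] + 2L,
               level_d1 = config$dmr_levels[1L],
               level_d2 = config$dmr_levels[2L],
               n_cpgs = m, stringsAsFactors = FALSE)
  })
  reset_rownames(do.call(rbind, rows))
}

## 0-based positions of the C of each CpG dinucleotide
cpg_positions <- function(genome_seq) {
  hits <- Biostrings::matchPattern("CG", Biostrings::DNAString(genome_seq))
  BiocGenerics::start(hits) - 1L
}

## near-deterministic PWM from a consensus word
consensus_to_pwm <- function(name, consensus, major = 0.91) {
  chars <- strsplit(consensus, "", fixed = TRUE)[[1L]]
  mat <- matrix((1 - major) / 3, length(chars), 4L,
                dimnames = list(NULL, DNA_BASES))
  mat[cbind(seq_along(chars), match(chars, DNA_BASES))] <- major
  new_pwm(name, mat)
}

#' Generate two-donor synthetic methylomes
#'
#' Every CpG of the genome receives, per donor, a Poisson read depth and
#' a binomial methylated-read count whose success probability is the
#' copy's true donor level inside repeat copies, the implanted DMR level
#' inside DMR blocks, and the background level elsewhere. Sites drawn
#' with zero depth are dropped (they would not appear in a coverage
#' file). Deterministic given the config.
#'
#' @param sim Output of [generate_genome()].
#' @param config The same [synth_config()] object.
#' @return List of two CpG tables (`donor1`, `donor2`) in the
#'   [read_cpg_table()] schema.
#' @export
generate_methylomes <- function(sim, config) {
  set.seed(config$seed + 1000L)
  cg <- cpg_positions(sim$genome[[1L]])
  tc <- sim$truth$copies
  td <- sim$truth$dmrs
  out <- list()
  for (donor in 1:2) {
    level <- rep(config$background_level, length(cg))
    lv <- tc[[paste0("level_d", donor)]]
    for (i in seq_len(nrow(tc))) {
      level[cg >= tc$start[i] & cg < tc$end[i]] <- lv[i]
    }
    if (nrow(td) > 0L) {
      dl <- td[[paste0("level_d", donor)]]
      for (i in seq_len(nrow(td))) {
        level[cg >= td$start[i] & cg < td$end[i]] <- dl[i]
      }
    }
    depth <- rpois(length(cg), config$read_depth)
    meth <- rbinom(length(cg), depth, level)
    keep <- depth > 0L
    out[[paste0("donor", donor)]] <- data.frame(
      chrom = "chrS", pos = cg[keep], meth_reads = meth[keep],
      total_reads = depth[keep], stringsAsFactors = FALSE)
  }
  out
}

#' Generate synthetic ChIP peaks coupled to motif count
#'
#' Each copy receives a peak with probability
#' `plogis(intercept + slope * motif_count)`. For copies with a VNTR the
#' peak covers the VNTR (motif cluster) span plus 50 bp flanks; for
#' others it covers the element's first 200 bp (5' end, strand-aware).
#'
#' @param sim Output of [generate_genome()].
#' @param config The same [synth_config()] object.
#' @return Interval table (`chrom`, `start`, `end`) of peaks; empty when
#'   no peak is drawn.
#' @export
generate_peaks <- function(sim, config) {
  set.seed(config$seed + 2000L)
  tc <- sim$truth$copies
  il <- config$peak_logistic
  p <- stats::plogis(il[["intercept"]] + il[["slope"]] * tc$motif_count)
  draw <- runif(nrow(tc)) < p
  rows <- lapply(which(draw), function(i) {
    if (!is.na(tc$vntr_start[i])) {
      s <- max(0L, tc$vntr_start[i] - 50L)
      e <- tc$vntr_end[i] + 50L
    } else if (tc$strand[i] == "+") {
      s <- tc$start[i]
      e <- min(tc$end[i], tc$start[i] + 200L)
    } else {
      s <- max(tc$start[i], tc$end[i] - 200L)
      e <- tc$end[i]
    }
    data.frame(chrom = tc$chrom[i], start = s, end = e,
               stringsAsFactors = FALSE)
  })
  if (length(rows) == 0L) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  reset_rownames(do.call(rbind, rows))
}

#' Generate synthetic per-cell expression coupled to antisense copies
#'
#' One cell type of `n_cells` cells. Genes hosting an antisense copy
#' whose two-donor concordance class is `common_high` are shifted up by
#' `expression_coupling` log2 units relative to the base mean;
#' `high_and_low` hosts receive half the shift; all other genes
#' (including background genes) stay at the base mean. Counts are
#' negative-binomial (size 10).
#'
#' @param sim Output of [generate_genome()].
#' @param config The same [synth_config()] object.
#' @param base_mean Base negative-binomial mean count (default 50).
#' @return List with `counts` (genes x cells matrix) and `cell_types`
#'   (named character vector).
#' @export
generate_expression <- function(sim, config, base_mean = 50) {
  set.seed(config$seed + 3000L)
  genes <- sim$genes
  tc <- sim$truth$copies
  conc <- concordance_class(tc$level_d1, tc$level_d2)
  mu <- setNames(rep(base_mean, nrow(genes)), genes$name)
  antisense <- tc$context == "genic_antisense" & !is.na(tc$host_gene)
  shift <- config$expression_coupling
  mu[tc$host_gene[antisense & conc == "common_high"]] <-
    base_mean * 2^shift
  mu[tc$host_gene[antisense & conc == "high_and_low"]] <-
    base_mean * 2^(shift / 2)
  cells <- sprintf("cell_%03d", seq_len(config$n_cells))
  counts <- matrix(rnbinom(nrow(genes) * config$n_cells,
                           mu = rep(mu, times = config$n_cells),
                           size = 10),
                   nrow = nrow(genes), ncol = config$n_cells,
                   dimnames = list(genes$name, cells))
  list(counts = counts,
       cell_types = setNames(rep("SSC", config$n_cells), cells))
}

#' Strand-aware sequence of each repeat copy
#'
#' Extracts each copy's genomic span and reverse-complements minus-strand
#' copies so the returned sequence reads 5' to 3' along the element.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param copies Repeat copy table.
#' @return Character vector of element-oriented sequences, named by
#'   `copy_id`.
#' @export
get_copy_seq <- function(genome, copies) {
  out <- vapply(seq_len(nrow(copies)), function(i) {
    s <- substring(genome[[copies$chrom[i]]],
                   copies$start[i] + 1L, copies$end[i])
    if (copies$strand[i] == "-") revcomp_chr(s) else s
  }, character(1))
  setNames(out, copies$copy_id)
}
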