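# small, fast generator configuration shared across generator tests
small_cfg <- function(seed = 3, ...) {
  synth_config(
    seed = seed,
    subtypes = data.frame(
      subtype = c("SVA_A", "L1PA4"), family = c("SVA", "L1"),
      n_copies = c(15L, 10L), head_len = c(200L, 500L),
      tail_len = c(200L, 500L), vntr_units_consensus = c(3L, 0L),
      stringsAsFactors = FALSE),
    gap_range = c(300L, 500L), n_background_genes = 5L, ...)
}

test_that("generation is a pure function of the configuration", {
  a <- generate_genome(small_cfg())
  b <- generate_genome(small_cfg())
  expect_identical(a$genome, b$genome)
  expect_identical(a$truth, b$truth)
  cfg <- small_cfg()
  expect_identical(generate_methylomes(a, cfg), generate_methylomes(b, cfg))
  expect_identical(generate_peaks(a, cfg), generate_peaks(b, cfg))
  expect_identical(generate_expression(a, cfg)$counts,
                   generate_expression(b, cfg)$counts)
  # a different seed changes the genome
  expect_false(identical(generate_genome(small_cfg(seed = 4))$genome,
                         a$genome))
})

test_that("truncated copies fall below the full-length boundary", {
  sim <- generate_genome(small_cfg(seed = 5, truncate_frac = 0.5))
  full <- select_full_length(sim$repeats, sim$consensus_lengths)
  truth <- sim$truth$copies
  trunc_ids <- truth$copy_id[truth$is_truncated]
  expect_true(length(trunc_ids) > 0)
  expect_false(any(trunc_ids %in% full$copy_id))
  # and non-truncated copies always pass (VNTR never shrinks them below 90%)
  expect_true(all(truth$copy_id[!truth$is_truncated] %in% full$copy_id))
})

test_that("VNTR and motif truth close the loop with the estimators", {
  cfg <- small_cfg(seed = 7, divergence = 0)
  sim <- generate_genome(cfg)
  truth <- sim$truth$copies
  keep <- truth$family == "SVA" & !truth$is_truncated
  seqs <- get_copy_seq(sim$genome, sim$repeats[keep, ])
  v <- vapply(seqs, estimate_vntr_units, integer(1),
              unit_consensus = cfg$vntr_unit)
  expect_equal(unname(v), truth$vntr_units[keep])
  m <- vapply(seqs, motif_count_per_copy, integer(1),
              pwm = sim$motif_pwm, p_threshold = 1e-6)
  expect_equal(unname(m), truth$motif_count[keep])
})

test_that("methylomes follow the latent per-copy levels", {
  # degenerate level: true level 1 gives site level 1 wherever covered
  cfg <- small_cfg(seed = 9, level_ranges = list(low = c(0, 0),
                                                 medium = c(0.5, 0.5),
                                                 high = c(1, 1)),
                   read_depth = 30)
  sim <- generate_genome(cfg)
  meth <- generate_methylomes(sim, cfg)
  expect_true(all(meth$donor1$meth_reads <= meth$donor1$total_reads))
  truth <- sim$truth$copies
  hi <- truth[truth$class_d1 == "high", ][1, ]
  in_hi <- meth$donor1$pos >= hi$start & meth$donor1$pos < hi$end
  lv <- meth$donor1$meth_reads[in_hi] / meth$donor1$total_reads[in_hi]
  expect_true(all(lv == 1))
  lo <- truth[truth$class_d1 == "low", ][1, ]
  in_lo <- meth$donor1$pos >= lo$start & meth$donor1$pos < lo$end
  expect_true(all(meth$donor1$meth_reads[in_lo] == 0))
})

test_that("identical-donor mode gives equal latent levels", {
  sim <- generate_genome(small_cfg(seed = 13, identical_donors = TRUE))
  expect_equal(sim$truth$copies$level_d1, sim$truth$copies$level_d2)
})

test_that("implanted DMR blocks land in copy-free background", {
  cfg <- synth_config(seed = 15, n_dmrs = 3)  # needs full-size gaps
  sim <- generate_genome(cfg)
  td <- sim$truth$dmrs
  expect_equal(nrow(td), 3L)
  expect_true(all(td$n_cpgs >= 15 & td$n_cpgs <= 20))
  hits <- GenomicRanges::findOverlaps(
    GenomicRanges::GRanges(td$chrom, IRanges::IRanges(td$start + 1, td$end)),
    GenomicRanges::GRanges(sim$repeats$chrom,
                           IRanges::IRanges(sim$repeats$start + 1,
                                            sim$repeats$end)))
  expect_length(hits, 0L)
})

test_that("peak placement probability rises with motif count", {
  cfg <- small_cfg(seed = 17)
  sim <- generate_genome(cfg)
  peaks <- generate_peaks(sim, cfg)
  truth <- sim$truth$copies
  ov <- rep(FALSE, nrow(truth))
  if (nrow(peaks) > 0) {
    hits <- GenomicRanges::findOverlaps(
      GenomicRanges::GRanges(truth$chrom,
                             IRanges::IRanges(truth$start + 1, truth$end)),
      GenomicRanges::GRanges(peaks$chrom,
                             IRanges::IRanges(peaks$start + 1, peaks$end)))
    ov[unique(S4Vectors::queryHits(hits))] <- TRUE
  }
  # many-motif copies overlap peaks more often than motif-free ones
  expect_gt(mean(ov[truth$motif_count >= 9]),
            mean(ov[truth$motif_count == 0]))
})

test_that("expression is shifted for antisense common_high hosts", {
  cfg <- small_cfg(seed = 19, expression_coupling = 3,
                   donor_concordance = 1)
  sim <- generate_genome(cfg)
  expr <- generate_expression(sim, cfg)
  truth <- sim$truth$copies
  conc <- concordance_class(truth$level_d1, truth$level_d2)
  anti <- truth$context == "genic_antisense"
  rpm <- expression_rpm(expr$counts, expr$cell_types)
  mean_rpm <- rowMeans(rpm)
  hi_genes <- truth$host_gene[anti & conc == "common_high"]
  lo_genes <- truth$host_gene[anti & conc == "common_low"]
  expect_gt(length(hi_genes), 0)
  expect_gt(length(lo_genes), 0)
  expect_gt(mean(mean_rpm[hi_genes]), mean(mean_rpm[lo_genes]))
})
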