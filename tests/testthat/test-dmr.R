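# two flat methylomes with an optional implanted block of differing level
two_donor_fixture <- function(n_sites = 200, depth = 30, bg = 0.7,
                              blocks = NULL) {
  pos <- seq(100, by = 50, length.out = n_sites)
  lv1 <- rep(bg, n_sites)
  lv2 <- rep(bg, n_sites)
  for (b in blocks) {
    lv1[b$from:b$to] <- b$d1
    lv2[b$from:b$to] <- b$d2
  }
  list(d1 = cpg_table(pos, round(depth * lv1), rep(depth, n_sites)),
       d2 = cpg_table(pos, round(depth * lv2), rep(depth, n_sites)),
       pos = pos)
}

test_that("identical methylomes yield no candidates or DMRs", {
  fx <- two_donor_fixture()
  cands <- candidate_dmrs(fx$d1, fx$d2)
  expect_equal(nrow(cands), 0L)
  expect_equal(nrow(refine_dmrs(cands, fx$d1, fx$d2)), 0L)
})

test_that("an implanted 20-CpG block is found as one candidate", {
  fx <- two_donor_fixture(blocks = list(list(from = 60, to = 79,
                                             d1 = 0.9, d2 = 0.1)))
  cands <- candidate_dmrs(fx$d1, fx$d2)
  expect_equal(nrow(cands), 1L)
  expect_equal(cands$start, fx$pos[60])
  expect_equal(cands$end, fx$pos[79] + 1L)
  # and two well-separated blocks give two candidates
  fx2 <- two_donor_fixture(blocks = list(
    list(from = 30, to = 49, d1 = 0.9, d2 = 0.1),
    list(from = 120, to = 139, d1 = 0.1, d2 = 0.9)))
  expect_equal(nrow(candidate_dmrs(fx2$d1, fx2$d2)), 2L)
})

test_that("refinement applies the run-length and difference filters", {
  ten <- cpg_table(seq(0, 90, by = 10), meth = c(rep(9, 10)),
                   total = rep(10, 10))
  ten2 <- cpg_table(seq(0, 90, by = 10), meth = rep(1, 10),
                    total = rep(10, 10))
  cand <- interval_table(0, 100)
  kept <- refine_dmrs(cand, ten, ten2)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$direction, "d1_hyper")
  expect_equal(kept$mean_d1 - kept$mean_d2, 0.8)
  # 9 analyzable CpGs -> rejected
  nine1 <- ten[1:9, ]
  nine2 <- ten2[1:9, ]
  expect_equal(nrow(refine_dmrs(cand, nine1, nine2)), 0L)
  # mean difference 0.39 -> rejected
  d1 <- cpg_table(seq(0, 90, by = 10), meth = rep(55, 10),
                  total = rep(100, 10))
  d2 <- cpg_table(seq(0, 90, by = 10), meth = rep(16, 10),
                  total = rep(100, 10))
  expect_equal(nrow(refine_dmrs(cand, d1, d2)), 0L)
})

test_that("a low-depth site interrupts the successive run", {
  pos <- seq(0, 100, by = 10)  # 11 sites, middle one under-covered in d2
  d1 <- cpg_table(pos, meth = rep(9, 11), total = rep(10, 11))
  d2 <- cpg_table(pos, meth = rep(0, 11),
                  total = c(rep(10, 5), 4, rep(10, 5)))
  cand <- interval_table(0, 101)
  expect_equal(nrow(refine_dmrs(cand, d1, d2)), 0L)
  # the relaxed "total" interpretation keeps it (10 analyzable in total)
  expect_equal(nrow(refine_dmrs(cand, d1, d2, successive = "total")), 1L)
  # a CpG observed in only one sample interrupts too
  d2b <- cpg_table(pos[-6], meth = rep(0, 10), total = rep(10, 10))
  expect_equal(nrow(refine_dmrs(cand, d1, d2b)), 0L)
})

test_that("refinement is anti-monotone in its thresholds", {
  set.seed(17)
  fx <- two_donor_fixture(blocks = list(
    list(from = 40, to = 58, d1 = 0.95, d2 = 0.25),
    list(from = 100, to = 113, d1 = 0.2, d2 = 0.75)))
  cands <- candidate_dmrs(fx$d1, fx$d2)
  n_base <- nrow(refine_dmrs(cands, fx$d1, fx$d2,
                             min_diff = 0.3, min_successive = 8))
  for (md in c(0.4, 0.5, 0.7)) {
    expect_lte(nrow(refine_dmrs(cands, fx$d1, fx$d2, min_diff = md,
                                min_successive = 8)), n_base)
  }
  for (ms in c(12, 16, 25)) {
    expect_lte(nrow(refine_dmrs(cands, fx$d1, fx$d2, min_diff = 0.3,
                                min_successive = ms)), n_base)
  }
})

test_that("DMR annotation counts family overlap per direction", {
  dmrs <- data.frame(chrom = "chr1", start = c(0, 100, 200),
                     end = c(50, 150, 250),
                     mean_d1 = c(0.9, 0.9, 0.1), mean_d2 = c(0.1, 0.1, 0.9),
                     n_cpgs_both = 10L,
                     direction = c("d1_hyper", "d1_hyper", "d2_hyper"))
  reps <- copy_row(start = 40, end = 60)  # overlaps first DMR only
  ann <- annotate_dmrs(dmrs, reps, family = "SVA")
  expect_equal(ann$summary$n, c(2L, 1L))
  expect_equal(ann$summary$n_overlapping, c(1L, 0L))
  expect_equal(ann$summary$fraction, c(0.5, 0))
  # abutting half-open intervals do not overlap
  abut <- copy_row(start = 50, end = 100)
  expect_equal(annotate_dmrs(dmrs, abut)$summary$n_overlapping, c(0L, 0L))
  # no repeats at all
  none <- annotate_dmrs(dmrs, copy_row(start = 0, end = 10,
                                       family = "L1"))
  expect_equal(none$summary$fraction, c(0, 0))
})
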