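test_that("overlap fractions count copies hit by any peak", {
  by_class <- list(
    high = do.call(rbind, lapply(seq(0, 4600, by = 100), function(s)
      copy_row(start = s, end = s + 50))),
    low = do.call(rbind, lapply(seq(10000, 10700, by = 100), function(s)
      copy_row(start = s, end = s + 50))))
  # peaks hit 30 of the 47 high copies, none of the 8 low copies
  peaks <- interval_table(start = seq(0, 2900, by = 100) + 20,
                          end = seq(0, 2900, by = 100) + 40)
  tab <- overlap_fraction(by_class, peaks)
  expect_equal(tab$n_copies, c(47L, 8L))
  expect_equal(tab$n_overlapping, c(30L, 0L))
  expect_equal(tab$fraction, c(30 / 47, 0))
  expect_equal(round(100 * tab$fraction[1], 1), 63.8)
  # no peaks at all -> all fractions zero
  none <- overlap_fraction(by_class, interval_table(integer(0), integer(0)))
  expect_equal(none$fraction, c(0, 0))
})

test_that("overlap fraction is invariant to peak order and splitting", {
  set.seed(3)
  by_class <- list(all = do.call(rbind, lapply(seq(0, 9000, by = 300),
                                               function(s)
    copy_row(start = s, end = s + 200))))
  peaks <- interval_table(start = sample(0:9000, 40),
                          end = sample(0:9000, 40) + 120)
  peaks <- peaks[peaks$end > peaks$start, ]
  base <- overlap_fraction(by_class, peaks)$fraction
  shuf <- overlap_fraction(by_class, peaks[sample(nrow(peaks)), ])$fraction
  expect_equal(base, shuf)
  # split every peak into two abutting halves
  mid <- floor((peaks$start + peaks$end) / 2)
  halves <- rbind(interval_table(peaks$start, mid),
                  interval_table(mid, peaks$end))
  halves <- halves[halves$end > halves$start, ]
  expect_equal(overlap_fraction(by_class, halves)$fraction, base)
})

test_that("association tests match hand-computed chi-square", {
  # expected counts (7,3,7,3): chi2 = 2*(4/7) + 2*(4/3) = 3.8095
  res <- class_association_test(matrix(c(5, 9, 5, 1), 2))
  expect_equal(res$statistic, 80 / 21, tolerance = 1e-6)
  expect_equal(res$df, 1)
  expect_equal(res$method, "two_proportion")
  # identical proportions -> p = 1
  eq <- class_association_test(matrix(c(10, 10, 5, 5), 2))
  expect_equal(eq$p_value, 1, tolerance = 1e-9)
  # three classes -> Pearson chi-square with df = 2
  three <- class_association_test(matrix(c(2, 10, 20, 30, 22, 12), 3))
  expect_equal(three$df, 2)
  expect_equal(three$method, "chi_square")
  expect_warning(class_association_test(matrix(c(1, 0, 30, 20), 2)),
                 "expected cell")
})

test_that("metaprofiles are length-normalized and strand-flipped", {
  copies <- rbind(copy_row(start = 0, end = 1000, strand = "+"),
                  copy_row(start = 2000, end = 3000, strand = "+"))
  # signal only in the first 10% of each copy
  sig <- interval_table(start = c(0, 2000), end = c(100, 2100))
  prof <- metaprofile(copies, sig, n_bins = 10)
  expect_equal(prof, c(1, rep(0, 9)))
  # uniform coverage -> flat profile
  flat <- metaprofile(copies, interval_table(0, 4000), n_bins = 10)
  expect_equal(flat, rep(1, 10))
  # minus-strand copy with signal at its genomic end = element 5' end
  minus <- copy_row(start = 0, end = 1000, strand = "-")
  prof_m <- metaprofile(minus, interval_table(900, 1000), n_bins = 10)
  expect_equal(prof_m, c(1, rep(0, 9)))
  expect_warning(metaprofile(copy_row(start = 0, end = 5), sig,
                             n_bins = 10), "skipped")
})

test_that("RPM normalization and type means follow their definitions", {
  counts <- matrix(c(10, 90, 30, 70), 2,
                   dimnames = list(c("g1", "g2"), c("c1", "c2")))
  types <- c(c1 = "SSC", c2 = "SSC")
  rpm <- expression_rpm(counts, types)
  expect_equal(rpm["g1", "SSC"], mean(c(1e5, 3e5)))
  expect_equal(rpm["g2", "SSC"], mean(c(9e5, 7e5)))
  expect_equal(sum(rpm[, "SSC"]) , 1e6)  # per-cell RPM sums to 1e6
  counts[, 2] <- 0
  expect_error(expression_rpm(counts, types), "zero total")
})

test_that("group comparisons control the familywise error rate", {
  set.seed(8)
  same <- list(a = rnorm(25), b = rnorm(25))
  expect_gt(group_comparison(same)$p_adj, 0.05)
  apart <- list(a = rnorm(50), b = rnorm(50, 5), c = rnorm(50, 5.2))
  tk <- group_comparison(apart)
  expect_equal(attr(tk, "method"), "tukey_hsd")
  expect_lt(tk$p_adj[tk$comparison == "b-a"], 1e-6)
  # adjusted p >= unadjusted pairwise p
  raw <- stats::t.test(apart$b, apart$c)$p.value
  expect_gte(tk$p_adj[tk$comparison == "c-b"], raw * 0.99)
  dn <- group_comparison(apart, "vs_control")
  expect_equal(attr(dn, "method"), "dunnett_mvt")
  expect_equal(nrow(dn), 2L)  # many-to-one: two comparisons vs control
  expect_true(all(dn$p_adj < 1e-4))
  expect_error(group_comparison(list(a = 1, b = c(1, 2))), "at least 2")
})
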