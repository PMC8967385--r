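test_that("full-length selection is inclusive at the 90% boundary", {
  copies <- rbind(copy_row(start = 0, end = 900),
                  copy_row(start = 2000, end = 2899),
                  copy_row(start = 5000, end = 6100))
  kept <- select_full_length(copies, c(SVA_A = 1000))
  expect_equal(kept$start, c(0, 5000))  # 900/1000 kept, 899/1000 excluded
  expect_equal(kept$consensus_fraction, c(0.9, 1.1))
})

test_that("solo-LTR copies are measured against the LTR consensus", {
  solo <- copy_row(start = 0, end = 950, subtype = "HERVX")
  solo$is_solo_ltr <- TRUE
  cons <- c(HERVX = 9000, HERVX_LTR = 1000)
  expect_equal(nrow(select_full_length(solo, cons)), 1L)  # 95% of LTR
  # without the LTR entry the full-element consensus applies
  expect_equal(nrow(select_full_length(solo, c(HERVX = 9000))), 0L)
})

test_that("a missing consensus length is a configuration error", {
  expect_error(select_full_length(copy_row(start = 0, end = 500),
                                  c(L1HS = 6000)),
               "no consensus length")
})

test_that("selection is idempotent and monotone in min_fraction", {
  set.seed(7)
  copies <- do.call(rbind, lapply(1:50, function(i) {
    s <- i * 2000
    copy_row(start = s, end = s + sample(500:1500, 1))
  }))
  cons <- c(SVA_A = 1200)
  for (f in c(0.5, 0.7, 0.9, 1.0)) {
    once <- select_full_length(copies, cons, f)
    twice <- select_full_length(once, cons, f)
    expect_equal(once$copy_id, twice$copy_id)
  }
  sizes <- vapply(c(0.5, 0.7, 0.9, 1.0), function(f)
    nrow(select_full_length(copies, cons, f)), numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("genomic context follows strand and >= 1 bp overlap", {
  genes <- interval_table(start = c(1000, 5000), end = c(3000, 6000),
                          strand = c("+", "-"),
                          name = c("geneA", "geneB"))
  copies <- rbind(copy_row(start = 1500, end = 2000, strand = "-"),
                  copy_row(start = 2999, end = 3500, strand = "+"),
                  copy_row(start = 8000, end = 8500, strand = "+"))
  ctx <- classify_genomic_context(copies, genes)
  expect_equal(ctx$context,
               c("genic_antisense", "genic_sense", "non_genic"))
  expect_equal(ctx$host_gene, c("geneA", "geneA", NA))  # 1 bp overlap counts
})

test_that("largest overlap wins, ties to the smaller gene start", {
  genes <- interval_table(start = c(0, 900), end = c(1200, 3000),
                          strand = c("+", "-"),
                          name = c("small", "large"))
  copy <- copy_row(start = 1000, end = 2000, strand = "+")
  expect_equal(classify_genomic_context(copy, genes)$host_gene, "large")
  # exact tie: both overlap by 500 bp -> smaller start wins
  genes2 <- interval_table(start = c(100, 1500), end = c(1500, 2900),
                           strand = c("+", "-"),
                           name = c("first", "second"))
  expect_equal(classify_genomic_context(copy, genes2)$host_gene, "first")
})

test_that("context classification is invariant to gene order", {
  set.seed(11)
  genes <- interval_table(start = seq(0, 9000, by = 1000),
                          end = seq(800, 9800, by = 1000),
                          strand = sample(c("+", "-"), 10, replace = TRUE),
                          name = paste0("g", 1:10))
  copies <- do.call(rbind, lapply(seq(100, 9100, by = 500), function(s)
    copy_row(start = s, end = s + 300,
             strand = sample(c("+", "-"), 1))))
  a <- classify_genomic_context(copies, genes)
  b <- classify_genomic_context(copies, genes[sample(nrow(genes)), ])
  expect_equal(a$context, b$context)
  expect_equal(a$host_gene, b$host_gene)
})

test_that("a strandless copy overlapping a gene is an error", {
  genes <- interval_table(start = 0, end = 1000, strand = "+", name = "g")
  copy <- copy_row(start = 100, end = 300, strand = ".")
  expect_error(classify_genomic_context(copy, genes), "orientation")
})

test_that("context fractions per class sum to one", {
  copies <- rbind(copy_row(start = 0, end = 100),
                  copy_row(start = 200, end = 300),
                  copy_row(start = 400, end = 500),
                  copy_row(start = 600, end = 700))
  copies$context <- c("genic_antisense", "genic_antisense",
                      "non_genic", "non_genic")
  tab <- context_fraction_by_class(copies, rep("common_high", 4))
  expect_equal(tab$genic_antisense, 0.5)
  expect_equal(tab$genic_sense, 0.0)
  expect_equal(tab$non_genic, 0.5)
  expect_equal(tab$genic_antisense + tab$genic_sense + tab$non_genic, 1)
})
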