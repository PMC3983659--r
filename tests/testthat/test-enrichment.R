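test_that("fold enrichment of predictions is the ratio of proportions", {
  expect_equal(fold_enrichment_counts(40, 1000, 10, 1000), 4)
  expect_equal(fold_enrichment_counts(30, 600, 25, 500), 1)
  expect_equal(fold_enrichment_counts(0, 100, 5, 100), 0)
  expect_warning(inf <- fold_enrichment_counts(5, 100, 0, 100), "infinite")
  expect_identical(inf, Inf)
  expect_error(fold_enrichment_counts(1, 0, 1, 10), "positive")
  # scale invariance
  expect_equal(fold_enrichment_counts(40, 1000, 10, 1000),
               fold_enrichment_counts(120, 3000, 30, 3000))
})

test_that("Fisher's exact test matches hypergeometric enumeration", {
  expect_equal(fisher_exact(matrix(c(2, 0, 0, 2), 2)), 1 / 3)
  expect_equal(fisher_exact(matrix(c(5, 5, 5, 5), 2)), 1)
  expect_warning(p0 <- fisher_exact(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
                 "degenerate")
  expect_equal(p0, 1)
  set.seed(20)
  for (i in 1:20) {
    tab <- matrix(rpois(4, 8), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact(tab), fisher_enum(tab), tolerance = 1e-9)
  }
})

test_that("fraction-of-loci fold reproduces printed ratios", {
  expect_equal(fold_loci_fraction(120, 200, 86, 200), 120 / 86 , tolerance = 1e-12)
  expect_equal(round(fold_loci_fraction(120, 200, 86, 200), 2), 1.40)
  expect_equal(fold_loci_fraction(50, 100, 50, 100), 1)
  expect_warning(expect_identical(fold_loci_fraction(3, 10, 0, 10), Inf))
  expect_error(fold_loci_fraction(11, 10, 2, 10), "exceed")
  # common scaling cancels
  expect_equal(fold_loci_fraction(12, 20, 9, 20),
               fold_loci_fraction(36, 60, 27, 60))
})

test_that("score-shift test is an exact rank statistic on small samples", {
  expect_equal(score_shift_test(c(1, 2, 3), c(3, 2, 1)), 1)
  expect_equal(score_shift_test(c(4, 5, 6), c(1, 2, 3)), 0.1)
  # invariance under common monotone transforms
  set.seed(21)
  a <- rnorm(12); b <- rnorm(15, 1)
  expect_equal(score_shift_test(a, b), score_shift_test(exp(a), exp(b)))
  expect_error(score_shift_test(numeric(0), b), "non-empty")
})

test_that("randomization p-values behave at the saturation and empty limits", {
  chrom_sizes <- c(chr1 = 10000L)
  q <- intervals("chr1", c(100L, 4000L), c(200L, 4100L))
  all_marks <- intervals("chr1", 0L, 10000L)
  r <- randomization_pvalue(q, all_marks, chrom_sizes, n_rand = 50, seed = 1)
  expect_equal(r$observed, 2L)
  expect_true(all(r$randomized == 2L))
  expect_equal(r$empirical_p, 1)     # every randomization ties
  none <- intervals(character(), integer(), integer())
  r0 <- randomization_pvalue(q, none, chrom_sizes, n_rand = 50, seed = 1)
  expect_equal(r0$observed, 0L)
  expect_equal(r0$empirical_p, 1)
  expect_gte(r0$empirical_p, 1 / 51)
})

test_that("randomized overlap matches the binomial expectation on a uniform genome", {
  set.seed(22)
  chrom_sizes <- c(chr1 = 100000L)
  ms <- seq(0L, 99000L, by = 10000L)
  marks <- intervals("chr1", ms, ms + 3000L)      # 30% coverage
  qs <- sample.int(99000L, 60)
  q <- intervals("chr1", qs, qs + 1L)              # 1-bp queries
  r <- randomization_pvalue(q, marks, chrom_sizes, n_rand = 500, seed = 5)
  expect_equal(length(r$randomized), 500)
  p_cov <- coverage_bases(marks) / 100000
  mu <- 60 * p_cov
  se <- sqrt(60 * p_cov * (1 - p_cov) / 500)
  expect_lt(abs(mean(r$randomized) - mu), 3 * se + 0.05)
  # seed reproducibility
  r2 <- randomization_pvalue(q, marks, chrom_sizes, n_rand = 500, seed = 5)
  expect_identical(r$randomized, r2$randomized)
  expect_error(randomization_pvalue(intervals("chr1", 0L, 99999L),
                                    marks, c(chr1 = 100000L),
                                    excluded = intervals("chr1", 2L, 99999L)),
               "allowed space")
})

test_that("GC log-ratio handles bases and degenerate input", {
  expect_equal(gc_log_ratio("ACGT", "ACGT"), 0)
  expect_equal(gc_log_ratio("GCAT", c("GCAAAT", "AA"), base = 2), 1)
  a <- c("GGCC", "ATGC"); b <- c("ATAT", "GCGC")
  expect_equal(gc_log_ratio(a, b), gc_log_ratio(a, b, base = 2) * log(2),
               tolerance = 1e-12)
  expect_error(gc_log_ratio("NNN", "ACGT"), "informative")
  expect_error(gc_log_ratio("GC", "ATAT"), "zero")
})

test_that("the locus-level report assembles counts consistently", {
  cand <- intervals("chr1", seq(0L, 1900L, 100L), seq(50L, 1950L, 100L),
                    sequence = "A")
  cand$locus_id <- rep(1:4, each = 5)
  cand$score <- c(rep(2, 4), -1,            # locus 1 (high): 4 called
                  rep(2, 2), rep(-1, 3),    # locus 2 (high): 2 called
                  rep(-1, 5),               # locus 3 (low): 0 called
                  2, rep(-1, 4))            # locus 4 (low): 1 called
  ps <- call_predictions(cand, 0)
  rep <- enrichment_report(ps, c(`1` = "high", `2` = "high",
                                 `3` = "low", `4` = "low"))
  expect_equal(unname(rep$counts["pred_high"]), 6)
  expect_equal(unname(rep$counts["pred_low"]), 1)
  expect_equal(rep$fold_predictions, (6 / 10) / (1 / 10))
  expect_equal(rep$fold_loci_fraction, (2 / 2) / (1 / 2))
  expect_true(rep$fisher_p <= 1 && rep$fisher_p > 0)
  expect_true(rep$score_shift_p <= 1)
})
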