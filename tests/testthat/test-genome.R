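tx <- function(gene, start, end, strand = "+", chrom = "chr1") {
  data.frame(gene_symbol = gene, chrom = chrom, start = as.integer(start),
             end = as.integer(end), strand = strand, stringsAsFactors = FALSE)
}

test_that("transcript clustering joins chains of overlaps and nothing else", {
  d <- rbind(tx("a", 10, 100), tx("b", 50, 200))
  cl <- cluster_transcripts(d)
  expect_equal(nrow(cl), 1)
  expect_equal(c(cl$start, cl$end), c(10L, 200L))

  d2 <- rbind(tx("a", 10, 100), tx("b", 200, 300))
  expect_equal(nrow(cluster_transcripts(d2)), 2)

  # chain of pairwise overlaps (union-find oracle: all pairs connected)
  d3 <- rbind(tx("a", 0, 50), tx("b", 40, 90), tx("c", 80, 120))
  cl3 <- cluster_transcripts(d3)
  expect_equal(nrow(cl3), 1)
  expect_equal(c(cl3$start, cl3$end), c(0L, 120L))

  # abutting transcripts ([0,50) and [50,100)) share no base: two clusters
  expect_equal(nrow(cluster_transcripts(rbind(tx("a", 0, 50),
                                              tx("b", 50, 100)))), 2)
})

test_that("clustering is invariant to input order and ignores strand", {
  set.seed(1)
  s <- sample.int(5000L, 40)
  d <- do.call(rbind, lapply(seq_along(s), function(i)
    tx(paste0("g", i), s[i], s[i] + sample(300, 1),
       strand = sample(c("+", "-"), 1))))
  ref <- cluster_transcripts(d)[, c("chrom", "start", "end")]
  for (r in 1:3) {
    perm <- cluster_transcripts(d[sample.int(nrow(d)), ])
    expect_equal(perm[, c("chrom", "start", "end")], ref)
  }
})

test_that("loci split intergenic gaps at the floor midpoint and tile exactly", {
  cl <- cluster_transcripts(rbind(tx("a", 100, 200), tx("b", 400, 500)))
  loci <- define_loci(cl, c(chr1 = 600L))
  expect_equal(loci$start, c(0L, 300L))
  expect_equal(loci$end, c(300L, 600L))

  one <- define_loci(cluster_transcripts(tx("a", 100, 200)), c(chr1 = 600L))
  expect_equal(c(one$start, one$end), c(0L, 600L))

  # odd gap: floor rule puts the extra base on the right locus
  odd <- define_loci(cluster_transcripts(rbind(tx("a", 0, 10),
                                               tx("b", 11, 20))),
                     c(chr1 = 20L))
  expect_equal(odd$end[1], 10L)
  expect_equal(odd$start[2], 10L)
})

test_that("locus tiling covers every base exactly once (property)", {
  set.seed(9)
  for (rep in 1:3) {
    s <- sort(sample.int(90000L, 25))
    d <- do.call(rbind, lapply(seq_along(s), function(i)
      tx(paste0("g", i), s[i], s[i] + sample(2000, 1))))
    loci <- define_loci(cluster_transcripts(d), c(chr1 = 100000L))
    loci <- loci[order(loci$start), ]
    expect_equal(loci$start[1], 0L)
    expect_equal(loci$end[nrow(loci)], 100000L)
    expect_equal(loci$start[-1], loci$end[-nrow(loci)])  # no gap, no overlap
  }
})

test_that("promoters span -2.5 kb / +0.5 kb strand-aware with clipping", {
  expect_equal(unname(define_promoter(10000L, "+", 1e6)), c(7500L, 10500L))
  expect_equal(unname(define_promoter(10000L, "-", 1e6)), c(9501L, 12501L))
  expect_equal(unname(define_promoter(1000L, "+", 1e6)), c(0L, 1500L))
  expect_error(define_promoter(-5L, "+", 1e6), "bounds")
  expect_error(define_promoter(1e6, "+", 1e6), "bounds")
})

test_that("promoter definition is mirror-symmetric between strands", {
  # on a chromosome of length 2T, position tss on + mirrors (2T-1-tss) on -
  T2 <- 40000L
  for (tss in c(5000L, 17321L)) {
    pp <- define_promoter(tss, "+", T2)
    pm <- define_promoter(T2 - 1L - tss, "-", T2)
    expect_equal(unname(pm), c(T2 - pp[["end"]], T2 - pp[["start"]]))
  }
  pr <- promoter_regions(rbind(tx("a", 10000, 16000, "+"),
                               tx("b", 10000, 16000, "-")),
                         c(chr1 = 1e6))
  expect_equal(pr$end - pr$start, c(3000L, 3000L))
  expect_true(all(pr$start <= pr$tss & pr$tss < pr$end))
})

test_that("CNE extraction thresholds, merges abutting blocks and drops short runs", {
  genome <- c(chr1 = random_dna(1000))
  blocks <- intervals("chr1", c(0, 100, 300, 600), c(100, 180, 420, 640),
                      identity = c(0.8, 0.8, 0.75, 0.9))
  cnes <- extract_cnes(blocks, genome, min_identity = 0.70, min_length = 100L)
  # first two abut -> one element [0,180); [600,640) is below min_length
  expect_equal(cnes$start, c(0L, 300L))
  expect_equal(cnes$end, c(180L, 420L))
  expect_equal(nchar(cnes$sequence), cnes$end - cnes$start)
  expect_equal(cnes$sequence[2], substr(genome[["chr1"]], 301, 420))

  low <- intervals("chr1", 0, 250, identity = 0.69)
  expect_equal(nrow(extract_cnes(low, genome)), 0)
  kept <- extract_cnes(intervals("chr1", 0, 250, identity = 0.75), genome)
  expect_equal(nrow(kept), 1)
})

test_that("CNE extraction limits: zero threshold merges everything, >1 empties", {
  genome <- c(chr1 = random_dna(2000))
  set.seed(3)
  s <- sample.int(1800L, 30)
  blocks <- intervals("chr1", s, s + 60L,
                      identity = runif(30, 0.3, 0.99))
  all_in <- extract_cnes(blocks, genome, min_identity = 0, min_length = 1L)
  expect_identical(all_in[, c("chrom", "start", "end")],
                   merge_intervals(blocks)[, c("chrom", "start", "end")])
  expect_equal(nrow(extract_cnes(blocks, genome, min_identity = 1 + 1e-9)), 0)
  expect_error(extract_cnes(intervals("chr1", 0, 10, identity = 1.2), genome),
               "\\[0, 1\\]")
})

test_that("distance to nearest TSS matches the exhaustive scan", {
  d <- rbind(tx("a", 150, 900), tx("b", 250, 700), tx("c", 50, 80, "-"))
  iv <- intervals("chr1", 100, 200)
  expect_equal(distance_to_nearest_tss(iv, d), 0)  # tss 150 inside
  expect_equal(distance_to_nearest_tss(intervals("chr1", 100, 200),
                                       tx("b", 250, 700)), 50)
  expect_error(distance_to_nearest_tss(intervals("chr9", 0, 10), d),
               "no transcript")
  set.seed(5)
  many <- do.call(rbind, lapply(1:50, function(i)
    tx(paste0("g", i), sample.int(10000L, 1), 10010 + i,
       sample(c("+", "-"), 1))))
  many$end <- many$start + sample.int(500L, 50)
  iv <- intervals("chr1", 4000, 4400)
  tsss <- with_tss(many)$tss
  oracle <- min(vapply(tsss, function(t)
    if (t >= 4000 && t < 4400) 0L else min(abs(4000L - t), abs(t - 4400L)),
    integer(1)))
  expect_equal(distance_to_nearest_tss(iv, many), oracle)
})

test_that("assign_loci places elements by midpoint into the tiling", {
  loci <- define_loci(cluster_transcripts(rbind(tx("a", 100, 200),
                                                tx("b", 400, 500))),
                      c(chr1 = 600L))
  got <- assign_loci(intervals("chr1", c(10, 290, 310, 590),
                               c(20, 299, 320, 600)), loci)
  expect_equal(got, c(1L, 1L, 2L, 2L))
})
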