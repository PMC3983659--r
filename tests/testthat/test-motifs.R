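test_that("JASPAR counts gain a 0.25 pseudocount per cell", {
  f <- withr::local_tempfile(lines = c(
    ">M1 TEST",
    "A [ 10  0 ]",
    "C [  0 10 ]",
    "G [  0  0 ]",
    "T [  0  0 ]"))
  lib <- parse_motifs(f, "jaspar")
  expect_length(lib, 1)
  m <- lib[[1]]
  expect_equal(attr(m, "motif_id"), "M1")
  expect_equal(unclass(m)[1, ], c(A = 10.25, C = 0.25, G = 0.25, T = 0.25) / 11)
  expect_equal(unclass(m)[2, ], c(A = 0.25, C = 10.25, G = 0.25, T = 0.25) / 11)
})

test_that("TRANSFAC blocks and MEME matrices parse; MEME probabilities pass through", {
  ft <- withr::local_tempfile(lines = c(
    "AC M00001", "XX", "ID V$TEST", "XX",
    "P0      A      C      G      T",
    "01      2      0      8      0      G",
    "02      0     10      0      0      C",
    "//"))
  lib <- parse_motifs(ft, "transfac")
  expect_length(lib, 1)
  expect_equal(unname(unclass(lib[[1]])[1, "G"]), 8.25 / 11)

  fm <- withr::local_tempfile(lines = c(
    "MEME version 4", "", "ALPHABET= ACGT", "",
    "MOTIF MX",
    "letter-probability matrix: alength= 4 w= 2 nsites= 20 E= 0",
    " 0.500000 0.250000 0.125000 0.125000",
    " 0.100000 0.200000 0.300000 0.400000"))
  mm <- parse_motifs(fm, "meme")[[1]]
  expect_equal(unclass(mm)[1, ], c(A = .5, C = .25, G = .125, T = .125),
               tolerance = 1e-9)
  # empty file -> empty library
  fe <- withr::local_tempfile(lines = character())
  expect_length(parse_motifs(fe, "jaspar"), 0)
  # duplicate ids rejected
  fd <- withr::local_tempfile(lines = c(
    ">M1", "A [ 1 ]", "C [ 1 ]", "G [ 1 ]", "T [ 1 ]",
    ">M1", "A [ 1 ]", "C [ 1 ]", "G [ 1 ]", "T [ 1 ]"))
  expect_error(parse_motifs(fd, "jaspar"), "duplicate")
})

test_that("log-odds scores are log2(prob/bg) and demand positive probabilities", {
  m <- pwm(matrix(c(0.5, 0.25, 0.125, 0.125), 1), "m")
  lo <- log_odds(m, background_model())
  expect_equal(unname(lo[1, ]), c(1, 0, -1, -1))
  set.seed(2)
  r <- random_pwm(4)
  bgf <- c(0.3, 0.2, 0.2, 0.3)
  expect_equal(log_odds(r, background_model(bgf)),
               log2(sweep(unclass(r), 2, bgf, "/")),
               ignore_attr = TRUE)
  zero <- pwm(matrix(c(1, 0, 0, 0), 1), "z")
  expect_error(log_odds(zero), "pseudocount")
})

test_that("score distribution matches exhaustive k-mer enumeration", {
  bg <- background_model()
  # L = 1: four atoms
  m1 <- pwm(matrix(c(0.7, 0.1, 0.1, 0.1), 1), "m1")
  d1 <- score_distribution(log_odds(m1, bg), bg)
  expect_equal(score_pvalue(d1, log2(0.7 / 0.25)), 0.25)
  expect_equal(score_pvalue(d1, log2(0.1 / 0.25)), 1)
  # L = 2 and L = 6 against brute force over the identically-binned matrix
  set.seed(11)
  for (L in c(2, 6)) {
    m <- random_pwm(L)
    lom <- log_odds(m, bg)
    bw <- 1e-3
    d <- score_distribution(lom, bg, bw)
    lom_r <- round(lom / bw) * bw
    for (t in quantile(replicate(5, sum(apply(lom, 1, sample, size = 1))),
                       c(.2, .5, .9))) {
      expect_equal(score_pvalue(d, t),
                   tail_enum(lom_r, as.numeric(bg),
                             (round(t / bw) - 0.5) * bw),
                   tolerance = 1e-6)
    }
  }
  expect_error(score_distribution(log_odds(m1, bg), bg, bin_width = 0),
               "positive")
})

test_that("scanning finds consensus hits, respects N and strand symmetry", {
  m <- sharp_pwm("ACCGTAAC", "s8")  # non-palindromic consensus
  bg <- background_model()
  cons <- "ACCGTAAC"
  hits <- scan_motif(cons, m, bg)
  expect_gte(nrow(hits), 1)
  expect_true(any(hits$start == 0 & hits$strand == "+"))
  expect_true(all(hits$pvalue <= 1e-4))
  expect_true(all(hits$end - hits$start == 8))

  set.seed(21)
  seq1 <- paste0(random_dna(40), cons, random_dna(40), cons, random_dna(15))
  fwd <- scan_motif(seq1, m, bg)
  rev <- scan_motif(revcomp(seq1), m, bg)
  expect_equal(nrow(fwd), nrow(rev))
  expect_equal(sum(fwd$strand == "+"), sum(rev$strand == "-"))

  expect_equal(nrow(scan_motif(strrep("N", 50), m, bg)), 0)
  expect_equal(nrow(scan_motif("ACG", m, bg)), 0)  # shorter than motif
  # an N anywhere in the window suppresses that window only
  withN <- paste0(cons, "N", cons)
  expect_equal(nrow(scan_motif(withN, m, bg)), 2)
})

test_that("hit p-values agree with the exact distribution queries", {
  set.seed(31)
  m <- random_pwm(5)
  bg <- background_model(c(0.3, 0.2, 0.2, 0.3))
  sc <- motif_scanner(list(m), bg, p_threshold = 0.05)
  s <- random_dna(300)
  hits <- scan_motif(s, m, bg, p_threshold = 0.05)
  expect_gt(nrow(hits), 0)
  f <- hits$strand == "+"
  expect_equal(hits$pvalue[f],
               score_pvalue(sc$motifs[[1]]$distF, hits$score[f]))
  expect_equal(hits$pvalue[!f],
               score_pvalue(sc$motifs[[1]]$distR, hits$score[!f]))
  # and with the enumeration oracle (L = 5 <= 6) on the binned matrix
  lomF_r <- round(sc$motifs[[1]]$lomF / 1e-3) * 1e-3
  for (i in head(which(f), 3)) {
    expect_equal(hits$pvalue[i],
                 tail_enum(lomF_r, as.numeric(bg),
                           (round(hits$score[i] / 1e-3) - 0.5) * 1e-3),
                 tolerance = 1e-6)
  }
})

test_that("count_hits counts planted copies and is chunking-consistent", {
  m <- sharp_pwm("GATTACAGGA", "pl")
  bg <- background_model()
  set.seed(41)
  seq1 <- paste0(random_dna(30), "GATTACAGGA", random_dna(25),
                 "GATTACAGGA", random_dna(30), "GATTACAGGA", random_dna(10))
  counts <- count_hits(seq1, list(m), bg)
  expect_equal(unname(counts["pl"]), 3L)
  expect_equal(unname(count_hits("", list(m), bg)), 0L)

  # splitting with L-1 overlap partitions the windows exactly
  n <- nchar(seq1); L <- 10
  for (k in c(25, 60, 101)) {
    left <- substr(seq1, 1, k + L - 1)
    right <- substr(seq1, k + 1, n)
    expect_equal(count_hits(left, list(m), bg) +
                   count_hits(right, list(m), bg),
                 count_hits(seq1, list(m), bg))
  }
})

test_that("motif GC content averages P(G) + P(C) over positions", {
  allA <- pwm(matrix(rep(c(1 - 3e-9, 1e-9, 1e-9, 1e-9), 3), 3, 4,
                     byrow = TRUE), "a")
  expect_equal(motif_gc(allA), 0, tolerance = 1e-8)
  allG <- pwm(matrix(rep(c(1e-9, 1e-9, 1 - 3e-9, 1e-9), 2), 2, 4,
                     byrow = TRUE), "g")
  expect_equal(motif_gc(allG), 1, tolerance = 1e-8)
  two <- pwm(rbind(c(0, 0.5, 0.5, 0), c(1, 0, 0, 0)), "t")
  expect_equal(motif_gc(two), 0.5)
})

test_that("PWM permutation preserves per-position multisets and the seed determines it", {
  m <- pwm(rbind(c(0.7, 0.1, 0.1, 0.1), c(0.4, 0.3, 0.2, 0.1)), "p")
  set.seed(5)
  p1 <- permute_pwm(m)
  for (i in 1:2)
    expect_equal(sort(unclass(p1)[i, ]), sort(unclass(m)[i, ]),
                 ignore_attr = TRUE)
  set.seed(5)
  expect_identical(unclass(permute_pwm(m)), unclass(p1))
  # L = 1: expected GC over all arrangements of a symmetric multiset is 0.5
  m1 <- pwm(matrix(c(0.6, 0.2, 0.15, 0.05), 1), "q")
  mean_gc <- mean(vapply(1:200, function(i) {
    set.seed(i); motif_gc(permute_pwm(m1))
  }, numeric(1)))
  expect_equal(mean_gc, 0.5, tolerance = 0.08)
})

test_that("rank-sum test: exact small-sample path matches enumeration facts", {
  # identical multisets -> p = 1
  expect_equal(rank_sum_test(c(1, 2, 3), c(1, 2, 3))$p.value, 1)
  # complete separation, 3 vs 3: two extreme splits of C(6,3) = 20
  t1 <- rank_sum_test(c(5, 6, 7), c(0, 0, 1))
  expect_equal(t1$p.value, 2 / 20)
  # symmetry: swapping flips the statistic, keeps p
  t2 <- rank_sum_test(c(0, 0, 1), c(5, 6, 7))
  expect_equal(t2$statistic, -t1$statistic)
  expect_equal(t2$p.value, t1$p.value)
  expect_error(rank_sum_test(numeric(0), 1), "non-empty")
  # large-sample path is the tie-corrected normal approximation
  set.seed(6)
  x <- rpois(30, 3); y <- rpois(35, 4)
  expect_equal(rank_sum_test(x, y)$p.value,
               wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
})

test_that("motif over-representation compares per-sequence hit counts", {
  m <- sharp_pwm("TTGACCTTGA", "ov")
  bg <- background_model()
  set.seed(51)
  rich <- replicate(3, paste0(random_dna(20), "TTGACCTTGA", random_dna(20),
                              "TTGACCTTGA", random_dna(20)))
  poor <- replicate(3, random_dna(70))
  r <- motif_overrepresentation(rich, poor, m, bg)
  expect_gt(r$statistic, 0)
  expect_lte(r$p.value, 0.2)
  same <- motif_overrepresentation(rich, rich, m, bg)
  expect_equal(same$p.value, 1)
  expect_error(motif_overrepresentation(character(), poor, m, bg),
               "non-empty")
})
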