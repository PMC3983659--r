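# Independent oracles and small fixture builders shared across tests.

# per-base boolean mask of an interval set on a toy chromosome
bitmask <- function(x, chrom, len) {
  m <- logical(len)
  d <- x[x$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(d))) m[(d$start[i] + 1):d$end[i]] <- TRUE
  m
}

# exhaustive-pair AUC
auc_pairs <- function(pos, neg) {
  wins <- 0
  for (p in pos) for (n in neg)
    wins <- wins + if (p > n) 1 else if (p == n) 0.5 else 0
  wins / (length(pos) * length(neg))
}

# two-sided Fisher p by full enumeration over tables with fixed margins
fisher_enum <- function(tab) {
  a <- tab[1, 1]; r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1]); n <- r1 + r2
  supp <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(supp, r1, r2, c1)
  sum(probs[probs <= dhyper(a, r1, r2, c1) * (1 + 1e-7)])
}

# exact motif-score tail by enumerating all 4^L k-mers
tail_enum <- function(lom, bg, t) {
  L <- nrow(lom)
  kmers <- as.matrix(expand.grid(rep(list(1:4), L)))
  sc <- apply(kmers, 1, function(k) sum(lom[cbind(seq_len(L), k)]))
  pr <- apply(kmers, 1, function(k) prod(bg[k]))
  sum(pr[sc >= t])
}

random_pwm <- function(L, id = "rnd") {
  m <- matrix(rgamma(L * 4, 1) + 0.05, L, 4)
  promsig::pwm(m / rowSums(m), id, "synthetic")
}

# a PWM with a single dominant base per position (consensus recoverable)
sharp_pwm <- function(bases, id = "sharp", p = 0.94) {
  idx <- match(strsplit(bases, "")[[1]], c("A", "C", "G", "T"))
  m <- matrix((1 - p) / 3, length(idx), 4)
  m[cbind(seq_along(idx), idx)] <- p
  promsig::pwm(m, id, "synthetic")
}

revcomp <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# labeled toy feature matrix: positives loaded on the first feature,
# negatives on the second; `per` elements per promoter
toy_training_fm <- function(n_prom_pos = 6, n_prom_neg = 6, per = 2,
                            p = 8, sep = 3) {
  n_pos <- n_prom_pos * per; n_neg <- n_prom_neg * per
  counts <- matrix(rpois((n_pos + n_neg) * p, 0.2), n_pos + n_neg, p)
  counts[seq_len(n_pos), 1] <- counts[seq_len(n_pos), 1] + sep
  counts[n_pos + seq_len(n_neg), 2] <- counts[n_pos + seq_len(n_neg), 2] + sep
  colnames(counts) <- paste0("m", seq_len(p))
  elements <- promsig::intervals("chr1", seq_len(n_pos + n_neg) * 1000L,
                                 seq_len(n_pos + n_neg) * 1000L + 200L)
  promoter_of <- c(lapply(rep(seq_len(n_prom_pos), each = per),
                          function(i) paste0("hi", i)),
                   lapply(rep(seq_len(n_prom_neg), each = per),
                          function(i) paste0("lo", i)))
  promsig::feature_matrix(counts, elements,
                          label = c(rep(1, n_pos), rep(-1, n_neg)),
                          promoter_of = promoter_of)
}
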