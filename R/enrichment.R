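# Locus-level and genome-level statistics evaluating a prediction set:
# ratio-of-proportions fold enrichments, Fisher and rank-sum tests, mark
# overlaps with randomization p-values, and GC log-ratios.

#' Fold enrichment of predictions (ratio of two proportions)
#'
#' `(pred_high / scanned_high) / (pred_low / scanned_low)`: the proportion
#' of scanned sequences called in loci of highly expressed genes over the
#' same proportion in loci of lowly expressed genes.
#'
#' @param pred_high,scanned_high predictions / scanned sequences in high
#'   loci.
#' @param pred_low,scanned_low same for low loci.
#' @return the fold ratio; `Inf` (with a warning) when `pred_low == 0` and
#'   `pred_high > 0`; 0 when `pred_high == 0`.
#' @export
fold_enrichment_counts <- function(pred_high, scanned_high,
                                   pred_low, scanned_low) {
  if (scanned_high <= 0 || scanned_low <= 0)
    stop("scanned counts must be positive")
  if (pred_high == 0) return(0)
  if (pred_low == 0) {
    warning("no predictions in control loci; fold enrichment is infinite")
    return(Inf)
  }
  (pred_high / scanned_high) / (pred_low / scanned_low)
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Exact p by summing hypergeometric probabilities at most that of the
#' observed table. Degenerate tables (an all-zero margin) return p = 1
#' with a warning.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return two-sided p-value.
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == 2), all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    warning("degenerate margin; p = 1")
    return(1)
  }
  stats::fisher.test(table)$p.value
}

#' Fold enrichment of the fraction of loci with predictions
#'
#' `(hit_high / tot_high) / (hit_low / tot_low)` where `hit` counts loci
#' containing at least one prediction and `tot` counts loci containing at
#' least one scanned sequence.
#'
#' @param hit_high,tot_high,hit_low,tot_low locus counts.
#' @return the ratio of the two fractions (`Inf` with warning when
#'   `hit_low == 0` and `hit_high > 0`).
#' @export
fold_loci_fraction <- function(hit_high, tot_high, hit_low, tot_low) {
  if (tot_high <= 0 || tot_low <= 0) stop("locus totals must be positive")
  if (hit_high > tot_high || hit_low > tot_low)
    stop("hits cannot exceed totals")
  if (hit_high == 0) return(0)
  if (hit_low == 0) {
    warning("no control locus hit; fold is infinite")
    return(Inf)
  }
  (hit_high / tot_high) / (hit_low / tot_low)
}

#' Score-shift test between two candidate score sets
#'
#' Two-sided rank-sum comparison of prediction scores in high- versus
#' low-expression loci; invariant under any common monotone transform.
#'
#' @param scores_high,scores_low numeric score vectors (non-empty).
#' @return two-sided p-value.
#' @export
score_shift_test <- function(scores_high, scores_low) {
  rank_sum_test(scores_high, scores_low)$p.value
}

#' Randomization test for overlap with a mark set
#'
#' Each of `n_rand` randomizations places `nrow(queries)` intervals of
#' identical lengths uniformly in the allowed space (chromosomes minus
#' `excluded`), counts overlaps with the merged marks, and compares with
#' the observed count. The empirical p-value uses add-one smoothing,
#' `p = (1 + #{rand >= obs}) / (n_rand + 1)`, so it is never zero.
#' Randomized intervals are not collision-checked against each other.
#'
#' @param queries query intervals.
#' @param marks mark intervals (merged internally).
#' @param chrom_sizes named integer vector.
#' @param excluded intervals unavailable for placement (may be empty).
#' @param n_rand number of randomizations (default 1000).
#' @param seed RNG seed.
#' @return list of class `"overlap_report"`: `observed`,
#'   `randomized` (vector of counts), `empirical_p`, `fold`.
#' @export
randomization_pvalue <- function(queries, marks, chrom_sizes,
                                 excluded = NULL, n_rand = 1000L,
                                 seed = 1L) {
  observed <- overlap_count(queries, marks)
  if (is.null(excluded))
    excluded <- intervals(character(), integer(), integer())
  allowed <- complement_intervals(excluded, chrom_sizes)
  seg_len <- allowed$end - allowed$start
  qlen <- queries$end - queries$start
  if (max(qlen) > max(seg_len))
    stop("allowed space smaller than the longest query")
  marks_m <- merge_intervals(marks)
  set.seed(as.integer(seed))
  randomized <- vapply(seq_len(n_rand), function(r) {
    # placements per query: segment chosen with probability proportional
    # to the number of valid start positions it offers
    starts <- integer(length(qlen)); chroms <- character(length(qlen))
    for (q in seq_along(qlen)) {
      wt <- pmax(0, seg_len - qlen[q] + 1)
      i <- sample.int(nrow(allowed), 1, prob = wt)
      s <- allowed$start[i] + sample.int(seg_len[i] - qlen[q] + 1, 1) - 1L
      starts[q] <- s; chroms[q] <- allowed$chrom[i]
    }
    rnd <- data.frame(chrom = chroms, start = starts,
                      end = starts + qlen, strand = ".",
                      stringsAsFactors = FALSE)
    overlap_count(rnd, marks_m)
  }, integer(1))
  structure(list(observed = observed, randomized = randomized,
                 empirical_p = (1 + sum(randomized >= observed)) /
                   (n_rand + 1),
                 fold = observed / mean(randomized)),
            class = "overlap_report")
}

#' Log-ratio of GC content between two sequence sets
#'
#' GC content is computed over the concatenated non-N bases of each set;
#' the default base is e (natural log).
#'
#' @param seqs_a,seqs_b character vectors of sequences.
#' @param base logarithm base (e or 2).
#' @return `log_base(GC_a / GC_b)`.
#' @export
gc_log_ratio <- function(seqs_a, seqs_b, base = exp(1)) {
  gc <- function(seqs) {
    v <- strsplit(toupper(paste(seqs, collapse = "")), "")[[1]]
    n <- sum(v %in% DNA_BASES)
    if (n == 0) stop("sequence set has no informative base")
    sum(v %in% c("G", "C")) / n
  }
  a <- gc(seqs_a); b <- gc(seqs_b)
  if (b == 0) stop("GC content of the reference set is zero")
  log(a / b, base = base)
}

#' Locus-level enrichment report for a prediction set
#'
#' Computes, for high- versus low-expression loci: the ratio-of-proportions
#' fold enrichment of prediction counts with its Fisher p-value, the
#' fold enrichment of the fraction of loci containing predictions with its
#' Fisher p-value, and the rank-sum p for the shift of prediction scores.
#'
#' @param pred_set a `"prediction_set"` whose candidates carry `locus_id`
#'   and `score`.
#' @param locus_class named vector mapping locus id to `"high"` / `"low"`
#'   (other values ignored).
#' @return list of class `"enrichment_report"`.
#' @export
enrichment_report <- function(pred_set, locus_class) {
  cand <- pred_set$candidates
  if (!"locus_id" %in% names(cand)) stop("candidates carry no locus map")
  cls <- locus_class[as.character(cand$locus_id)]
  called <- cand$score > pred_set$threshold & !is.na(cand$score)
  ph <- sum(called & cls == "high", na.rm = TRUE)
  pl <- sum(called & cls == "low", na.rm = TRUE)
  sh <- sum(cls == "high", na.rm = TRUE)
  sl <- sum(cls == "low", na.rm = TRUE)
  fold_pred <- fold_enrichment_counts(ph, sh, pl, sl)
  fisher_p <- fisher_exact(matrix(c(ph, sh - ph, pl, sl - pl), 2,
                                  byrow = TRUE))
  # loci with >= 1 scanned sequence / >= 1 prediction
  loci_high <- unique(cand$locus_id[cls == "high" & !is.na(cls)])
  loci_low <- unique(cand$locus_id[cls == "low" & !is.na(cls)])
  hit_high <- length(unique(cand$locus_id[called & cls == "high" &
                                            !is.na(cls)]))
  hit_low <- length(unique(cand$locus_id[called & cls == "low" &
                                           !is.na(cls)]))
  fold_frac <- fold_loci_fraction(hit_high, length(loci_high),
                                  hit_low, length(loci_low))
  frac_p <- fisher_exact(matrix(c(hit_high, length(loci_high) - hit_high,
                                  hit_low, length(loci_low) - hit_low),
                                2, byrow = TRUE))
  shift_p <- if (ph > 0 && pl > 0)
    score_shift_test(cand$score[called & cls == "high" & !is.na(cls)],
                     cand$score[called & cls == "low" & !is.na(cls)])
  else NA_real_
  structure(list(fold_predictions = fold_pred, fisher_p = fisher_p,
                 fold_loci_fraction = fold_frac, fraction_p = frac_p,
                 score_shift_p = shift_p,
                 counts = c(pred_high = ph, scanned_high = sh,
                            pred_low = pl, scanned_low = sl,
                            hit_high = hit_high, tot_high = length(loci_high),
                            hit_low = hit_low, tot_low = length(loci_low))),
            class = "enrichment_report")
}

#' @export
print.enrichment_report <- function(x, ...) {
  cat(sprintf(paste0("enrichment_report: fold(predictions) = %.2f",
                     " (p = %.3g); fold(loci fraction) = %.2f (p = %.3g)\n"),
              x$fold_predictions, x$fisher_p,
              x$fold_loci_fraction, x$fraction_p))
  invisible(x)
}
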