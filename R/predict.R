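# Genome-wide application of a trained model: candidate selection (distal
# CNEs or sliding windows), scoring, and the min(0, delta) calling rule.

#' Select conserved distal candidates
#'
#' CNEs overlapping any promoter exclusion zone (the training -2.5 kb /
#' +0.5 kb region around a TSS) by >= 1 bp are removed; survivors are
#' annotated with the locus containing them.
#'
#' @param cnes conserved elements (with sequences).
#' @param promoters promoter interval data.frame (the exclusion zones).
#' @param loci optional locus table from [define_loci()] for locus
#'   annotation.
#' @return candidate data.frame: the surviving CNE rows plus `origin` and
#'   (when loci are given) `locus_id`.
#' @export
select_conserved_candidates <- function(cnes, promoters, loci = NULL) {
  keep <- !overlaps_any(cnes, promoters)
  out <- cnes[keep, , drop = FALSE]
  out$origin <- rep("cne", nrow(out))
  if (!is.null(loci)) out$locus_id <- assign_loci(out, loci)
  rownames(out) <- NULL
  out
}

#' Tile promoter-free windows across the genome
#'
#' Windows of `size` bp shifted by `step` bp tile each chromosome; any
#' window overlapping a promoter zone is excluded, and the trailing partial
#' window is dropped. Defaults (230/115) give half-overlapping windows the
#' length of an average human-mouse conserved block.
#'
#' @param genome named character vector of chromosome sequences.
#' @param promoters promoter exclusion zones.
#' @param size,step window geometry in bp (`size >= step >= 1`).
#' @param loci optional locus table for annotation.
#' @return candidate data.frame with `sequence`, `origin = "window"`.
#' @export
make_windows <- function(genome, promoters, size = 230L, step = 115L,
                         loci = NULL) {
  stopifnot(size >= step, step >= 1)
  chrom_sizes <- vapply(genome, nchar, integer(1))
  out <- lapply(names(genome), function(chr) {
    len <- chrom_sizes[[chr]]
    if (len < size) return(NULL)
    starts <- seq.int(0L, len - size, by = step)
    data.frame(chrom = chr, start = starts, end = starts + as.integer(size),
               strand = ".", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out) || nrow(out) == 0)
    return(intervals(character(), integer(), integer(),
                     sequence = character(), origin = character()))
  out <- out[!overlaps_any(out, promoters), , drop = FALSE]
  out$sequence <- substr(genome[out$chrom], out$start + 1L, out$end)
  out$origin <- "window"
  if (!is.null(loci)) out$locus_id <- assign_loci(out, loci)
  rownames(out) <- NULL
  out
}

#' Score candidate sequences with a trained model
#'
#' Builds the motif-count features of each candidate and attaches the raw
#' linear decision score. A pure function of its inputs.
#'
#' @param model a `"linear_model"`.
#' @param candidates candidate data.frame with `sequence`.
#' @param library motif library or [motif_scanner()]; its motif ordering
#'   must match the model's.
#' @param bg background model (`NULL`: estimated from the candidates).
#' @param p_threshold scan threshold.
#' @return `candidates` with a `score` column.
#' @export
score_candidates <- function(model, candidates, library, bg = NULL,
                             p_threshold = 1e-4) {
  fm <- build_features(candidates, library, bg, p_threshold)
  if (!is.null(model$motif_ids) &&
      !identical(model$motif_ids, fm$motif_ids))
    stop("model and library motif ordering differ")
  candidates$score <- decision_score(model, fm$counts)
  candidates
}

#' Prediction threshold from control scores
#'
#' `delta` is the lowest score among the top 5% (by default) of the control
#' scores, with `k = max(1, floor(top_fraction * N))`; the calling
#' threshold is `s = min(0, delta)`.
#'
#' @param control_scores numeric scores of the control candidates.
#' @param top_fraction fraction defining the control tail (default 0.05).
#' @return list with `s`, `delta`, `k`, `n_controls`.
#' @export
compute_threshold <- function(control_scores, top_fraction = 0.05) {
  n <- length(control_scores)
  if (n == 0) stop("no control scores")
  k <- max(1L, floor(top_fraction * n))
  delta <- sort(control_scores, decreasing = TRUE)[k]
  list(s = min(0, delta), delta = delta, k = k, n_controls = n)
}

#' Call enhancer predictions
#'
#' A scored candidate is a prediction iff its score is strictly greater
#' than the threshold `s` (ties at `s` never pass).
#'
#' @param scored scored candidate data.frame.
#' @param s calling threshold (from [compute_threshold()]).
#' @param model_id optional model identifier carried into the set.
#' @return list of class `"prediction_set"`: `predictions` (the called
#'   rows), `candidates` (all scored rows), `threshold`, `model_id`.
#' @export
call_predictions <- function(scored, s, model_id = NA_character_) {
  if (nrow(scored) > 0 && !"score" %in% names(scored))
    stop("candidates are not scored")
  called <- scored[!is.na(scored$score) & scored$score > s, , drop = FALSE]
  rownames(called) <- NULL
  structure(list(predictions = called, candidates = scored,
                 threshold = s, model_id = model_id),
            class = "prediction_set")
}

#' @export
print.prediction_set <- function(x, ...) {
  cat(sprintf("prediction_set: %d predictions of %d candidates (s = %.4g)\n",
              nrow(x$predictions), nrow(x$candidates), x$threshold))
  invisible(x)
}
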