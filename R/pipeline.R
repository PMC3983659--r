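# End-to-end orchestration: train a tissue model from genome + annotation
# + conservation + expression, scan distal candidates with it, and evaluate
# the predictions at locus level. All stages consume the in-memory bundle
# shape produced by generate_synthetic(); file-based runs load the same
# shape through the io readers.

#' Load a study bundle from a directory
#'
#' Reads the files written by [write_bundle()] (or equivalently organized
#' real data) back into the in-memory bundle shape used by the `run_*`
#' functions. Motif libraries are supplied separately.
#'
#' @param dir directory containing `genome.fa`, `transcripts.tsv`,
#'   `conservation.bed`, `expression.tsv` (and optionally
#'   `truth_enhancers.bed`).
#' @return list with `genome`, `chrom_sizes`, `transcripts`,
#'   `conservation`, `expression`, `truth`.
#' @export
load_bundle <- function(dir) {
  genome <- read_genome_fasta(file.path(dir, "genome.fa"))
  out <- list(genome = genome,
              chrom_sizes = vapply(genome, nchar, integer(1)),
              transcripts = read_transcripts(file.path(dir, "transcripts.tsv")),
              conservation = read_bed(file.path(dir, "conservation.bed"),
                                      identity_score = TRUE),
              expression = read_expression(file.path(dir, "expression.tsv")))
  tpath <- file.path(dir, "truth_enhancers.bed")
  if (file.exists(tpath)) out$truth <- read_bed(tpath)
  out
}

select_gene_sets <- function(expression, tissue, n_top, n_bottom) {
  if (!tissue %in% names(expression))
    stop("tissue column not found: ", tissue)
  v <- expression[[tissue]]
  if (length(unique(v)) < 2)
    stop("expression column is constant; cannot rank genes")
  if (nrow(expression) < n_top + n_bottom)
    stop("fewer genes than n_top + n_bottom")
  ord <- order(v, decreasing = TRUE)
  list(high = expression$gene_symbol[ord[seq_len(n_top)]],
       low = expression$gene_symbol[rev(ord)[seq_len(n_bottom)]])
}

#' Train a tissue-specific promoter model
#'
#' Selects the `n_top` most and `n_bottom` least expressed genes in the
#' focal tissue, builds their promoters and the CNEs within them, scans
#' the motif library, runs the double-loop cross-validation and trains the
#' final consistent-set classifier.
#'
#' @param bundle study bundle (from [generate_synthetic()] or
#'   [load_bundle()]).
#' @param library motif library (list of PWMs); defaults to the bundle's
#'   own library when present.
#' @param tissue expression column name (default `"tissue_a"`).
#' @param n_top,n_bottom gene-set sizes (default 200 each).
#' @param min_identity,min_cne_length CNE extraction parameters.
#' @param p_threshold motif scan threshold.
#' @param cfg a [train_config()].
#' @return list: `model` (with background and metadata attached),
#'   `cv` (a `"cv_report"`), `features` (the training matrix), `log`
#'   (set cardinalities).
#' @export
run_train <- function(bundle, library = bundle$library,
                      tissue = "tissue_a", n_top = 200L, n_bottom = 200L,
                      min_identity = 0.70, min_cne_length = 100L,
                      p_threshold = 1e-4, cfg = train_config()) {
  sets <- select_gene_sets(bundle$expression, tissue, n_top, n_bottom)
  tx <- bundle$transcripts
  prom <- promoter_regions(tx, bundle$chrom_sizes)
  prom_high <- prom[prom$gene_symbol %in% sets$high, , drop = FALSE]
  prom_low <- prom[prom$gene_symbol %in% sets$low, , drop = FALSE]
  cnes <- extract_cnes(bundle$conservation, bundle$genome,
                       min_identity, min_cne_length)
  bg <- estimate_background(cnes$sequence)
  fm <- assemble_training_set(prom_high, prom_low, cnes, library,
                              bg = bg, p_threshold = p_threshold)
  cv <- double_loop_cv(fm, cfg)
  model <- train_final_model(fm, gamma = cv$chosen_gamma, cfg = cfg)
  model$bg <- as.numeric(bg)
  model$p_threshold <- p_threshold
  model$tissue <- tissue
  list(model = model, cv = cv, features = fm,
       log = c(n_high_promoters = nrow(prom_high),
               n_low_promoters = nrow(prom_low),
               n_cnes = nrow(cnes),
               n_positive = sum(fm$label == 1),
               n_negative = sum(fm$label == -1),
               consistent_size = model$consistent_size))
}

#' Scan distal candidates and call enhancer predictions
#'
#' Scores the conserved distal candidates (and, optionally, sliding
#' windows) with a trained model; the calling threshold `s = min(0, delta)`
#' is derived from the scores of candidates lying in the loci of the
#' lowly expressed gene set (the control loci), separately per candidate
#' class.
#'
#' @param bundle study bundle.
#' @param model trained `"linear_model"` carrying `bg` and `p_threshold`.
#' @param library motif library matching the model.
#' @param use_windows also scan promoter-free sliding windows
#'   (default `FALSE`).
#' @param top_fraction control-tail fraction for the threshold.
#' @param min_identity,min_cne_length CNE extraction parameters (must
#'   match training).
#' @param tissue,n_top,n_bottom gene-set definition used to derive
#'   high/low locus classes when the bundle does not record them; defaults
#'   to the model's tissue and the training set sizes.
#' @return a `"prediction_set"`; its candidates carry `locus_id` and
#'   `score`, the set carries `threshold` and `delta`.
#' @export
run_scan <- function(bundle, model, library = bundle$library,
                     use_windows = FALSE, top_fraction = 0.05,
                     min_identity = 0.70, min_cne_length = 100L,
                     tissue = NULL, n_top = 200L, n_bottom = 200L) {
  if (!identical(vapply(library, motif_id, character(1)),
                 model$motif_ids))
    stop("model was trained on a different motif library")
  prom <- promoter_regions(bundle$transcripts, bundle$chrom_sizes)
  cnes <- extract_cnes(bundle$conservation, bundle$genome,
                       min_identity, min_cne_length)
  cand <- select_conserved_candidates(cnes, prom, bundle$loci)
  if (is.null(bundle$loci)) {
    loci <- define_loci(cluster_transcripts(bundle$transcripts),
                        bundle$chrom_sizes)
    cand$locus_id <- assign_loci(cand, loci)
  }
  if (use_windows) {
    win <- make_windows(bundle$genome, prom, loci = bundle$loci)
    keep <- intersect(names(cand), names(win))
    cand <- rbind(cand[, keep, drop = FALSE], win[, keep, drop = FALSE])
  }
  bg <- if (!is.null(model$bg)) background_model(model$bg)
        else NULL
  scored <- score_candidates(model, cand, library, bg = bg,
                             p_threshold = model$p_threshold %||% 1e-4)
  lc <- locus_classes(bundle, tissue = tissue %||% model$tissue %||%
                        "tissue_a", n_top = n_top, n_bottom = n_bottom)
  control <- scored$score[lc[as.character(scored$locus_id)] == "low"]
  control <- control[!is.na(control)]
  thr <- compute_threshold(control, top_fraction)
  ps <- call_predictions(scored, thr$s, model_id = model$tissue %||% "model")
  ps$delta <- thr$delta
  ps$n_controls <- thr$n_controls
  ps
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' High/low class of each locus
#'
#' Returns the generator-recorded locus classes when present; otherwise
#' derives them from the expression table (top `n_top` genes' loci are
#' `"high"`, bottom `n_bottom` are `"low"`, the rest `"other"`).
#'
#' @param bundle study bundle.
#' @param tissue expression column.
#' @param n_top,n_bottom gene-set sizes.
#' @return named character vector over locus (cluster) ids.
#' @export
locus_classes <- function(bundle, tissue = "tissue_a",
                          n_top = 200L, n_bottom = 200L) {
  if (!is.null(bundle$locus_class)) return(bundle$locus_class)
  sets <- select_gene_sets(bundle$expression, tissue, n_top, n_bottom)
  clusters <- cluster_transcripts(bundle$transcripts)
  gene_of <- vapply(clusters$members, function(i)
    bundle$transcripts$gene_symbol[i[1]], character(1))
  cls <- ifelse(gene_of %in% sets$high, "high",
                ifelse(gene_of %in% sets$low, "low", "other"))
  stats::setNames(cls, clusters$cluster_id)
}

#' Evaluate a prediction set at locus level
#'
#' Computes the Table-1-style statistics (fold enrichment of predictions
#' with Fisher p, fold enrichment of the fraction of loci with predictions
#' with Fisher p, score-shift rank-sum p) and, when truth enhancers are
#' available, precision and recall; optional mark sets add randomization
#' overlap reports.
#'
#' @param bundle study bundle.
#' @param pred_set a `"prediction_set"` from [run_scan()].
#' @param marks optional named list of mark interval sets.
#' @param n_rand randomizations per mark set.
#' @param seed RNG seed for the randomization test.
#' @param tissue,n_top,n_bottom locus-class derivation (see
#'   [locus_classes()]).
#' @return list: `enrichment` (an `"enrichment_report"`), `truth`
#'   (precision/recall when available), `overlaps` (named list of
#'   `"overlap_report"`s, omitted when no marks are given).
#' @export
run_evaluate <- function(bundle, pred_set, marks = NULL, n_rand = 1000L,
                         seed = 1L, tissue = "tissue_a",
                         n_top = 200L, n_bottom = 200L) {
  if (!"locus_id" %in% names(pred_set$candidates))
    stop("predictions carry no locus map")
  enr <- enrichment_report(pred_set, locus_classes(bundle, tissue = tissue,
                                                   n_top = n_top,
                                                   n_bottom = n_bottom))
  out <- list(enrichment = enr)
  if (!is.null(bundle$truth) && nrow(bundle$truth) > 0)
    out$truth <- truth_eval(pred_set, bundle$truth)
  if (!is.null(marks)) {
    excl <- promoter_regions(bundle$transcripts, bundle$chrom_sizes)
    out$overlaps <- lapply(marks, function(m)
      randomization_pvalue(pred_set$predictions, m, bundle$chrom_sizes,
                           excluded = excl, n_rand = n_rand, seed = seed))
  }
  out
}
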