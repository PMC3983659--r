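# Fully seeded synthetic genomes with planted regulatory truth. The
# generator emulates the structure of the study system: per tissue, 200
# highly and 200 lowly expressed genes, ~2.4 CNEs per promoter with a mean
# length of 249 bp, sharp tissue-specific motifs planted in high-promoter
# CNEs and in distal truth enhancers of high-gene loci, and neutral distal
# CNEs in all loci so that control loci contain scanned sequences.

#' Synthetic study specification
#'
#' Defaults mirror the study conditions: 200 genes per expression class,
#' Poisson(2.4) CNEs per promoter with geometric lengths of mean 249 bp,
#' 3 planted motifs embedded with probability 0.8 per motif per element
#' into high-promoter CNEs and into 2 distal truth enhancers per high
#' locus, against a library padded with 57 decoy motifs.
#'
#' @param n_high,n_low,n_other gene counts per class.
#' @param locus_length bp of genomic territory per gene (default 60 kb).
#' @param tx_length transcript length in bp.
#' @param cnes_per_promoter_mean Poisson mean of CNEs per promoter.
#' @param cne_length_mean mean CNE length in bp (geometric above
#'   `min_cne_length`).
#' @param min_cne_length minimum CNE length (matches the extraction
#'   default).
#' @param distal_cnes_per_locus Poisson mean of neutral distal CNEs per
#'   locus (both classes; these are the scanned control sequences).
#' @param n_enh planted truth enhancers per high-gene locus.
#' @param p_plant per-motif, per-element embedding probability.
#' @param n_planted,n_decoys motif library composition.
#' @param motif_length,motif_sharpness length and dominant-base probability
#'   of the generated PWMs.
#' @param background length-4 background nucleotide frequencies.
#' @param loci_per_chrom loci tiled end to end per chromosome.
#' @param seed master seed; the whole bundle is reproducible from it.
#' @return list of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(n_high = 200L, n_low = 200L, n_other = 0L,
                           locus_length = 60000L, tx_length = 6000L,
                           cnes_per_promoter_mean = 2.4,
                           cne_length_mean = 249, min_cne_length = 100L,
                           distal_cnes_per_locus = 4,
                           n_enh = 2L, p_plant = 0.8,
                           n_planted = 3L, n_decoys = 57L,
                           motif_length = 10L, motif_sharpness = 0.95,
                           background = c(0.25, 0.25, 0.25, 0.25),
                           loci_per_chrom = 20L, seed = 1L) {
  spec <- list(n_high = as.integer(n_high), n_low = as.integer(n_low),
               n_other = as.integer(n_other),
               locus_length = as.integer(locus_length),
               tx_length = as.integer(tx_length),
               cnes_per_promoter_mean = cnes_per_promoter_mean,
               cne_length_mean = cne_length_mean,
               min_cne_length = as.integer(min_cne_length),
               distal_cnes_per_locus = distal_cnes_per_locus,
               n_enh = as.integer(n_enh), p_plant = p_plant,
               n_planted = as.integer(n_planted),
               n_decoys = as.integer(n_decoys),
               motif_length = as.integer(motif_length),
               motif_sharpness = motif_sharpness,
               background = background / sum(background),
               loci_per_chrom = as.integer(loci_per_chrom),
               seed = as.integer(seed))
  stopifnot(spec$n_high >= 0, spec$n_low >= 0, spec$p_plant >= 0,
            spec$p_plant <= 1, spec$locus_length > spec$tx_length + 8000)
  structure(spec, class = "synthetic_spec")
}

# sharp random PWMs: one dominant base per position
random_sharp_pwm <- function(id, L, sharpness) {
  m <- matrix((1 - sharpness) / 3, L, 4)
  dom <- sample.int(4, L, replace = TRUE)
  m[cbind(seq_len(L), dom)] <- sharpness
  pwm(m, id, "synthetic")
}

#' Generate a synthetic motif library
#'
#' `n_planted` sharp PWMs (ids `planted1..`) followed by `n_decoys` decoys
#' (ids `decoy1..`) of the same construction; planted and decoy motifs are
#' statistically exchangeable, only their use by the generator differs.
#'
#' @param spec a [synthetic_spec()] (or arguments matching its fields).
#' @return list of [pwm()] objects.
#' @export
synthetic_motif_library <- function(spec) {
  c(lapply(seq_len(spec$n_planted), function(i)
    random_sharp_pwm(paste0("planted", i), spec$motif_length,
                     spec$motif_sharpness)),
    lapply(seq_len(spec$n_decoys), function(i)
      random_sharp_pwm(paste0("decoy", i), spec$motif_length,
                       spec$motif_sharpness)))
}

sample_site <- function(x) {
  paste(DNA_BASES[apply(unclass(x), 1, function(p)
    sample.int(4, 1, prob = p))], collapse = "")
}

# place n non-overlapping intervals of the given lengths inside [lo, hi),
# avoiding `taken` (two-column matrix of starts/ends); gap >= 10 bp so
# placed conservation blocks never merge during extraction
place_nonoverlapping <- function(n, lens, lo, hi, taken = NULL,
                                 max_tries = 50L) {
  res <- matrix(integer(0), 0, 2)
  occ <- if (is.null(taken)) matrix(integer(0), 0, 2) else taken
  for (i in seq_len(n)) {
    len <- lens[i]
    if (hi - lo < len) break
    placed <- FALSE
    for (t in seq_len(max_tries)) {
      s <- lo + sample.int(hi - lo - len + 1, 1) - 1L
      e <- s + len
      if (nrow(occ) == 0 ||
          all(s >= occ[, 2] + 10L | e <= occ[, 1] - 10L)) {
        res <- rbind(res, c(s, e)); occ <- rbind(occ, c(s, e))
        placed <- TRUE; break
      }
    }
    if (!placed) next
  }
  res
}

#' Generate a synthetic study bundle
#'
#' Lays gene loci end to end on chromosomes, draws i.i.d. background
#' sequence, marks promoter CNEs (Poisson per promoter), neutral distal
#' CNEs (all loci) and truth enhancers (high loci) as conserved blocks with
#' identity ~ Uniform(0.70, 0.95), embeds planted-motif instances (sampled
#' from the PWMs, replacing background bases in place) into high-promoter
#' CNEs and truth enhancers, and writes an expression table ranking high
#' genes top and low genes bottom in the focal tissue. Byte-identical for a
#' fixed seed.
#'
#' @param spec a [synthetic_spec()].
#' @return list of class `"synthetic_bundle"`: `genome`, `chrom_sizes`,
#'   `transcripts`, `conservation`, `expression`, `truth`, `library`,
#'   `locus_class`, `loci`, `spec`.
#' @export
generate_synthetic <- function(spec = synthetic_spec()) {
  set.seed(spec$seed)
  n_loci <- spec$n_high + spec$n_low + spec$n_other
  if (n_loci < 1) stop("no genes requested")
  classes <- sample(c(rep("high", spec$n_high), rep("low", spec$n_low),
                      rep("other", spec$n_other)))
  lib <- synthetic_motif_library(spec)
  planted <- lib[seq_len(spec$n_planted)]

  n_chrom <- ceiling(n_loci / spec$loci_per_chrom)
  chrom_of <- paste0("chr", (seq_len(n_loci) - 1) %/% spec$loci_per_chrom + 1)
  offset_of <- ((seq_len(n_loci) - 1) %% spec$loci_per_chrom) *
    spec$locus_length
  chrom_sizes <- vapply(split(seq_len(n_loci), chrom_of), function(i)
    length(i) * spec$locus_length, numeric(1))
  chrom_sizes <- as.integer(chrom_sizes[paste0("chr", seq_len(n_chrom))])
  names(chrom_sizes) <- paste0("chr", seq_len(n_chrom))

  rgeom_len <- function(n) spec$min_cne_length +
    stats::rgeom(n, 1 / (spec$cne_length_mean - spec$min_cne_length + 1))

  tx <- vector("list", n_loci)
  cons <- vector("list", n_loci)
  truth <- vector("list", n_loci)
  plant_jobs <- vector("list", n_loci)  # intervals receiving motifs
  for (i in seq_len(n_loci)) {
    off <- offset_of[i]; chr <- chrom_of[i]
    strand <- sample(c("+", "-"), 1)
    tx_start <- off + as.integer((spec$locus_length - spec$tx_length) / 2) +
      sample.int(2000L, 1) - 1000L
    tx_end <- tx_start + spec$tx_length
    tss <- if (strand == "+") tx_start else tx_end - 1L
    gene <- sprintf("gene_%s_%04d", classes[i], i)
    tx[[i]] <- data.frame(gene_symbol = gene, chrom = chr,
                          start = tx_start, end = tx_end, strand = strand,
                          stringsAsFactors = FALSE)
    pr <- define_promoter(tss, strand, sum(chrom_sizes[chr]) )
    pr["start"] <- max(pr["start"], off)
    pr["end"] <- min(pr["end"], off + spec$locus_length)

    occ <- matrix(c(pr["start"], pr["end"]), 1, 2)  # keep distal out of zone
    # promoter CNEs
    k <- stats::rpois(1, spec$cnes_per_promoter_mean)
    pcne <- place_nonoverlapping(k, rgeom_len(max(k, 1)),
                                 pr[["start"]], pr[["end"]])
    # neutral distal CNEs anywhere in the locus outside the promoter zone
    m <- stats::rpois(1, spec$distal_cnes_per_locus)
    dcne <- place_nonoverlapping(m, rgeom_len(max(m, 1)),
                                 off + 500L, off + spec$locus_length - 500L,
                                 taken = occ)
    occ <- rbind(occ, dcne)
    # truth enhancers in high loci
    tr <- matrix(integer(0), 0, 2)
    if (classes[i] == "high" && spec$n_enh > 0) {
      lens <- pmax(rgeom_len(spec$n_enh), 3L * spec$motif_length + 15L)
      tr <- place_nonoverlapping(spec$n_enh, lens, off + 500L,
                                 off + spec$locus_length - 500L, taken = occ)
    }
    blocks <- rbind(pcne, dcne, tr)
    if (nrow(blocks) > 0)
      cons[[i]] <- data.frame(chrom = chr, start = blocks[, 1],
                              end = blocks[, 2], strand = ".",
                              identity = stats::runif(nrow(blocks), 0.70, 0.95),
                              stringsAsFactors = FALSE)
    if (nrow(tr) > 0)
      truth[[i]] <- data.frame(chrom = chr, start = tr[, 1], end = tr[, 2],
                               strand = ".", locus_of = gene,
                               stringsAsFactors = FALSE)
    if (classes[i] == "high") {
      jobs <- rbind(pcne, tr)
      if (nrow(jobs) > 0)
        plant_jobs[[i]] <- data.frame(chrom = chr, start = jobs[, 1],
                                      end = jobs[, 2],
                                      stringsAsFactors = FALSE)
    }
  }
  transcripts <- do.call(rbind, tx)
  conservation <- do.call(rbind, cons)
  truth <- if (length(Filter(Negate(is.null), truth)))
    do.call(rbind, truth) else
      data.frame(chrom = character(), start = integer(), end = integer(),
                 strand = character(), locus_of = character())
  rownames(transcripts) <- rownames(conservation) <- rownames(truth) <- NULL

  # background sequence, then in-place motif embedding
  genome <- lapply(names(chrom_sizes), function(chr) {
    sample(DNA_BASES, chrom_sizes[[chr]], replace = TRUE,
           prob = spec$background)
  })
  names(genome) <- names(chrom_sizes)
  plant_jobs <- do.call(rbind, Filter(Negate(is.null), plant_jobs))
  if (!is.null(plant_jobs) && nrow(plant_jobs) > 0 && spec$n_planted > 0) {
    for (j in seq_len(nrow(plant_jobs))) {
      len <- plant_jobs$end[j] - plant_jobs$start[j]
      zone <- len %/% spec$n_planted  # one zone per motif: no collisions
      for (mz in seq_len(spec$n_planted)) {
        if (stats::runif(1) > spec$p_plant) next
        site <- strsplit(sample_site(planted[[mz]]), "")[[1]]
        L <- length(site)
        zlo <- (mz - 1L) * zone
        if (zone < L) next
        pos <- plant_jobs$start[j] + zlo + sample.int(zone - L + 1, 1) - 1L
        genome[[plant_jobs$chrom[j]]][(pos + 1):(pos + L)] <- site
      }
    }
  }
  genome <- vapply(genome, paste, character(1), collapse = "")

  # expression: focal tissue separates the classes; a second tissue is a
  # permutation of the same values (no class structure)
  expr_val <- numeric(n_loci)
  expr_val[classes == "high"] <- stats::runif(spec$n_high, 8, 12)
  expr_val[classes == "low"] <- stats::runif(spec$n_low, 0.05, 1)
  expr_val[classes == "other"] <- stats::runif(spec$n_other, 2, 7)
  expression <- data.frame(gene_symbol = transcripts$gene_symbol,
                           tissue_a = expr_val,
                           tissue_b = sample(expr_val),
                           stringsAsFactors = FALSE)

  clusters <- cluster_transcripts(transcripts)
  loci <- define_loci(clusters, chrom_sizes)
  gene_of_cluster <- vapply(clusters$members, function(i)
    transcripts$gene_symbol[i[1]], character(1))
  locus_class <- stats::setNames(
    classes[match(gene_of_cluster, transcripts$gene_symbol)],
    clusters$cluster_id)

  structure(list(genome = genome, chrom_sizes = chrom_sizes,
                 transcripts = transcripts, conservation = conservation,
                 expression = expression, truth = truth, library = lib,
                 planted_motif_ids = vapply(planted, motif_id, character(1)),
                 loci = loci, locus_class = locus_class, spec = spec),
            class = "synthetic_bundle")
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat("synthetic_bundle:", length(x$genome), "chromosomes,",
      nrow(x$transcripts), "genes,", nrow(x$conservation),
      "conserved blocks,", nrow(x$truth), "truth enhancers\n")
  invisible(x)
}

#' Precision and recall of a prediction set against planted truth
#'
#' A prediction is a true positive iff it overlaps a truth enhancer by at
#' least 1 bp; recall is the fraction of truth enhancers overlapped by at
#' least one prediction. An empty prediction set reports precision 0 with
#' `precision_defined = FALSE`.
#'
#' @param pred_set a `"prediction_set"` (or a plain interval data.frame of
#'   predictions).
#' @param truth truth enhancer intervals.
#' @return list with `precision`, `recall`, `precision_defined`, `tp`.
#' @export
truth_eval <- function(pred_set, truth) {
  preds <- if (inherits(pred_set, "prediction_set"))
    pred_set$predictions else pred_set
  if (nrow(preds) == 0)
    return(list(precision = 0, recall = 0, precision_defined = FALSE,
                tp = 0L))
  hit <- overlaps_any(preds, truth)
  covered <- overlaps_any(truth, preds)
  list(precision = mean(hit),
       recall = if (nrow(truth)) mean(covered) else NA_real_,
       precision_defined = TRUE, tp = sum(hit))
}
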