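# Feature matrices: one row per conserved element, one column per motif,
# entries = motif occurrence counts. The promoter attribution map is kept
# alongside the counts because the consistent-positive-set algorithm needs
# to know which elements belong to which promoter.

element_ids <- function(x) paste0(x$chrom, ":", x$start, "-", x$end)

#' Construct a feature matrix object
#'
#' @param counts integer matrix, rows = elements, columns = motifs.
#' @param elements interval data.frame aligned with the rows.
#' @param label numeric vector in `{+1, -1, NA}` (NA = unlabeled).
#' @param promoter_of list of character vectors: the gene symbols of the
#'   promoters each element is attributed to (may be empty).
#' @return list of class `"feature_matrix"` with components `counts`,
#'   `elements`, `label`, `promoter_of`, `motif_ids`, `element_id`.
#' @export
feature_matrix <- function(counts, elements, label = rep(NA_real_, nrow(counts)),
                           promoter_of = rep(list(character()), nrow(counts))) {
  counts <- as.matrix(counts)
  ids <- element_ids(elements)
  if (anyDuplicated(ids)) stop("element ids must be unique; deduplicate first")
  stopifnot(nrow(counts) == nrow(elements), length(label) == nrow(counts),
            length(promoter_of) == nrow(counts))
  if (any(counts < 0)) stop("feature counts must be non-negative")
  structure(list(counts = counts, elements = elements, label = label,
                 promoter_of = promoter_of,
                 motif_ids = colnames(counts), element_id = ids),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("feature_matrix:", nrow(x$counts), "elements x",
      ncol(x$counts), "motifs;",
      sum(x$label == 1, na.rm = TRUE), "positive,",
      sum(x$label == -1, na.rm = TRUE), "negative\n")
  invisible(x)
}

subset_fm <- function(fm, idx) {
  feature_matrix(fm$counts[idx, , drop = FALSE],
                 fm$elements[idx, , drop = FALSE],
                 fm$label[idx], fm$promoter_of[idx])
}

#' Build the motif-count feature matrix of a set of conserved elements
#'
#' @param elements interval data.frame with a `sequence` column (as from
#'   [extract_cnes()]).
#' @param library list of PWMs or a prebuilt [motif_scanner()].
#' @param bg background model; when `NULL`, a 0-order model is estimated
#'   from the element sequences themselves.
#' @param p_threshold scan hit threshold.
#' @return a [feature_matrix()] (unlabeled).
#' @export
build_features <- function(elements, library, bg = NULL, p_threshold = 1e-4) {
  if (!inherits(library, "motif_scanner") && length(library) == 0)
    stop("empty motif library")
  if (!"sequence" %in% names(elements))
    stop("elements must carry sequences")
  if (is.null(bg)) bg <- estimate_background(elements$sequence)
  sc <- if (inherits(library, "motif_scanner")) library
        else motif_scanner(library, bg, p_threshold)
  counts <- vapply(elements$sequence, function(s) {
    enc <- encode_dna(s)
    vapply(sc$motifs, function(m) count_encoded(enc, m), integer(1))
  }, integer(length(sc$motifs)))
  counts <- if (is.null(dim(counts)))
    matrix(counts, ncol = 1) else t(counts)
  dimnames(counts) <- list(NULL, sc$motif_ids)
  feature_matrix(counts, elements)
}

#' Collapse rows with identical coordinates
#'
#' Rows sharing `chrom:start-end` collapse to a single row keeping the
#' union of promoter attributions (a CNE may serve several promoters).
#' Idempotent. Conflicting labels (+1 and -1 on the same element) raise an
#' error for the caller to resolve.
#'
#' @param fm a [feature_matrix()].
#' @return deduplicated [feature_matrix()].
#' @export
deduplicate_features <- function(fm) {
  ids <- paste0(fm$elements$chrom, ":", fm$elements$start, "-", fm$elements$end)
  first <- !duplicated(ids)
  if (all(first)) return(fm)
  keep <- which(first)
  promoter_of <- lapply(keep, function(i)
    sort(unique(unlist(fm$promoter_of[ids == ids[i]]))))
  label <- vapply(keep, function(i) {
    l <- unique(fm$label[ids == ids[i]])
    l <- l[!is.na(l)]
    if (length(l) > 1)
      stop("conflicting labels on element ", ids[i])
    if (length(l) == 0) NA_real_ else l
  }, numeric(1))
  feature_matrix(fm$counts[keep, , drop = FALSE],
                 fm$elements[keep, , drop = FALSE], label, promoter_of)
}

# gene symbols of promoters a CNE belongs to (>= 1 bp overlap by default;
# min_overlap_frac requires that fraction of the CNE to be covered)
promoters_of_element <- function(cnes, promoters, min_overlap_frac = 0) {
  lapply(seq_len(nrow(cnes)), function(i) {
    p <- promoters[promoters$chrom == cnes$chrom[i] &
                     promoters$start < cnes$end[i] &
                     promoters$end > cnes$start[i], , drop = FALSE]
    if (nrow(p) == 0) return(character())
    ov <- pmin(p$end, cnes$end[i]) - pmax(p$start, cnes$start[i])
    need <- min_overlap_frac * (cnes$end[i] - cnes$start[i])
    sort(unique(p$gene_symbol[ov >= pmax(1, need)]))
  })
}

#' Assemble the labeled training set for one tissue
#'
#' CNEs intersecting a promoter of the highly expressed set are labeled
#' `+1`, those intersecting a lowly expressed promoter `-1`; CNEs touching
#' both sets are dropped with a warning (ambiguous label), CNEs touching
#' neither are excluded. Duplicate CNEs (shared by several promoters)
#' enter once, with the union of promoter attributions.
#'
#' @param high_promoters,low_promoters promoter interval data.frames with
#'   `gene_symbol` (disjoint gene sets).
#' @param cnes conserved elements with sequences.
#' @param library motif library or scanner.
#' @param bg background model (`NULL`: estimated from the selected CNEs).
#' @param p_threshold scan threshold.
#' @param min_overlap_frac minimum fraction of a CNE that must overlap a
#'   promoter to be attributed to it (default 0 = any >= 1 bp overlap).
#' @return labeled, deduplicated [feature_matrix()].
#' @export
assemble_training_set <- function(high_promoters, low_promoters, cnes,
                                  library, bg = NULL, p_threshold = 1e-4,
                                  min_overlap_frac = 0) {
  shared <- intersect(high_promoters$gene_symbol, low_promoters$gene_symbol)
  if (length(shared) > 0)
    stop("gene(s) in both promoter sets: ", paste(shared, collapse = ", "))
  hi <- promoters_of_element(cnes, high_promoters, min_overlap_frac)
  lo <- promoters_of_element(cnes, low_promoters, min_overlap_frac)
  in_hi <- lengths(hi) > 0; in_lo <- lengths(lo) > 0
  both <- in_hi & in_lo
  if (any(both))
    warning(sum(both), " element(s) overlap both promoter sets; dropped")
  keep <- xor(in_hi, in_lo) & !both
  if (!any(keep)) stop("no CNE overlaps either promoter set")
  sel <- which(keep)
  cn <- cnes[sel, , drop = FALSE]
  dup <- duplicated(element_ids(cn))
  promoter_of <- lapply(sel, function(i)
    if (lengths(hi)[i] > 0) hi[[i]] else lo[[i]])
  label <- ifelse(in_hi[sel], 1, -1)
  if (any(dup)) {  # collapse duplicates before scanning
    ids <- element_ids(cn)
    keep1 <- !duplicated(ids)
    promoter_of <- lapply(ids[keep1], function(id)
      sort(unique(unlist(promoter_of[ids == id]))))
    lab1 <- vapply(ids[keep1], function(id) {
      l <- unique(label[ids == id])
      if (length(l) > 1) stop("conflicting labels on element ", id)
      l
    }, numeric(1))
    cn <- cn[keep1, , drop = FALSE]; label <- lab1
  }
  fm <- build_features(cn, library, bg, p_threshold)
  fm$label <- as.numeric(label)
  fm$promoter_of <- promoter_of
  fm
}

#' Serialize a feature matrix to TSV
#' @param fm a [feature_matrix()].
#' @param path output path.
#' @export
write_feature_matrix <- function(fm, path) {
  d <- data.frame(element_id = fm$element_id, label = fm$label,
                  promoter_of = vapply(fm$promoter_of, paste,
                                       character(1), collapse = ","),
                  stringsAsFactors = FALSE)
  d <- cbind(d, as.data.frame(fm$counts))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
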