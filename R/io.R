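# Readers and writers for the standard formats consumed and produced by
# the pipeline: FASTA (via Biostrings), BED6, TSV tables, model JSON.

#' Read a genome FASTA into a named character vector
#' @param path FASTA file.
#' @return named character vector of chromosome sequences.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write a named character vector of sequences to FASTA
#' @param genome named character vector.
#' @param path output path.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path)
}

#' Read a transcript annotation TSV
#'
#' Expected columns: `gene_symbol`, `chrom`, `start`, `end`, `strand`
#' (0-based half-open).
#'
#' @param path TSV file with header.
#' @return transcript data.frame.
#' @export
read_transcripts <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_symbol", "chrom", "start", "end", "strand")
  if (!all(need %in% names(d)))
    stop("transcript table needs columns: ", paste(need, collapse = ", "))
  validate_intervals(d)
  d
}

#' Read a gene-by-tissue expression table
#' @param path TSV with a `gene_symbol` column and one numeric column per
#'   tissue.
#' @return data.frame.
#' @export
read_expression <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"gene_symbol" %in% names(d))
    stop("expression table needs a gene_symbol column")
  d
}

#' Read a BED file (BED3/BED6, optional identity in the score column)
#'
#' @param path BED path (no header).
#' @param identity_score if `TRUE`, interpret column 5 as identity x 1000.
#' @return interval data.frame.
#' @export
read_bed <- function(path, identity_score = FALSE) {
  d <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(d)[1:3] <- c("chrom", "start", "end")
  if (ncol(d) >= 6) d$strand <- d[[6]] else d$strand <- "."
  if (identity_score && ncol(d) >= 5) d$identity <- d[[5]] / 1000
  validate_intervals(d)
  d[, intersect(c("chrom", "start", "end", "strand", "identity"),
                names(d)), drop = FALSE]
}

#' Write intervals as BED6
#'
#' @param x interval data.frame.
#' @param path output path.
#' @param name,score column sources: column names in `x` or constants.
#'   CNE identities are conventionally exported as `identity * 1000`.
#' @export
write_bed <- function(x, path, name = ".", score = 0) {
  nm <- if (is.character(name) && length(name) == 1 && name %in% names(x))
    x[[name]] else rep(name, nrow(x))
  sc <- if (is.character(score) && length(score) == 1 && score %in% names(x))
    x[[score]] else rep(score, nrow(x))
  strand <- if ("strand" %in% names(x)) x$strand else "."
  d <- data.frame(x$chrom, x$start, x$end, nm, sc, strand)
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Write motif hits as BED6
#'
#' Converts sequence-relative hits from [scan_motif()] to genomic
#' coordinates and writes BED6 with the score column set to
#' `-log10(p-value)`.
#'
#' @param hits hit data.frame from [scan_motif()].
#' @param chrom chromosome the scanned sequence came from.
#' @param offset genomic start of the scanned sequence (0-based).
#' @param path output path.
#' @export
write_hits_bed <- function(hits, chrom, offset, path) {
  d <- data.frame(chrom = chrom,
                  start = hits$start + as.integer(offset),
                  end = hits$end + as.integer(offset),
                  name = hits$motif_id,
                  score = round(-log10(pmax(hits$pvalue, 1e-300)), 3),
                  strand = hits$strand)
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Serialize a trained model to JSON
#' @param model a `"linear_model"`.
#' @param path output path.
#' @param extra named list of training metadata to embed.
#' @export
write_model_json <- function(model, path, extra = list()) {
  obj <- c(list(motif_ids = model$motif_ids, w = unname(model$w),
                b = model$b, C = model$C, w1 = model$w1), extra)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
}

#' Read a model back from JSON
#' @param path JSON path written by [write_model_json()].
#' @return a `"linear_model"`.
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  w <- stats::setNames(as.numeric(obj$w), obj$motif_ids)
  structure(list(w = w, b = obj$b, C = obj$C, w1 = obj$w1,
                 motif_ids = obj$motif_ids, bg = obj$bg,
                 gamma = obj$gamma, tissue = obj$tissue),
            class = "linear_model")
}

#' Write a motif library in JASPAR count format
#'
#' Probabilities are scaled to integer counts out of `depth`; re-parsing
#' recovers the probabilities up to the parser's pseudocount (0.25 against
#' a depth of 1000 shifts entries by < 1e-3).
#'
#' @param library list of [pwm()] objects.
#' @param path output path.
#' @param depth pseudo-observation count per position (default 1000).
#' @export
write_motifs_jaspar <- function(library, path, depth = 1000L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in library) {
    writeLines(paste0(">", motif_id(m)), con)
    counts <- round(unclass(m) * depth)
    for (b in DNA_BASES)
      writeLines(sprintf("%s [ %s ]", b,
                         paste(counts[, b], collapse = " ")), con)
  }
  invisible(path)
}

#' Write a synthetic bundle to a directory
#'
#' Emits `genome.fa`, `transcripts.tsv`, `conservation.bed` (identity x
#' 1000 in the score column), `expression.tsv`, `truth_enhancers.bed`, and
#' a `manifest.json` recording the generating spec and seed.
#'
#' @param bundle a `"synthetic_bundle"`.
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genome_fasta(bundle$genome, file.path(dir, "genome.fa"))
  utils::write.table(bundle$transcripts, file.path(dir, "transcripts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cons <- bundle$conservation
  cons$identity_k <- round(cons$identity * 1000)
  write_bed(cons, file.path(dir, "conservation.bed"),
            name = ".", score = "identity_k")
  utils::write.table(bundle$expression, file.path(dir, "expression.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_bed(bundle$truth, file.path(dir, "truth_enhancers.bed"),
            name = "locus_of")
  if (!is.null(bundle$library))
    write_motifs_jaspar(bundle$library, file.path(dir, "motifs.jaspar"))
  jsonlite::write_json(c(bundle$spec, list(class = "synthetic_spec")),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
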