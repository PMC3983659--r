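# Transcript clustering, locus partitioning, promoter definition and CNE
# extraction. Transcripts are data.frames with columns gene_symbol, chrom,
# start, end, strand; the strand-aware TSS is derived (start on "+",
# end - 1 on "-").

#' Attach the strand-aware TSS to a transcript table
#' @param transcripts data.frame with gene_symbol, chrom, start, end, strand.
#' @return the same data.frame with a `tss` column.
#' @export
with_tss <- function(transcripts) {
  validate_intervals(transcripts)
  if (!all(transcripts$strand %in% c("+", "-")))
    stop("transcripts must be stranded (+/-)")
  transcripts$tss <- ifelse(transcripts$strand == "+",
                            transcripts$start, transcripts$end - 1L)
  transcripts
}

#' Cluster overlapping transcripts into gene clusters
#'
#' Two transcripts belong to the same cluster iff they are connected by a
#' chain of >= 1 bp overlaps on the same chromosome. Strand is ignored:
#' antisense transcripts sharing bases share a cluster. The result is
#' independent of input order.
#'
#' @param transcripts transcript data.frame.
#' @return data.frame with one row per cluster: `cluster_id`, `chrom`,
#'   `start`, `end` (the cluster span) and `members` (list column of row
#'   indices into the input).
#' @export
cluster_transcripts <- function(transcripts) {
  validate_intervals(transcripts)
  if (nrow(transcripts) == 0)
    stop("no transcripts supplied")
  ord <- order(transcripts$chrom, transcripts$start, transcripts$end)
  d <- transcripts[ord, , drop = FALSE]
  run_end <- stats::ave(d$end, d$chrom, FUN = cummax)
  prev_end <- c(-1L, run_end[-nrow(d)])
  new_run <- d$start >= prev_end | c(TRUE, d$chrom[-1] != d$chrom[-nrow(d)])
  grp <- cumsum(new_run)
  spans <- lapply(split(seq_len(nrow(d)), grp), function(i) {
    data.frame(chrom = d$chrom[i[1]],
               start = min(d$start[i]), end = max(d$end[i]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, spans)
  out$cluster_id <- seq_len(nrow(out))
  out$strand <- "."
  out$members <- I(lapply(split(ord, grp), identity))
  rownames(out) <- NULL
  out[, c("cluster_id", "chrom", "start", "end", "strand", "members")]
}

#' Partition chromosomes into gene loci
#'
#' Each cluster receives the closest half of each flanking intergenic gap;
#' chromosome ends are assigned to the terminal loci. The midpoint of a gap
#' between a cluster ending at `e` and the next starting at `s` is
#' `floor((e + s) / 2)` (the floor is the left locus end), so loci tile each
#' chromosome exactly, without gaps or overlaps.
#'
#' @param clusters cluster data.frame from [cluster_transcripts()].
#' @param chrom_sizes named integer vector of chromosome lengths.
#' @return data.frame `cluster_id`, `chrom`, `start`, `end` of loci.
#' @export
define_loci <- function(clusters, chrom_sizes) {
  validate_intervals(clusters, chrom_sizes)
  out <- lapply(split(clusters, clusters$chrom), function(d) {
    d <- d[order(d$start), , drop = FALSE]
    if (any(d$start[-1] < d$end[-nrow(d)]))
      stop("clusters overlap; run cluster_transcripts first")
    len <- as.integer(chrom_sizes[[d$chrom[1]]])
    mids <- if (nrow(d) > 1)
      as.integer((d$end[-nrow(d)] + d$start[-1]) %/% 2) else integer(0)
    data.frame(cluster_id = d$cluster_id, chrom = d$chrom[1],
               start = c(0L, mids), end = c(mids, len),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Define a promoter region around a TSS
#'
#' The default promoter spans 2.5 kb upstream and 0.5 kb downstream of the
#' TSS (3 kb total), strand-aware, clipped to the chromosome. On "+" the
#' region is `[tss - upstream, tss + downstream)`; on "-" it is the mirror
#' image `[tss - downstream + 1, tss + upstream + 1)`.
#'
#' @param tss 0-based TSS position.
#' @param strand "+" or "-".
#' @param chrom_size chromosome length in bp.
#' @param upstream,downstream span in bp (defaults 2500 / 500).
#' @return integer vector `c(start, end)`.
#' @export
define_promoter <- function(tss, strand, chrom_size,
                            upstream = 2500L, downstream = 500L) {
  if (tss < 0 || tss >= chrom_size) stop("tss out of chromosome bounds")
  if (strand == "+") {
    s <- tss - upstream; e <- tss + downstream
  } else if (strand == "-") {
    s <- tss - downstream + 1L; e <- tss + upstream + 1L
  } else stop("strand must be '+' or '-'")
  c(start = max(0L, as.integer(s)), end = min(as.integer(chrom_size), as.integer(e)))
}

#' Promoter regions for a transcript table
#'
#' @param transcripts transcript data.frame (TSS derived internally).
#' @param chrom_sizes named integer vector.
#' @inheritParams define_promoter
#' @return interval data.frame with `gene_symbol` and `tss` columns; one
#'   promoter per transcript.
#' @export
promoter_regions <- function(transcripts, chrom_sizes,
                             upstream = 2500L, downstream = 500L) {
  tx <- with_tss(transcripts)
  validate_intervals(tx, chrom_sizes)
  se <- t(mapply(function(tss, strand, chr)
    define_promoter(tss, strand, chrom_sizes[[chr]], upstream, downstream),
    tx$tss, tx$strand, tx$chrom))
  intervals(chrom = tx$chrom, start = se[, 1], end = se[, 2],
            strand = tx$strand, gene_symbol = tx$gene_symbol, tss = tx$tss)
}

#' Extract conserved non-coding elements from identity blocks
#'
#' Blocks with cross-species identity at or above `min_identity` are kept,
#' merged when overlapping or abutting, dropped when shorter than
#' `min_length`, and their sequences attached from the genome. The identity
#' of a merged element is the length-weighted mean of its parts.
#'
#' @param identity_blocks interval data.frame with an `identity` column in
#'   `[0, 1]`.
#' @param genome named character vector of chromosome sequences (may be
#'   `NULL` to skip sequence attachment).
#' @param min_identity minimum identity fraction (default 0.70).
#' @param min_length minimum merged element length in bp (default 100).
#' @return interval data.frame with `identity` and (if a genome was given)
#'   `sequence` columns.
#' @export
extract_cnes <- function(identity_blocks, genome = NULL,
                         min_identity = 0.70, min_length = 100L) {
  validate_intervals(identity_blocks)
  if (!"identity" %in% names(identity_blocks))
    stop("identity_blocks needs an 'identity' column")
  if (any(identity_blocks$identity < 0 | identity_blocks$identity > 1))
    stop("identity values must lie in [0, 1]")
  keep <- identity_blocks[identity_blocks$identity >= min_identity, ,
                          drop = FALSE]
  if (nrow(keep) == 0)
    return(intervals(character(), integer(), integer(), identity = numeric()))
  merged <- merge_intervals(keep)
  # length-weighted identity over the constituent blocks of each element
  merged$identity <- vapply(seq_len(nrow(merged)), function(i) {
    b <- keep[keep$chrom == merged$chrom[i] &
                keep$start < merged$end[i] & keep$end > merged$start[i], ]
    stats::weighted.mean(b$identity, b$end - b$start)
  }, numeric(1))
  merged <- merged[merged$end - merged$start >= min_length, , drop = FALSE]
  rownames(merged) <- NULL
  if (!is.null(genome) && nrow(merged) > 0) {
    validate_intervals(merged, vapply(genome, nchar, integer(1)))
    merged$sequence <- substr(genome[merged$chrom],
                              merged$start + 1L, merged$end)
  }
  merged
}

#' Distance from an interval to the nearest TSS
#'
#' Zero when a TSS falls inside the half-open interval; otherwise the gap
#' between the closest interval boundary and the TSS.
#'
#' @param interval one-row interval data.frame (or list with chrom/start/end).
#' @param transcripts transcript data.frame.
#' @return distance in bp.
#' @export
distance_to_nearest_tss <- function(interval, transcripts) {
  tx <- with_tss(transcripts)
  tss <- tx$tss[tx$chrom == interval$chrom]
  if (length(tss) == 0)
    stop("no transcript on chromosome ", interval$chrom)
  min(pmax(0L, interval$start - tss, tss - interval$end))
}

#' Assign intervals to loci
#'
#' An interval is assigned to the locus containing its midpoint (loci tile
#' each chromosome, so the assignment is total for in-bounds intervals).
#'
#' @param x interval data.frame.
#' @param loci locus data.frame from [define_loci()].
#' @return integer vector of `cluster_id`s (NA for intervals on chromosomes
#'   without loci).
#' @export
assign_loci <- function(x, loci) {
  validate_intervals(x)
  out <- rep(NA_integer_, nrow(x))
  mid <- (x$start + x$end) %/% 2
  for (chr in unique(x$chrom)) {
    l <- loci[loci$chrom == chr, , drop = FALSE]
    xi <- which(x$chrom == chr)
    if (nrow(l) == 0) next
    l <- l[order(l$start), , drop = FALSE]
    idx <- findInterval(mid[xi], l$start)
    ok <- idx >= 1 & mid[xi] < l$end[pmax(idx, 1L)]
    out[xi[ok]] <- l$cluster_id[idx[ok]]
  }
  out
}
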