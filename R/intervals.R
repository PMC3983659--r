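#' Construct a set of genomic intervals
#'
#' Intervals follow the BED convention throughout the package: 0-based,
#' half-open `[start, end)`. Coordinates are only rendered 1-based in report
#' text, never internally.
#'
#' @param chrom character vector of chromosome identifiers.
#' @param start,end integer vectors; `0 <= start < end` is enforced.
#' @param strand character vector over `"+"`, `"-"`, `"."` (recycled).
#' @param ... further columns to carry along (e.g. `identity`, `name`).
#' @return a `data.frame` with columns `chrom`, `start`, `end`, `strand`
#'   plus any extra columns.
#' @export
intervals <- function(chrom, start, end, strand = ".", ...) {
  x <- data.frame(chrom = as.character(chrom),
                  start = as.integer(start),
                  end = as.integer(end),
                  strand = rep_len(as.character(strand),
                                   length(chrom)),
                  ...,
                  stringsAsFactors = FALSE)
  validate_intervals(x)
  x
}

#' Validate interval invariants
#'
#' Checks `0 <= start < end`, legal strand symbols and, when `chrom_sizes`
#' is supplied, that every interval lies within its chromosome.
#'
#' @param x interval data.frame.
#' @param chrom_sizes optional named integer vector of chromosome lengths.
#' @return `x`, invisibly; stops on violation.
#' @export
validate_intervals <- function(x, chrom_sizes = NULL) {
  stopifnot(is.data.frame(x),
            all(c("chrom", "start", "end") %in% names(x)))
  if (nrow(x) == 0) return(invisible(x))
  if (any(x$start < 0)) stop("interval start must be >= 0")
  if (any(x$start >= x$end)) stop("interval must satisfy start < end")
  if ("strand" %in% names(x) && !all(x$strand %in% c("+", "-", ".")))
    stop("strand must be one of '+', '-', '.'")
  if (!is.null(chrom_sizes)) {
    if (!all(x$chrom %in% names(chrom_sizes)))
      stop("interval on unknown chromosome: ",
           paste(setdiff(x$chrom, names(chrom_sizes)), collapse = ", "))
    if (any(x$end > chrom_sizes[x$chrom]))
      stop("interval extends beyond chromosome end")
  }
  invisible(x)
}

#' Merge overlapping or abutting intervals
#'
#' Returns the minimal set of disjoint intervals with exactly the same base
#' coverage as the input (so abutting intervals are joined). Idempotent.
#' Strand is ignored; the result carries strand `"."`.
#'
#' @param x interval data.frame.
#' @return merged interval data.frame, sorted by `(chrom, start)`.
#' @export
merge_intervals <- function(x) {
  validate_intervals(x)
  if (nrow(x) == 0)
    return(intervals(character(), integer(), integer()))
  out <- lapply(split(x, x$chrom), function(d) {
    d <- d[order(d$start, d$end), , drop = FALSE]
    # sweep: start a new run whenever the next start exceeds the running end
    run_end <- cummax(d$end)
    new_run <- c(TRUE, d$start[-1] > run_end[-nrow(d)])
    grp <- cumsum(new_run)
    data.frame(chrom = d$chrom[1],
               start = tapply(d$start, grp, min),
               end = tapply(d$end, grp, max),
               strand = ".", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out$start <- as.integer(out$start)
  out$end <- as.integer(out$end)
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Which query intervals overlap a subject set?
#'
#' Overlap means sharing at least one base under half-open semantics;
#' 1-bp abutment (`end == start`) does not count.
#'
#' @param queries,subjects interval data.frames.
#' @return logical vector along `queries`.
#' @export
overlaps_any <- function(queries, subjects) {
  validate_intervals(queries)
  if (nrow(subjects) == 0 || nrow(queries) == 0)
    return(rep(FALSE, nrow(queries)))
  marks <- merge_intervals(subjects)
  hit <- rep(FALSE, nrow(queries))
  for (chr in unique(queries$chrom)) {
    m <- marks[marks$chrom == chr, , drop = FALSE]
    qi <- which(queries$chrom == chr)
    if (nrow(m) == 0 || length(qi) == 0) next
    # disjoint sorted marks: the mark with the largest start < q end decides
    idx <- findInterval(queries$end[qi] - 1L, m$start)
    ok <- idx >= 1L
    ok[ok] <- m$end[idx[ok]] > queries$start[qi[ok]]
    hit[qi] <- ok
  }
  hit
}

#' Count queries overlapping a merged mark set
#'
#' @param queries query intervals.
#' @param marks mark intervals (merged internally).
#' @return integer count of queries intersecting at least one mark by >= 1 bp.
#' @export
overlap_count <- function(queries, marks) {
  sum(overlaps_any(queries, marks))
}

#' Total bases covered by an interval set
#' @param x interval data.frame.
#' @return integer base count (after merging).
#' @export
coverage_bases <- function(x) {
  m <- merge_intervals(x)
  if (nrow(m) == 0) return(0L)
  sum(m$end - m$start)
}

#' Complement of an interval set within chromosomes
#'
#' @param x interval data.frame (merged internally).
#' @param chrom_sizes named integer vector.
#' @return intervals covering every base of every chromosome not covered
#'   by `x`.
#' @export
complement_intervals <- function(x, chrom_sizes) {
  m <- merge_intervals(x)
  out <- lapply(names(chrom_sizes), function(chr) {
    len <- chrom_sizes[[chr]]
    d <- m[m$chrom == chr, , drop = FALSE]
    starts <- c(0L, d$end)
    ends <- c(d$start, as.integer(len))
    keep <- starts < ends
    data.frame(chrom = chr, start = starts[keep], end = ends[keep],
               strand = ".", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
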