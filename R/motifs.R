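# Motif library I/O, log-odds scanning with an exact discretized null
# distribution, motif GC content, PWM permutation and over-representation
# testing. A PWM is an L x 4 probability matrix (columns A, C, G, T; rows =
# positions) with attributes `motif_id` and `source`.

DNA_BASES <- c("A", "C", "G", "T")

#' Construct a PWM object
#' @param probs L x 4 matrix of per-position nucleotide probabilities
#'   (columns A, C, G, T); each row must sum to 1 within 1e-9.
#' @param motif_id character identifier.
#' @param source dialect tag (e.g. "jaspar", "transfac", "meme", "synthetic").
#' @return the probability matrix with attributes set, class `"pwm"`.
#' @export
pwm <- function(probs, motif_id, source = "matrix") {
  probs <- as.matrix(probs)
  if (ncol(probs) != 4 || nrow(probs) < 1)
    stop("PWM must be an L x 4 matrix with L >= 1: ", motif_id)
  if (any(probs < 0) || any(abs(rowSums(probs) - 1) > 1e-9))
    stop("PWM rows must be probabilities summing to 1: ", motif_id)
  dimnames(probs) <- list(NULL, DNA_BASES)
  structure(probs, motif_id = as.character(motif_id), source = source,
            class = c("pwm", "matrix", "array"))
}

motif_id <- function(x) attr(x, "motif_id")

#' Background nucleotide model
#' @param freqs numeric length-4 (A, C, G, T), strictly positive, summing
#'   to 1 (renormalized internally).
#' @return named numeric vector of class `"background_model"`.
#' @export
background_model <- function(freqs = c(0.25, 0.25, 0.25, 0.25)) {
  stopifnot(length(freqs) == 4, all(freqs > 0))
  freqs <- freqs / sum(freqs)
  structure(stats::setNames(freqs, DNA_BASES), class = "background_model")
}

#' Estimate a 0-order background from a sequence set
#'
#' Counts A/C/G/T over all sequences (N ignored); falls back to the uniform
#' model when no informative base is present.
#'
#' @param seqs character vector of DNA sequences.
#' @return a [background_model()].
#' @export
estimate_background <- function(seqs) {
  tab <- table(factor(unlist(strsplit(toupper(paste(seqs, collapse = "")),
                                      "")), levels = DNA_BASES))
  if (sum(tab) == 0) return(background_model())
  background_model((as.numeric(tab) + 1) / (sum(tab) + 4))
}

#' Parse a motif library file
#'
#' Supported dialects: `"jaspar"` (`>id name` header followed by four
#' `A [ n n ... ]` count rows), `"transfac"` (`P0`-headed count blocks
#' terminated by `//`), and `"meme"` minimal (letter-probability matrices).
#' Count matrices are converted to probabilities with a pseudocount of 0.25
#' per cell; MEME probabilities are taken as-is.
#'
#' @param path file path.
#' @param dialect one of `"jaspar"`, `"transfac"`, `"meme"`.
#' @param pseudocount added to every cell of a count matrix (default 0.25).
#' @return list of [pwm()] objects with unique ids.
#' @export
parse_motifs <- function(path, dialect = c("jaspar", "transfac", "meme"),
                         pseudocount = 0.25) {
  dialect <- match.arg(dialect)
  lines <- readLines(path, warn = FALSE)
  out <- switch(dialect,
                jaspar = parse_jaspar(lines, pseudocount),
                transfac = parse_transfac(lines, pseudocount),
                meme = parse_meme(lines))
  ids <- vapply(out, motif_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate motif id: ", ids[duplicated(ids)][1])
  out
}

counts_to_probs <- function(counts, id, source, pseudocount) {
  counts <- counts + pseudocount
  pwm(counts / rowSums(counts), id, source)
}

parse_jaspar <- function(lines, pseudocount) {
  heads <- grep("^>", lines)
  lapply(heads, function(h) {
    id <- strsplit(sub("^>", "", lines[h]), "[ \t]+")[[1]][1]
    rows <- lines[(h + 1):min(h + 4, length(lines))]
    if (length(rows) < 4) stop("malformed JASPAR record: ", id)
    mat <- lapply(rows, function(r) {
      stripped <- sub("^[ \t]*[ACGT]", "", r)
      as.numeric(regmatches(stripped,
                            gregexpr("[0-9.eE+-]+", stripped))[[1]])
    })
    if (length(unique(lengths(mat))) != 1 || any(is.na(unlist(mat))))
      stop("malformed JASPAR record: ", id)
    counts <- t(do.call(rbind, mat))  # rows were A, C, G, T
    counts_to_probs(counts, id, "jaspar", pseudocount)
  })
}

parse_transfac <- function(lines, pseudocount) {
  out <- list()
  i <- 1; id <- NULL; rows <- NULL; in_mat <- FALSE
  for (ln in lines) {
    tag <- substr(ln, 1, 2)
    if (tag %in% c("ID", "AC") && is.null(id))
      id <- trimws(sub("^..", "", ln))
    if (tag == "AC") id <- trimws(sub("^..", "", ln))  # prefer accession
    if (tag == "ID") id <- trimws(sub("^..", "", ln))
    if (tag == "P0" || tag == "PO") { in_mat <- TRUE; rows <- list(); next }
    if (in_mat && grepl("^[0-9][0-9]", ln)) {
      f <- strsplit(trimws(ln), "[ \t]+")[[1]]
      if (length(f) < 5) stop("malformed TRANSFAC row in motif: ", id)
      rows[[length(rows) + 1]] <- as.numeric(f[2:5])
    }
    if (tag == "//") {
      if (in_mat) {
        if (length(rows) == 0 || is.null(id))
          stop("malformed TRANSFAC block (no matrix rows)")
        counts <- do.call(rbind, rows)
        if (any(is.na(counts))) stop("malformed TRANSFAC counts in motif: ", id)
        out[[length(out) + 1]] <- counts_to_probs(counts, id, "transfac",
                                                  pseudocount)
      }
      id <- NULL; rows <- NULL; in_mat <- FALSE
    }
  }
  out
}

parse_meme <- function(lines) {
  heads <- grep("^MOTIF", lines)
  lapply(heads, function(h) {
    id <- strsplit(trimws(sub("^MOTIF", "", lines[h])), "[ \t]+")[[1]][1]
    j <- h + 1
    while (j <= length(lines) && !grepl("letter-probability matrix", lines[j]))
      j <- j + 1
    if (j > length(lines)) stop("malformed MEME record (no matrix): ", id)
    w <- suppressWarnings(as.integer(sub(".*w=\\s*([0-9]+).*", "\\1", lines[j])))
    rows <- list()
    k <- j + 1
    while (k <= length(lines) &&
           grepl("^\\s*[0-9.eE+-]", lines[k]) &&
           (is.na(w) || length(rows) < w)) {
      rows[[length(rows) + 1]] <- as.numeric(strsplit(trimws(lines[k]),
                                                      "[ \t]+")[[1]])
      k <- k + 1
    }
    if (length(rows) == 0 || any(lengths(rows) != 4))
      stop("malformed MEME record: ", id)
    pwm(do.call(rbind, rows), id, "meme")
  })
}

#' Log-odds score matrix of a PWM against a background
#'
#' Entry `(i, b)` is `log2(prob[i, b] / bg[b])` in bits.
#'
#' @param x a [pwm()].
#' @param bg a [background_model()].
#' @return L x 4 numeric matrix.
#' @export
log_odds <- function(x, bg = background_model()) {
  if (any(x == 0))
    stop("PWM ", motif_id(x),
         " has zero probabilities; apply a pseudocount before scoring")
  sweep(log2(unclass(x)), 2, log2(as.numeric(bg)), "-")
}

#' Exact null distribution of a motif score
#'
#' Computes, by position-wise convolution over the discretized score grid,
#' the exact distribution of the log-odds score of a random background
#' k-mer. Supports tail-probability queries used to calibrate scan hits.
#'
#' @param lom log-odds matrix from [log_odds()].
#' @param bg background model generating the random k-mers.
#' @param bin_width score discretization in bits (default 1e-3).
#' @return object of class `"score_distribution"`: list with `bin_width`,
#'   `offset` (bin index of the first pmf entry), `pmf` and `tail`
#'   (upper-tail probabilities per bin).
#' @export
score_distribution <- function(lom, bg = background_model(),
                               bin_width = 1e-3) {
  if (bin_width <= 0) stop("bin_width must be positive")
  if (any(!is.finite(lom))) stop("log-odds scores must be finite")
  b <- round(lom / bin_width)  # integer bins per position/letter
  lo <- sum(apply(b, 1, min)); hi <- sum(apply(b, 1, max))
  pmf <- numeric(hi - lo + 1)
  # dp over positions; cur[k] = P(partial score bin == k + cur_lo - 1)
  cur <- 1; cur_lo <- 0
  p <- as.numeric(bg)
  for (i in seq_len(nrow(b))) {
    row_lo <- min(b[i, ]); row_hi <- max(b[i, ])
    nxt <- numeric(length(cur) + (row_hi - row_lo))
    for (a in 1:4) {
      sh <- b[i, a] - row_lo
      idx <- seq_along(cur) + sh
      nxt[idx] <- nxt[idx] + cur * p[a]
    }
    cur <- nxt; cur_lo <- cur_lo + row_lo
  }
  pmf[(cur_lo - lo + 1):(cur_lo - lo + length(cur))] <- cur
  tail <- rev(cumsum(rev(pmf)))
  structure(list(bin_width = bin_width, offset = lo, pmf = pmf, tail = tail),
            class = "score_distribution")
}

#' Upper-tail p-value of a score
#' @param dist a [score_distribution()].
#' @param score numeric score(s) in bits.
#' @return `P(S >= score)` under the background, evaluated on the bin grid.
#' @export
score_pvalue <- function(dist, score) {
  k <- round(score / dist$bin_width) - dist$offset + 1
  k <- pmin(pmax(k, 1), length(dist$tail) + 1)
  ifelse(k > length(dist$tail), 0, dist$tail[k])
}

# smallest score (bits) whose upper-tail p-value is <= p_threshold
threshold_score <- function(dist, p_threshold) {
  k <- which(dist$tail <= p_threshold)
  if (length(k) == 0) return(Inf)
  (min(k) + dist$offset - 1) * dist$bin_width
}

encode_dna <- function(sequence) {
  v <- strsplit(toupper(sequence), "")[[1]]
  m <- match(v, DNA_BASES)  # N and anything else -> NA
  m
}

revcomp_lom <- function(lom) {
  lom[rev(seq_len(nrow(lom))), c(4, 3, 2, 1), drop = FALSE]
}

# raw per-position scores of a log-odds matrix along an encoded sequence;
# windows containing N give NA
window_scores <- function(enc, lom) {
  L <- nrow(lom); n <- length(enc)
  if (n < L) return(numeric(0))
  s <- numeric(n - L + 1)
  for (i in seq_len(L)) {
    v <- lom[i, enc[i:(n - L + i)]]
    s <- s + v
  }
  s
}

#' Precompute a scanner for a motif library
#'
#' Builds, per motif, the log-odds matrices (both strands) and the exact
#' null distributions, so that repeated scans over many sequences do not
#' recompute them. The default hit rule follows MAST-style scanning:
#' a window is a hit when its exact background p-value is at most
#' `p_threshold` (default 1e-4), on either strand, all overlapping hits
#' counted.
#'
#' @param library list of [pwm()] objects.
#' @param bg background model.
#' @param p_threshold per-position hit p-value threshold.
#' @param bin_width score discretization (bits).
#' @return object of class `"motif_scanner"`.
#' @export
motif_scanner <- function(library, bg = background_model(),
                          p_threshold = 1e-4, bin_width = 1e-3) {
  if (length(library) == 0) stop("empty motif library")
  motifs <- lapply(library, function(m) {
    lom <- log_odds(m, bg)
    lomR <- revcomp_lom(lom)
    dF <- score_distribution(lom, bg, bin_width)
    dR <- score_distribution(lomR, bg, bin_width)
    list(id = motif_id(m), L = nrow(lom), lomF = lom, lomR = lomR,
         distF = dF, distR = dR,
         thrF = threshold_score(dF, p_threshold),
         thrR = threshold_score(dR, p_threshold))
  })
  structure(list(motifs = motifs, bg = bg, p_threshold = p_threshold,
                 motif_ids = vapply(motifs, `[[`, character(1), "id")),
            class = "motif_scanner")
}

# count-only path: number of hits of one motif on both strands
count_encoded <- function(enc, m) {
  sF <- window_scores(enc, m$lomF)
  sR <- window_scores(enc, m$lomR)
  sum(!is.na(sF) & sF >= m$thrF) + sum(!is.na(sR) & sR >= m$thrR)
}

scan_encoded <- function(enc, m) {
  hits <- list()
  for (str in c("+", "-")) {
    lom <- if (str == "+") m$lomF else m$lomR
    thr <- if (str == "+") m$thrF else m$thrR
    dist <- if (str == "+") m$distF else m$distR
    s <- window_scores(enc, lom)
    pos <- which(!is.na(s) & s >= thr)
    if (length(pos))
      hits[[str]] <- data.frame(motif_id = m$id, start = pos - 1L,
                                end = pos - 1L + m$L, strand = str,
                                score = s[pos],
                                pvalue = score_pvalue(dist, s[pos]),
                                stringsAsFactors = FALSE)
  }
  if (length(hits)) do.call(rbind, hits)
  else data.frame(motif_id = character(), start = integer(), end = integer(),
                  strand = character(), score = numeric(), pvalue = numeric(),
                  stringsAsFactors = FALSE)
}

#' Scan a sequence for occurrences of one motif
#'
#' @param sequence DNA string over A/C/G/T/N; windows containing N are
#'   skipped. A sequence shorter than the motif yields no hits.
#' @param x a [pwm()].
#' @param bg background model.
#' @param p_threshold hit threshold on the exact per-position p-value.
#' @return data.frame of hits: `motif_id`, `start`, `end` (0-based,
#'   half-open, relative to the sequence), `strand`, `score` (bits),
#'   `pvalue`.
#' @export
scan_motif <- function(sequence, x, bg = background_model(),
                       p_threshold = 1e-4) {
  sc <- motif_scanner(list(x), bg, p_threshold)
  scan_encoded(encode_dna(sequence), sc$motifs[[1]])
}

#' Count motif hits of a whole library in one sequence
#'
#' @param sequence DNA string.
#' @param library list of PWMs, or a prebuilt [motif_scanner()].
#' @inheritParams scan_motif
#' @return named integer vector of per-motif hit counts (both strands,
#'   overlapping hits all counted).
#' @export
count_hits <- function(sequence, library, bg = background_model(),
                       p_threshold = 1e-4) {
  sc <- if (inherits(library, "motif_scanner")) library
        else motif_scanner(library, bg, p_threshold)
  enc <- encode_dna(sequence)
  counts <- vapply(sc$motifs, function(m) count_encoded(enc, m), integer(1))
  stats::setNames(counts, sc$motif_ids)
}

#' Mean G+C probability of a motif
#' @param x a [pwm()].
#' @return the average over positions of `P(G) + P(C)`, in `[0, 1]`.
#' @export
motif_gc <- function(x) {
  mean(x[, "G"] + x[, "C"])
}

#' Randomly permute the nucleotide probabilities of a PWM
#'
#' Within each position the four probabilities are permuted uniformly at
#' random, preserving the per-position probability multiset (and hence the
#' information content) while destroying base identity.
#'
#' @param x a [pwm()].
#' @return a permuted [pwm()] with id suffixed `"_perm"`.
#' @export
permute_pwm <- function(x) {
  m <- unclass(x)
  for (i in seq_len(nrow(m))) m[i, ] <- m[i, sample.int(4)]
  pwm(m, paste0(motif_id(x), "_perm"), attr(x, "source"))
}

#' Two-sided rank-sum test
#'
#' Exact permutation distribution (handles ties) when the combined sample
#' size is at most `exact_max`; otherwise the tie-corrected normal
#' approximation with continuity correction.
#'
#' @param x,y numeric samples.
#' @param exact_max combined-size cutoff for the exact path (default 20).
#' @return list with `statistic` (Mann-Whitney U of `x`, centered at 0)
#'   and `p.value`.
#' @export
rank_sum_test <- function(x, y, exact_max = 20) {
  nx <- length(x); ny <- length(y)
  if (nx == 0 || ny == 0) stop("both samples must be non-empty")
  r <- rank(c(x, y))
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  stat <- u - nx * ny / 2
  if (nx + ny <= exact_max) {
    splits <- utils::combn(nx + ny, nx)
    w <- colSums(matrix(r[splits], nrow = nx))
    dev <- abs(w - nx * (nx + ny + 1) / 2)
    p <- mean(dev >= abs(stat) - 1e-9)
  } else {
    p <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
  }
  list(statistic = stat, p.value = p)
}

#' Motif over-representation between two sequence sets
#'
#' Per-sequence hit counts of the motif in set A versus set B compared by
#' the two-sided rank-sum test.
#'
#' @param set_a,set_b character vectors of sequences (both non-empty).
#' @param x a [pwm()].
#' @inheritParams scan_motif
#' @return list with `statistic` (centered U; positive when A has more
#'   hits), `p.value`, and the two count vectors.
#' @export
motif_overrepresentation <- function(set_a, set_b, x,
                                     bg = background_model(),
                                     p_threshold = 1e-4) {
  if (length(set_a) == 0 || length(set_b) == 0)
    stop("both sequence sets must be non-empty")
  sc <- motif_scanner(list(x), bg, p_threshold)
  ca <- vapply(set_a, function(s) count_encoded(encode_dna(s),
                                                sc$motifs[[1]]), integer(1))
  cb <- vapply(set_b, function(s) count_encoded(encode_dna(s),
                                                sc$motifs[[1]]), integer(1))
  t <- rank_sum_test(as.numeric(ca), as.numeric(cb))
  list(statistic = t$statistic, p.value = t$p.value,
       counts_a = unname(ca), counts_b = unname(cb))
}
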