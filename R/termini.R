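# Untemplated oligo(A) tail detection against the genome, and discovery of
# the T-run + G transcription start site motif with its position frequency
# matrix.

#' Detect an untemplated 3' tail on one read
#'
#' Anchored at the read's 5' end, the templated match is extended maximally
#' along the genome; the unmatched 3' suffix is the tail. When the suffix is
#' all A and the templated end itself runs through A residues, the true
#' boundary is ambiguous: by the maximal-templated-extension convention the
#' last templated A is reported as the templated end, and the ambiguity is
#' carried as a range `tail_len_min..tail_len_max` (adding the contiguous
#' templated terminal As).
#'
#' @param read_seq read sequence 5'->3' in locus orientation.
#' @param genome_seq genome (or locus-forward window) sequence as one
#'   string, same orientation as the read.
#' @param aligned_start 0-based position of the read's 5' end in
#'   `genome_seq`.
#' @param anchor,strand optional mir-5p anchor; when given, `templated_end`
#'   is also reported as a relative coordinate (`templated_end_rel`).
#' @param max_tail longest suffix accepted as an oligo(A) tail.
#' @return list with `templated_end` (0-based position of the last templated
#'   base in `genome_seq` coordinates), `tail_seq`, `tail_len_min`,
#'   `tail_len_max`, `is_oligoA` (suffix non-empty, all A, 1..max_tail nt)
#'   and optionally `templated_end_rel`.
#' @export
detect_untemplated_tail <- function(read_seq, genome_seq, aligned_start,
                                    anchor = NULL, strand = "+",
                                    max_tail = 10L) {
  n <- nchar(read_seq)
  gseg <- substr(genome_seq, aligned_start + 1L, aligned_start + n)
  rb <- strsplit(read_seq, "", fixed = TRUE)[[1L]]
  gb <- strsplit(gseg, "", fixed = TRUE)[[1L]]
  match_len <- length(gb)
  mism <- which(rb[seq_along(gb)] != gb)
  if (length(mism)) match_len <- mism[1L] - 1L
  if (match_len < 1L)
    stop("not anchored: read 5' end does not match the genome at ",
         aligned_start)
  tail_seq <- substr(read_seq, match_len + 1L, n)
  tail_len <- n - match_len
  # ambiguity: templated terminal As contiguous with an all-A suffix
  ambig <- 0L
  all_a <- tail_len > 0L && grepl("^A+$", tail_seq)
  if (all_a) {
    k <- match_len
    while (k >= 1L && gb[k] == "A") { ambig <- ambig + 1L; k <- k - 1L }
  }
  out <- list(templated_end = aligned_start + match_len - 1L,
              tail_seq = tail_seq,
              tail_len_min = tail_len, tail_len_max = tail_len + ambig,
              is_oligoA = all_a && tail_len <= max_tail)
  if (!is.null(anchor))
    out$templated_end_rel <- to_relative(out$templated_end, anchor, strand)
  out
}

#' Tail calls for a table of aligned reads
#'
#' Runs [detect_untemplated_tail()] over an alignment table (reads whose
#' `seq` may extend past the aligned interval by a tail). Minus-strand reads
#' are processed against the reverse-complemented genome.
#'
#' @param reads alignment data.frame.
#' @param genome DNAStringSet or character genome.
#' @param anchor,strand optional mir-5p anchor for relative coordinates.
#' @return data.frame with one row per read: `read_id`, `templated_end`,
#'   (`templated_end_rel`,) `tail_seq`, `tail_len_min`, `tail_len_max`,
#'   `is_oligoA`.
#' @export
tail_calls <- function(reads, genome, anchor = NULL, strand = NULL) {
  genome_str <- if (is.character(genome)) genome[[1]]
                else as.character(genome)[[1]]
  L <- nchar(genome_str)
  rc <- NULL
  rows <- vector("list", nrow(reads))
  for (i in seq_len(nrow(reads))) {
    r <- reads[i, ]
    if (r$strand == "+") {
      tc <- detect_untemplated_tail(r$seq, genome_str, r$start,
                                    anchor = anchor, strand = "+")
    } else {
      if (is.null(rc)) rc <- revcomp(genome_str)
      # on the reverse-complemented genome the read's 5' end sits at L - end
      tc <- detect_untemplated_tail(r$seq, rc, L - r$end)
      tc$templated_end <- L - 1L - tc$templated_end  # back to + coordinates
      if (!is.null(anchor))
        tc$templated_end_rel <- to_relative(tc$templated_end, anchor, "-")
    }
    rows[[i]] <- data.frame(read_id = r$read_id,
                            templated_end = tc$templated_end,
                            templated_end_rel = if (!is.null(anchor))
                              tc$templated_end_rel else NA_integer_,
                            tail_seq = tc$tail_seq,
                            tail_len_min = tc$tail_len_min,
                            tail_len_max = tc$tail_len_max,
                            is_oligoA = tc$is_oligoA,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(read_id = character(),
                                      templated_end = integer(),
                                      templated_end_rel = integer(),
                                      tail_seq = character(),
                                      tail_len_min = integer(),
                                      tail_len_max = integer(),
                                      is_oligoA = logical())
  out
}

#' Tail spectrum of a locus
#'
#' Two-dimensional census of oligo(A) tail calls: counts per (templated end,
#' minimum tail length), deterministically ordered.
#'
#' @param tc output of [tail_calls()].
#' @param use_rel use relative (TRUE) or genomic templated-end coordinates.
#' @return data.frame with `templated_end`, `tail_len`, `count`; total
#'   count equals the number of oligo(A) calls.
#' @export
tail_spectrum <- function(tc, use_rel = TRUE) {
  tc <- tc[tc$is_oligoA, , drop = FALSE]
  if (!nrow(tc))
    return(data.frame(templated_end = integer(), tail_len = integer(),
                      count = integer()))
  ends <- if (use_rel && !all(is.na(tc$templated_end_rel)))
    tc$templated_end_rel else tc$templated_end
  agg <- stats::aggregate(list(count = rep(1L, nrow(tc))),
                          by = list(templated_end = ends,
                                    tail_len = tc$tail_len_min), FUN = sum)
  agg <- agg[order(agg$templated_end, agg$tail_len), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Find T-run + G transcription start site motifs
#'
#' Scans a window upstream of an anchor (typically the 5'-most covered
#' position of the pri-transcript) on the locus strand for maximal runs of
#' >= `min_run` T residues immediately followed by a G; the G is the
#' predicted TSS. Hits are ranked by run length (descending), then distance
#' to the anchor (ascending).
#'
#' @param genome DNAStringSet or character genome.
#' @param anchor 0-based genomic position anchoring the scan (its 5'-most
#'   covered position).
#' @param strand locus strand.
#' @param window how far upstream of the anchor to scan (nt).
#' @param min_run minimum T-run length.
#' @return data.frame with `predicted_tss` (0-based genomic position of the
#'   G), `run_start`, `run_length`, `distance_to_anchor`; zero rows if no
#'   motif is found.
#' @export
find_tss_motif <- function(genome, anchor, strand = "+", window = 140L,
                           min_run = 8L) {
  genome_str <- if (is.character(genome)) genome[[1]]
                else as.character(genome)[[1]]
  L <- nchar(genome_str)
  empty <- data.frame(predicted_tss = integer(), run_start = integer(),
                      run_length = integer(), distance_to_anchor = integer())
  if (strand == "+") {
    lo <- max(0L, anchor - window); hi <- min(L - 1L, anchor)
    s <- substr(genome_str, lo + 1L, hi + 1L)
    to_gen <- function(off) lo + off  # 0-based offset in s -> genomic
  } else {
    lo <- max(0L, anchor); hi <- min(L - 1L, anchor + window)
    s <- revcomp(substr(genome_str, lo + 1L, hi + 1L))
    to_gen <- function(off) hi - off
  }
  m <- gregexpr(sprintf("T{%d,}G", min_run), s)[[1L]]
  if (m[1L] == -1L) return(empty)
  len <- attr(m, "match.length")
  g_off <- as.integer(m) + len - 2L       # 0-based offset of the G in s
  run_len <- len - 1L
  # maximality: the base before the run must not be T
  run_start_off <- as.integer(m) - 1L
  ok <- run_start_off == 0L |
    substr(s, run_start_off, run_start_off) != "T"
  hits <- data.frame(predicted_tss = vapply(g_off[ok], to_gen, numeric(1)),
                     run_start = vapply(run_start_off[ok], to_gen,
                                        numeric(1)),
                     run_length = run_len[ok],
                     distance_to_anchor = abs(anchor -
                       vapply(g_off[ok], to_gen, numeric(1))))
  hits[order(-hits$run_length, hits$distance_to_anchor), , drop = FALSE]
}

#' Position frequency matrix of TSS motifs
#'
#' Aligns per-locus windows at the motif G (position +1) and tabulates base
#' frequencies per position from -upstream_span to +1. Loci whose window
#' would run off the segment are dropped with a warning.
#'
#' @param tss_hits data.frame with one row per locus: `predicted_tss` and
#'   `strand` columns.
#' @param genome DNAStringSet or character genome.
#' @param upstream_span how many positions upstream of the G to include.
#' @return 4 x (upstream_span + 1) matrix (rows A/C/G/T, columns
#'   -upstream_span..-1, +1); every column sums to 1, and column +1 has G
#'   frequency 1 by construction of the motif.
#' @export
build_pfm <- function(tss_hits, genome, upstream_span = 30L) {
  stopifnot(nrow(tss_hits) >= 1L)
  genome_str <- if (is.character(genome)) genome[[1]]
                else as.character(genome)[[1]]
  L <- nchar(genome_str)
  wins <- character(0)
  for (i in seq_len(nrow(tss_hits))) {
    tss <- tss_hits$predicted_tss[i]
    strand <- if (!is.null(tss_hits$strand)) tss_hits$strand[i] else "+"
    if (strand == "+") {
      if (tss - upstream_span < 0L) {
        warning("window off segment for row ", i, "; dropped"); next
      }
      wins <- c(wins, substr(genome_str, tss - upstream_span + 1L, tss + 1L))
    } else {
      if (tss + upstream_span > L - 1L) {
        warning("window off segment for row ", i, "; dropped"); next
      }
      wins <- c(wins, revcomp(substr(genome_str, tss + 1L,
                                     tss + upstream_span + 1L)))
    }
  }
  if (!length(wins)) stop("no usable motif windows")
  mat <- do.call(rbind, strsplit(wins, "", fixed = TRUE))
  pfm <- apply(mat, 2L, function(col)
    table(factor(col, levels = c("A", "C", "G", "T"))) / length(col))
  colnames(pfm) <- c(seq(-upstream_span, -1L), "+1")
  rownames(pfm) <- c("A", "C", "G", "T")
  pfm
}
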