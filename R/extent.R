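# Primary-transcript extent analysis from long RNA coverage: 5'/3' extremes
# in mir-5p-relative coordinates, knockout enrichment, readthrough into a
# downstream gene across A-rich coverage gaps, and 3'-end censuses.

#' Transcript extent of a locus from coverage
#'
#' The 5'-most and 3'-most positions with depth >= `min_depth` inside the
#' locus search window, reported in the signed mir-5p-relative system.
#'
#' @param track a [coverage_track()] on the locus strand.
#' @param locus list/row with `anchor` (mir-5p first nt, 0-based genomic),
#'   `strand`, and a search window `span_start`/`span_end` (0-based
#'   half-open; e.g. TSS scan region to downstream gene).
#' @param min_depth minimum depth for a position to count as covered.
#' @return list with `five_prime_most`, `three_prime_most` (relative
#'   coordinates), `covered` (n positions); NULL if nothing is covered.
#' @export
transcript_extent <- function(track, locus, min_depth = 1) {
  pos <- locus$span_start:(locus$span_end - 1L)
  depth <- track_depth(track, pos)
  cov <- pos[depth >= min_depth]
  if (!length(cov)) return(NULL)
  rel <- sort(to_relative(range(cov), locus$anchor, locus$strand))
  list(five_prime_most = rel[1L], three_prime_most = rel[2L],
       covered = length(cov), min_depth = min_depth)
}

#' Knockout enrichment of locus transcripts
#'
#' Pseudocounted log2 fold change of knockout vs wild-type coverage over the
#' locus window, in reads per million.
#'
#' @param track_wt,track_ko coverage tracks with library sizes.
#' @param locus list/row with `window_start`, `window_end`.
#' @param pseudocount added to both cpm values.
#' @return list with `wt_cpm`, `ko_cpm`, `log2fc`, `direction`.
#' @export
locus_enrichment <- function(track_wt, track_ko, locus, pseudocount = 1) {
  pos <- locus$window_start:(locus$window_end - 1L)
  wt <- sum(track_depth(track_wt, pos)) / track_wt$library_size * 1e6
  ko <- sum(track_depth(track_ko, pos)) / track_ko$library_size * 1e6
  lfc <- log2((ko + pseudocount) / (wt + pseudocount))
  list(wt_cpm = wt, ko_cpm = ko, log2fc = lfc,
       direction = if (lfc > 0) "up_in_ko" else
                   if (lfc < 0) "down_in_ko" else "unchanged")
}

#' Detect transcriptional readthrough into a downstream gene
#'
#' Walks coverage from the hairpin 3' edge toward the downstream feature.
#' Zero-depth gaps are tolerated iff they are at most `max_gap` nt long and
#' the gapped genomic sequence is at least `a_frac` A on the locus strand
#' (A-homopolymers resist sequencing, so their dropouts are not evidence of
#' termination). The locus reads through iff covered positions inside the
#' feature are reached.
#'
#' @param track coverage track on the locus strand.
#' @param locus list/row with `hp_start`, `hp_end`, `strand`.
#' @param downstream_feature list/row with `start`, `end` (0-based
#'   half-open), 3' of the hairpin on the locus strand.
#' @param genome DNAStringSet or character genome sequence.
#' @param max_gap longest tolerable zero-coverage gap (nt).
#' @param a_frac minimum A fraction of a tolerated gap (locus strand).
#' @param min_depth depth threshold for "covered".
#' @return list with `bridged`, `gaps` (data.frame of zero runs with their
#'   lengths and A fractions), `reached` (covered positions in feature).
#' @export
detect_readthrough <- function(track, locus, downstream_feature, genome,
                               max_gap = 50L, a_frac = 0.8, min_depth = 1) {
  genome_str <- if (is.character(genome)) genome[[1]]
                else as.character(genome)[[1]]
  fs <- downstream_feature$start; fe <- downstream_feature$end
  if (locus$strand == "+") {
    if (fs < locus$hp_end) stop("downstream feature is not 3' of the hairpin")
    walk <- locus$hp_end:(fe - 1L)
  } else {
    if (fe > locus$hp_start) stop("downstream feature is not 3' of the hairpin")
    walk <- (locus$hp_start - 1L):fs  # 3'-wards on the minus strand
  }
  depth <- track_depth(track, walk)
  in_feat <- walk >= fs & walk < fe
  reached <- sum(depth[in_feat] >= min_depth)
  # zero-depth runs between the hairpin edge and the last covered feature pos
  covered <- depth >= min_depth
  gaps <- data.frame(start = integer(), length = integer(),
                     a_fraction = numeric(), tolerated = logical())
  feat_hit <- which(covered & in_feat)
  bridged <- FALSE
  if (length(feat_hit)) {
    upto <- feat_hit[length(feat_hit)]
    r <- rle(covered[seq_len(upto)])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    z <- which(!r$values)
    if (length(z)) {
      gpos <- lapply(z, function(k) walk[starts[k]:ends[k]])
      af <- vapply(gpos, function(p) {
        b <- strsplit(substr(genome_str, min(p) + 1L, max(p) + 1L),
                      "", fixed = TRUE)[[1L]]
        base <- if (locus$strand == "+") "A" else "T"  # A on locus strand
        mean(b == base)
      }, numeric(1))
      glen <- r$lengths[z]
      gaps <- data.frame(start = vapply(gpos, min, numeric(1)),
                         length = glen, a_fraction = af,
                         tolerated = glen <= max_gap & af >= a_frac)
    }
    bridged <- all(gaps$tolerated) && reached > 0L
  }
  list(bridged = bridged, gaps = gaps, reached = reached)
}

#' Census of observed 3' ends
#'
#' Counts clones/reads per distinct 3'-end position; the dominant end is the
#' most frequent one, ties resolved toward the 3'-most.
#'
#' @param ends vector of 3'-end positions (relative coordinates), one entry
#'   per clone or read.
#' @return data.frame with `end` and `count`, sorted by position, with
#'   attributes `dominant` and `total`; zero rows for empty input.
#' @export
end_census <- function(ends) {
  if (!length(ends)) {
    out <- data.frame(end = integer(), count = integer())
    attr(out, "dominant") <- NA_integer_
    attr(out, "total") <- 0L
    return(out)
  }
  tab <- table(ends)
  out <- data.frame(end = as.integer(names(tab)), count = as.integer(tab))
  out <- out[order(out$end), , drop = FALSE]
  rownames(out) <- NULL
  best <- out$end[out$count == max(out$count)]
  attr(out, "dominant") <- max(best)
  attr(out, "total") <- sum(out$count)
  out
}

#' Transcript extents and enrichment for every miRNA locus
#'
#' Convenience driver over [transcript_extent()] and [locus_enrichment()]
#' for a set of loci against wild-type and knockout tracks.
#'
#' @param loci data.frame of loci (`locus_id`, `anchor`, `strand`,
#'   `window_start`, `window_end`, plus `span_start`/`span_end` or
#'   `tss`/`pri_end` to derive the search window).
#' @param coverage named list `wt`/`ko`, each a per-strand list of tracks.
#' @param min_depth passed to [transcript_extent()].
#' @param pad extra nt searched on both sides of the known/expected span.
#' @return data.frame with per-locus, per-genotype extents and the
#'   knockout enrichment.
#' @export
extent_table <- function(loci, coverage, min_depth = 1, pad = 100L) {
  rows <- list()
  for (i in seq_len(nrow(loci))) {
    locus <- as.list(loci[i, ])
    if (is.null(locus$span_start) || is.na(locus$span_start)) {
      span <- range(c(locus$tss, locus$pri_end,
                      if (!is.na(locus$dsg_end)) c(locus$dsg_start,
                                                   locus$dsg_end - 1L)))
      locus$span_start <- span[1L] - pad
      locus$span_end <- span[2L] + 1L + pad
    }
    tr_wt <- coverage$wt[[locus$strand]]
    tr_ko <- coverage$ko[[locus$strand]]
    e_wt <- transcript_extent(tr_wt, locus, min_depth)
    e_ko <- transcript_extent(tr_ko, locus, min_depth)
    enr <- locus_enrichment(tr_wt, tr_ko, locus)
    rows[[i]] <- data.frame(
      locus_id = locus$locus_id,
      wt_5p = if (is.null(e_wt)) NA_integer_ else e_wt$five_prime_most,
      wt_3p = if (is.null(e_wt)) NA_integer_ else e_wt$three_prime_most,
      ko_5p = if (is.null(e_ko)) NA_integer_ else e_ko$five_prime_most,
      ko_3p = if (is.null(e_ko)) NA_integer_ else e_ko$three_prime_most,
      wt_cpm = enr$wt_cpm, ko_cpm = enr$ko_cpm, log2fc = enr$log2fc,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
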