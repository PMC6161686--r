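# Size distribution and hierarchical classification of small RNA reads into
# annotation categories, as used for the 21-nt read population breakdown.

#' Classification categories
#'
#' Default priority order for hierarchical read classification. Structured
#' ncRNA annotations are unambiguous and take precedence; repeat families
#' come before mRNA so that repeat-derived siRNAs dominate; anything without
#' a qualifying feature overlap is intergenic.
#' @export
CLASS_PRIORITY <- c("tRNA", "rRNA", "snoRNA", "snRNA", "SRP", "classI",
                    "DIRS1", "complex_repeat", "mRNA_sense",
                    "mRNA_antisense", "intergenic")

# feature type -> classification category (mRNA handled separately by strand)
MRNA_LIKE <- c("mRNA", "exon", "intron", "gene_downstream")

#' Size histogram of a small RNA library
#'
#' Bins reads by aligned length over the 18-40 nt library window.
#'
#' @param reads alignment data.frame.
#' @param range length range to bin (defaults to the library window).
#' @return data.frame with `length` and `count`; total count equals the
#'   number of reads.
#' @export
size_histogram <- function(reads, range = 18:40) {
  len <- reads$end - reads$start
  data.frame(length = range,
             count = as.integer(table(factor(len, levels = range))))
}

#' Classify reads against an annotation
#'
#' Each read is assigned the single highest-priority category among features
#' it overlaps by at least half of its aligned length. mRNA-like overlap is
#' split into sense/antisense by strand; reads with no qualifying overlap
#' are intergenic.
#'
#' @param reads alignment data.frame.
#' @param features feature data.frame (see [features_df()]).
#' @param priority_order total order over categories (first = highest).
#' @param min_overlap minimum fraction of the read covered by the feature.
#' @return character vector of categories, one per read.
#' @export
classify_reads <- function(reads, features, priority_order = CLASS_PRIORITY,
                           min_overlap = 0.5) {
  stopifnot(setequal(priority_order, CLASS_PRIORITY))
  n <- nrow(reads)
  out <- rep("intergenic", n)
  if (n == 0L) return(out)
  usable <- features$ftype %in% c(setdiff(CLASS_PRIORITY, c(
    "mRNA_sense", "mRNA_antisense", "intergenic")), MRNA_LIKE)
  features <- features[usable, , drop = FALSE]
  rank <- stats::setNames(seq_along(priority_order), priority_order)
  best <- rep(Inf, n)
  for (seg in unique(reads$segment)) {
    ri <- which(reads$segment == seg)
    fi <- which(features$segment_id == seg)
    if (!length(ri) || !length(fi)) next
    rr <- IRanges::IRanges(start = reads$start[ri] + 1L, end = reads$end[ri])
    fr <- IRanges::IRanges(start = features$start[fi] + 1L,
                           end = features$end[fi])
    ov <- IRanges::findOverlaps(rr, fr)
    if (!length(ov)) next
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    w <- IRanges::width(IRanges::pintersect(rr[qh], fr[sh]))
    keep <- w >= min_overlap * IRanges::width(rr[qh])
    qh <- qh[keep]; sh <- sh[keep]
    if (!length(qh)) next
    ft <- features$ftype[fi][sh]
    cat_hit <- ifelse(ft %in% MRNA_LIKE,
                      ifelse(features$strand[fi][sh] == reads$strand[ri][qh],
                             "mRNA_sense", "mRNA_antisense"),
                      ft)
    r <- unname(rank[cat_hit])
    idx <- ri[qh]
    o <- order(idx, r)
    f <- !duplicated(idx[o])
    sel_idx <- idx[o][f]; sel_r <- r[o][f]; sel_cat <- cat_hit[o][f]
    upd <- sel_r < best[sel_idx]
    best[sel_idx[upd]] <- sel_r[upd]
    out[sel_idx[upd]] <- sel_cat[upd]
  }
  out
}

#' Category fractions of length-selected reads
#'
#' Fractions of reads of a given length (default 21 nt) per category.
#' Multimapping reads are counted once at their reported placement by
#' default; `weight = "fractional"` weights each read by 1/hits instead.
#'
#' @param reads alignment data.frame.
#' @param features feature data.frame.
#' @param length_filter read length to select (NULL = all lengths).
#' @param priority_order see [classify_reads()].
#' @param weight `"once"` or `"fractional"`.
#' @return data.frame with `category`, `weight` and `fraction`; fractions
#'   sum to 1.
#' @export
category_fractions <- function(reads, features, length_filter = 21L,
                               priority_order = CLASS_PRIORITY,
                               weight = c("once", "fractional")) {
  weight <- match.arg(weight)
  if (!is.null(length_filter))
    reads <- reads[(reads$end - reads$start) %in% length_filter, ,
                   drop = FALSE]
  if (nrow(reads) == 0L) stop("empty denominator: no reads after filter")
  cat <- classify_reads(reads, features, priority_order)
  w <- if (weight == "once") rep(1, nrow(reads)) else 1 / reads$hits
  tot <- tapply(w, factor(cat, levels = priority_order), sum, default = 0)
  data.frame(category = priority_order,
             weight = as.numeric(tot),
             fraction = as.numeric(tot) / sum(tot))
}
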