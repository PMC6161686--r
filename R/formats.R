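# Internal coordinate convention: 0-based half-open [start, end) everywhere.
# The signed, zero-free coordinate system relative to the first nucleotide of
# mir-5p exists only at reporting boundaries (to_relative / from_relative).

#' Reverse complement of a DNA string
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector, reverse complement.
#' @export
revcomp <- function(x) {
  out <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(out, "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""), character(1))
}

#' Read a genome FASTA file
#'
#' Sequences are upper-cased and U residues are mapped to T, so RNA FASTA is
#' accepted. Any character outside A/C/G/T/N is rejected with the position of
#' the first offending base.
#'
#' @param path path to a FASTA file.
#' @return a named [Biostrings::DNAStringSet] of genome segments.
#' @export
read_fasta <- function(path) {
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop("empty FASTA file: ", path)
  seqs <- toupper(as.character(raw))
  seqs <- chartr("U", "T", seqs)
  bad <- regexpr("[^ACGTN]", seqs)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf("illegal character '%s' in sequence '%s' at position %d",
                 substr(seqs[i], bad[i], bad[i]), names(raw)[i], bad[i]))
  }
  # first word of the header line is the segment id
  names(seqs) <- sub("\\s.*$", "", names(raw))
  Biostrings::DNAStringSet(seqs)
}

#' Write genome segments to FASTA
#' @param genome named character vector or DNAStringSet.
#' @param path output path.
#' @export
write_fasta <- function(genome, path) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

# Feature types understood by the classification and calling modules.
FEATURE_TYPES <- c("tRNA", "rRNA", "snoRNA", "snRNA", "SRP", "classI",
                   "mRNA", "exon", "intron", "DIRS1", "complex_repeat",
                   "hairpin_candidate", "gene_downstream")

#' Construct a feature table
#'
#' Features use 0-based half-open intervals on a genome segment.
#'
#' @param id,ftype,segment_id,start,end,strand vectors of equal length.
#' @return data.frame with the feature columns, validated.
#' @export
features_df <- function(id, ftype, segment_id, start, end, strand) {
  df <- data.frame(id = as.character(id), ftype = as.character(ftype),
                   segment_id = as.character(segment_id),
                   start = as.integer(start), end = as.integer(end),
                   strand = as.character(strand), stringsAsFactors = FALSE)
  bad <- which(!(df$ftype %in% FEATURE_TYPES))
  if (length(bad)) stop("unknown feature type: ", df$ftype[bad[1L]])
  if (any(df$start < 0L) || any(df$end <= df$start))
    stop("feature intervals must satisfy 0 <= start < end")
  if (any(!df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  df
}

#' Read features from GFF3
#'
#' The feature type is taken from column 3 verbatim; intervals are converted
#' to the internal 0-based half-open convention.
#'
#' @param path GFF3 file.
#' @return feature data.frame (see [features_df()]).
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  id <- as.character(S4Vectors::mcols(gr)$ID)
  if (is.null(id) || all(is.na(id)))
    id <- sprintf("feat%05d", seq_along(gr))
  features_df(id = id,
              ftype = as.character(S4Vectors::mcols(gr)$type),
              segment_id = as.character(GenomicRanges::seqnames(gr)),
              start = GenomicRanges::start(gr) - 1L,
              end = GenomicRanges::end(gr),
              strand = as.character(GenomicRanges::strand(gr)))
}

#' Write features to GFF3
#' @param features feature data.frame.
#' @param path output path.
#' @export
write_gff3 <- function(features, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = features$segment_id,
    ranges = IRanges::IRanges(start = features$start + 1L,
                              end = features$end),
    strand = features$strand,
    type = features$ftype,
    ID = features$id)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Convert a genomic position to a mir-5p-relative coordinate
#'
#' Positions are reported in the signed, zero-free system anchored at the
#' first nucleotide of mir-5p: +1 is always the mir-5p first nucleotide,
#' upstream positions are negative, and 0 does not exist.
#'
#' @param pos 0-based genomic position(s).
#' @param anchor 0-based genomic position of the mir-5p first nucleotide.
#' @param strand locus strand, `"+"` or `"-"`.
#' @return integer relative coordinate(s), never 0.
#' @export
to_relative <- function(pos, anchor, strand = "+") {
  d <- if (strand == "+") pos - anchor else anchor - pos
  ifelse(d >= 0L, d + 1L, d)
}

#' Convert a mir-5p-relative coordinate back to a genomic position
#' @param value signed nonzero relative coordinate(s).
#' @param anchor,strand as in [to_relative()].
#' @return 0-based genomic position(s).
#' @export
from_relative <- function(value, anchor, strand = "+") {
  if (any(value == 0L)) stop("relative coordinate 0 does not exist")
  d <- ifelse(value > 0L, value - 1L, value)
  if (strand == "+") anchor + d else anchor - d
}

#' Inclusive span length between two relative coordinates
#'
#' Counts the positions from `a` to `b` inclusive, skipping the nonexistent
#' position 0. E.g. a transcript mapped from -281 to +388 is 669 nt long.
#'
#' @param a,b signed nonzero relative coordinates with `a < b`.
#' @return integer length in nucleotides.
#' @export
span_length <- function(a, b) {
  if (any(a == 0L) || any(b == 0L)) stop("relative coordinate 0 does not exist")
  if (any(a >= b)) stop("span_length requires a < b")
  ifelse(a < 0L & b > 0L, -a + b, b - a + 1L)
}

ALN_COLS <- c("read_id", "segment", "start", "end", "strand", "seq",
              "mismatches", "hits")

validate_alignments <- function(df, origin = "alignments") {
  for (col in ALN_COLS)
    if (is.null(df[[col]])) stop(origin, ": missing column '", col, "'")
  n <- nrow(df)
  if (n == 0L) return(df)
  len <- nchar(df$seq)
  width <- df$end - df$start
  checks <- list(
    "end must be greater than start" = width <= 0L,
    "read length must be within 18-40 nt" = len < 18L | len > 40L,
    "aligned span cannot exceed read length" = width > len,
    "strand must be '+' or '-'" = !(df$strand %in% c("+", "-")),
    "mismatches must be >= 0" = df$mismatches < 0L,
    "hits must be >= 1" = df$hits < 1L,
    "start must be >= 0" = df$start < 0L)
  for (msg in names(checks)) {
    bad <- which(checks[[msg]])
    if (length(bad))
      stop(sprintf("%s: record %d (%s): %s", origin, bad[1L],
                   df$read_id[bad[1L]], msg))
  }
  df
}

#' Read small RNA alignments
#'
#' Two dialects are supported. `"tsv"` is the package's own lossless tabular
#' dialect with columns read_id, segment, start, end, strand, seq, mismatches,
#' hits (0-based half-open intervals; seq is the read 5'->3' as sequenced, so
#' it may extend past the aligned span by an untemplated tail). `"sam"` maps
#' mapped primary records only, with match-block CIGARs; the seq of minus
#' strand records is reverse-complemented back into read orientation.
#'
#' @param path input file.
#' @param dialect `"tsv"` or `"sam"`.
#' @return alignment data.frame.
#' @export
read_alignments <- function(path, dialect = c("tsv", "sam")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    df <- utils::read.delim(path, header = TRUE, comment.char = "#",
                            colClasses = c(read_id = "character",
                                           segment = "character",
                                           start = "integer", end = "integer",
                                           strand = "character",
                                           seq = "character",
                                           mismatches = "integer",
                                           hits = "integer"))
    return(validate_alignments(df, origin = path))
  }
  read_sam_alignments(path)
}

read_sam_alignments <- function(path) {
  bam <- Rsamtools::asBam(path,
                          destination = tempfile(fileext = ""),
                          overwrite = TRUE, indexDestination = FALSE)
  on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "rname", "pos", "strand", "cigar", "seq"),
    tag = c("NM", "NH"), flag = flags)
  rec <- Rsamtools::scanBam(bam, param = p)[[1L]]
  n <- length(rec$qname)
  if (n == 0L)
    return(validate_alignments(
      data.frame(read_id = character(), segment = character(),
                 start = integer(), end = integer(), strand = character(),
                 seq = character(), mismatches = integer(), hits = integer())))
  ref_width <- cigar_ref_width(rec$cigar)
  seq <- as.character(rec$seq)
  strand <- as.character(rec$strand)
  flip <- strand == "-"
  seq[flip] <- revcomp(seq[flip])
  nm <- rec$tag$NM
  nh <- rec$tag$NH
  if (is.null(nm)) nm <- rep(0L, n) else nm[is.na(nm)] <- 0L
  if (is.null(nh)) nh <- rep(1L, n) else nh[is.na(nh)] <- 1L
  validate_alignments(data.frame(
    read_id = rec$qname, segment = as.character(rec$rname),
    start = rec$pos - 1L, end = rec$pos - 1L + ref_width,
    strand = strand, seq = seq,
    mismatches = as.integer(nm), hits = as.integer(nh),
    stringsAsFactors = FALSE), origin = path)
}

# Reference-space width of match-block CIGARs (nM or n=/nX/nD/nN runs).
cigar_ref_width <- function(cigar) {
  ops <- gregexpr("(\\d+)([MIDNSHP=X])", cigar)
  vapply(seq_along(cigar), function(i) {
    m <- regmatches(cigar[i], ops[i])[[1L]]
    if (!length(m)) stop("unparseable CIGAR: ", cigar[i])
    lens <- as.integer(sub("[A-Z=]$", "", m))
    code <- sub("^\\d+", "", m)
    if (any(!code %in% c("M", "=", "X", "S")))
      stop("unsupported CIGAR operation in '", cigar[i],
           "': only match blocks (with soft clips) are supported")
    sum(lens[code %in% c("M", "=", "X")])
  }, integer(1))
}

#' Write small RNA alignments in the TSV dialect
#' @param reads alignment data.frame.
#' @param path output path.
#' @export
write_alignments <- function(reads, path) {
  validate_alignments(reads[ALN_COLS], origin = "write_alignments")
  utils::write.table(reads[ALN_COLS], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Construct a per-base coverage track
#'
#' A track holds per-position counts for a window of one strand of one
#' segment, together with the library size used for per-million scaling.
#'
#' @param segment_id segment name.
#' @param strand `"+"` or `"-"`.
#' @param start 0-based position of the first count.
#' @param counts numeric vector of non-negative per-position counts.
#' @param library_size total mapped reads in the originating library.
#' @return object of class `coverage_track`.
#' @export
coverage_track <- function(segment_id, strand, start, counts, library_size) {
  stopifnot(all(counts >= 0), library_size >= 1, start >= 0)
  structure(list(segment_id = segment_id, strand = strand,
                 start = as.integer(start), counts = as.numeric(counts),
                 library_size = as.numeric(library_size)),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("coverage_track %s(%s) [%d,%d) total=%g lib=%g\n",
              x$segment_id, x$strand, x$start, x$start + length(x$counts),
              sum(x$counts), x$library_size))
  invisible(x)
}

# Depth at 0-based positions (0 outside the track window).
track_depth <- function(track, pos) {
  i <- pos - track$start + 1L
  out <- numeric(length(pos))
  ok <- i >= 1L & i <= length(track$counts)
  out[ok] <- track$counts[i[ok]]
  out
}

#' Read a bedGraph coverage file
#' @param path bedGraph file.
#' @param strand strand the track belongs to (bedGraph itself is strandless).
#' @param library_size total mapped reads of the library.
#' @return a [coverage_track()].
#' @export
read_bedgraph <- function(path, strand = "+", library_size = 1e6) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (length(gr) == 0L) stop("empty bedGraph: ", path)
  if (length(unique(as.character(GenomicRanges::seqnames(gr)))) > 1L)
    stop("multi-segment bedGraph tracks are not supported")
  s0 <- min(GenomicRanges::start(gr)) - 1L
  e0 <- max(GenomicRanges::end(gr))
  counts <- numeric(e0 - s0)
  for (i in seq_along(gr)) {
    a <- GenomicRanges::start(gr)[i] - s0
    b <- GenomicRanges::end(gr)[i] - s0
    counts[a:b] <- S4Vectors::mcols(gr)$score[i]
  }
  coverage_track(as.character(GenomicRanges::seqnames(gr))[1L], strand,
                 s0, counts, library_size)
}

#' Write a coverage track as bedGraph
#' @param track a [coverage_track()].
#' @param path output path.
#' @export
write_bedgraph <- function(track, path) {
  r <- rle(track$counts)
  ends <- cumsum(r$lengths)
  starts <- c(0L, ends[-length(ends)])
  keep <- r$values != 0
  df <- data.frame(chrom = track$segment_id,
                   start = track$start + starts[keep],
                   end = track$start + ends[keep],
                   score = r$values[keep])
  writeLines(sprintf("%s\t%d\t%d\t%g", df$chrom, df$start, df$end, df$score),
             path)
  invisible(path)
}

#' Write a per-locus report table
#'
#' Plain TSV with optional `# key=value` header comments.
#'
#' @param calls data.frame of locus calls.
#' @param path output path.
#' @param header named character vector written as `# name=value` lines.
#' @export
write_report <- function(calls, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header))
    writeLines(sprintf("# %s=%s", names(header), unname(header)), con)
  utils::write.table(calls, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
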