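test_that("read_fasta normalizes case and RNA alphabet", {
  f <- tempfile(fileext = ".fa")
  writeLines(c(">x", "acgt"), f)
  g <- read_fasta(f)
  expect_equal(as.character(g), c(x = "ACGT"))
  writeLines(c(">x", "ACGU"), f)
  expect_equal(as.character(read_fasta(f)), c(x = "ACGT"))
  writeLines(c(">a desc", "AAAA", ">b", "CCGG"), f)
  g <- read_fasta(f)
  expect_equal(names(g), c("a", "b"))
  writeLines(c(">x", "ACXT"), f)
  expect_error(read_fasta(f), "illegal character 'X'.*position 3")
  writeLines(character(0), f)
  expect_error(read_fasta(f))
})

test_that("fasta round-trips through write_fasta", {
  f <- tempfile(fileext = ".fa")
  g <- c(chr1 = "ACGTACGTAAATTTGGGCCC", chr2 = "TTTTAAAACCCCGGGG")
  write_fasta(g, f)
  expect_equal(as.character(read_fasta(f)), g)
})

test_that("relative coordinates are signed, zero-free and anchored at +1", {
  expect_equal(to_relative(100L, 100L, "+"), 1L)
  expect_equal(to_relative(99L, 100L, "+"), -1L)
  expect_equal(to_relative(100L, 100L, "-"), 1L)
  expect_equal(to_relative(101L, 100L, "-"), -1L)
  expect_error(from_relative(0L, 50L, "+"), "0 does not exist")
})

test_that("to_relative/from_relative are inverse bijections", {
  set.seed(4)
  for (strand in c("+", "-")) {
    pos <- sample.int(1e6, 5000L)
    anchor <- sample.int(1e6, 5000L)
    rel <- to_relative(pos, anchor, strand)
    expect_true(all(rel != 0L))
    expect_equal(from_relative(rel, anchor, strand), pos)
  }
  # and the reverse direction: every nonzero value maps back
  vals <- setdiff(-500:500, 0)
  expect_equal(to_relative(from_relative(vals, 1000L, "+"), 1000L, "+"),
               vals)
  expect_equal(to_relative(from_relative(vals, 1000L, "-"), 1000L, "-"),
               vals)
})

test_that("span_length matches brute-force position counting", {
  # the worked example: a transcript from -281 to +388 is 669 nt
  expect_equal(span_length(-281L, 388L), 669L)
  expect_equal(span_length(-1L, 1L), 2L)
  expect_equal(span_length(5L, 9L), 5L)
  set.seed(11)
  for (r in 1:200) {
    ab <- sort(sample(setdiff(-500:500, 0), 2L))
    expect_equal(span_length(ab[1L], ab[2L]),
                 length(setdiff(ab[1L]:ab[2L], 0L)))
  }
  expect_error(span_length(5L, 5L), "a < b")
  expect_error(span_length(3L, -3L), "a < b")
})

test_that("alignment TSV dialect round-trips losslessly", {
  sim <- default_sim()
  reads <- sim$reads$wt_0h[1:500, ]
  f <- tempfile(fileext = ".tsv")
  write_alignments(reads, f)
  back <- read_alignments(f, "tsv")
  rownames(reads) <- NULL
  expect_equal(back, reads, ignore_attr = TRUE)
})

test_that("malformed alignment records are rejected with their position", {
  f <- tempfile(fileext = ".tsv")
  df <- data.frame(read_id = "r1", segment = "chr1", start = 100L,
                   end = 90L, strand = "+", seq = strrep("A", 21),
                   mismatches = 0L, hits = 1L)
  utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_alignments(f, "tsv"), "record 1.*end must be greater")
  df$end <- 121L
  df$seq <- strrep("A", 50)
  utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_alignments(f, "tsv"), "18-40")
})

test_that("empty alignment file yields an empty table", {
  f <- tempfile(fileext = ".tsv")
  writeLines(paste(c("read_id", "segment", "start", "end", "strand", "seq",
                     "mismatches", "hits"), collapse = "\t"), f)
  expect_equal(nrow(read_alignments(f, "tsv")), 0L)
})

test_that("SAM reader maps mapped primary records only", {
  f <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:unknown",
    "@SQ\tSN:chr1\tLN:1000",
    paste("r1", 0, "chr1", 101, 255, "21M", "*", 0, 0,
          strrep("A", 21), "*", "NM:i:1", "NH:i:2", sep = "\t"),
    paste("r2", 16, "chr1", 201, 255, "21M", "*", 0, 0,
          strrep("A", 21), "*", sep = "\t"),
    paste("r3", 4, "*", 0, 0, "*", "*", 0, 0,
          strrep("C", 21), "*", sep = "\t"),
    paste("r4", 256, "chr1", 301, 255, "21M", "*", 0, 0,
          strrep("G", 21), "*", sep = "\t")), f)
  aln <- read_alignments(f, "sam")
  expect_equal(sort(aln$read_id), c("r1", "r2"))
  r1 <- aln[aln$read_id == "r1", ]
  expect_equal(c(r1$start, r1$end, r1$mismatches, r1$hits),
               c(100L, 121L, 1L, 2L))
  r2 <- aln[aln$read_id == "r2", ]
  expect_equal(r2$strand, "-")
  expect_equal(r2$seq, strrep("T", 21))  # back to read orientation
})

test_that("bedGraph coverage round-trips", {
  tr <- coverage_track("chr1", "+", 10L, c(0, 0, 3, 3, 1, 0, 2), 1e6)
  f <- tempfile(fileext = ".bedGraph")
  write_bedgraph(tr, f)
  back <- read_bedgraph(f, "+", 1e6)
  # same depth at every position of the original window
  pos <- 10:16
  expect_equal(mirlocus:::track_depth(back, pos),
               mirlocus:::track_depth(tr, pos))
})

test_that("feature tables round-trip through GFF3", {
  sim <- default_sim()
  f <- tempfile(fileext = ".gff3")
  write_gff3(sim$features, f)
  back <- read_gff3(f)
  ord <- order(back$start)
  expect_equal(back[ord, c("ftype", "segment_id", "start", "end", "strand")],
               sim$features[order(sim$features$start),
                            c("ftype", "segment_id", "start", "end",
                              "strand")],
               ignore_attr = TRUE)
})

test_that("simulator output writers round-trip bit-exact", {
  sim <- default_sim()
  dir <- tempfile()
  dir.create(dir)
  write_alignments(sim$reads$ko_0h, file.path(dir, "r.tsv"))
  back <- read_alignments(file.path(dir, "r.tsv"), "tsv")
  x <- sim$reads$ko_0h
  rownames(x) <- NULL
  expect_equal(back, x, ignore_attr = TRUE)
  write_bedgraph(sim$coverage$wt[["+"]], file.path(dir, "c.bedGraph"))
  back <- read_bedgraph(file.path(dir, "c.bedGraph"), "+", 1e6)
  pos <- which(sim$coverage$wt[["+"]]$counts > 0) - 1L
  expect_equal(mirlocus:::track_depth(back, pos),
               mirlocus:::track_depth(sim$coverage$wt[["+"]], pos))
  unlink(dir, recursive = TRUE)
})
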