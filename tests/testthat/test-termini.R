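test_that("untemplated tails follow maximal templated extension", {
  genome <- "TTTTGCTAAATTTTTTTTCC"
  # read equals the genome substring: no tail
  tc <- detect_untemplated_tail("GCTAAA", genome, 4L)
  expect_equal(tc$tail_len_min, 0L)
  expect_equal(tc$tail_len_max, 0L)
  expect_false(tc$is_oligoA)
  expect_equal(tc$templated_end, 9L)
  # read = ...GCTAAA + AAAA: the three templated As before the cut make the
  # boundary ambiguous; the last templated A is reported as the end
  tc <- detect_untemplated_tail("GCTAAAAAAA", genome, 4L)
  expect_equal(tc$templated_end, 9L)
  expect_equal(tc$tail_seq, "AAAA")
  expect_equal(tc$tail_len_min, 4L)
  expect_equal(tc$tail_len_max, 7L)
  expect_true(tc$is_oligoA)
  # non-A suffixes are tails but not oligo(A)
  tc <- detect_untemplated_tail("GCTAAACCC", genome, 4L)
  expect_equal(tc$tail_seq, "CCC")
  expect_false(tc$is_oligoA)
  # a mismatch at the 5' anchor is an error
  expect_error(detect_untemplated_tail("CCTAAA", genome, 4L),
               "not anchored")
})

test_that("tail detection is exact without terminal-A ambiguity", {
  set.seed(17)
  g <- paste(sample(c("A", "C", "G", "T"), 4000, replace = TRUE,
                    prob = c(0.39, 0.11, 0.11, 0.39)), collapse = "")
  n_checked <- 0L
  for (r in 1:300) {
    start <- sample(100:3800, 1L)
    len <- sample(20:30, 1L)
    tl <- sample(0:8, 1L)
    end0 <- start + len - 1L
    templ <- substr(g, start + 1L, end0 + 1L)
    # unambiguous construction: last templated base not A, next base not A
    if (substr(templ, len, len) == "A") next
    if (tl > 0L && substr(g, end0 + 2L, end0 + 2L) == "A") next
    tc <- detect_untemplated_tail(paste0(templ, strrep("A", tl)), g, start)
    expect_equal(tc$tail_len_min, tl)
    expect_equal(tc$tail_len_max, tl)
    expect_equal(tc$templated_end, end0)
    n_checked <- n_checked + 1L
  }
  expect_gt(n_checked, 100L)
})

test_that("ambiguous tail ranges always bracket the true split", {
  set.seed(18)
  g <- paste(sample(c("A", "C", "G", "T"), 4000, replace = TRUE,
                    prob = c(0.45, 0.05, 0.05, 0.45)), collapse = "")
  for (r in 1:300) {
    start <- sample(100:3800, 1L)
    len <- sample(20:30, 1L)
    tl <- sample(0:8, 1L)
    templ <- substr(g, start + 1L, start + len)
    read <- paste0(templ, strrep("A", tl))
    tc <- detect_untemplated_tail(read, g, start)
    # a tail absorbed entirely by templated As is undetectable under the
    # maximal-templated-extension convention and reported as untailed
    if (tc$tail_len_min == 0L && tl > 0L) next
    expect_lte(tc$tail_len_min, tl)
    expect_gte(tc$tail_len_max, tl)
  }
})

test_that("planted tails are recovered from the simulated intermediates", {
  sim <- default_sim()
  l <- sim$truth$loci[1L, ]
  tc <- tail_calls(sim$tailed, sim$genome, anchor = l$anchor,
                   strand = l$strand)
  planted <- attr(sim$tailed, "truth")
  sites <- attr(sim$tailed, "site_rel")
  unamb <- tc$tail_len_min == tc$tail_len_max
  # unambiguous calls are exact; all calls bracket the truth
  expect_true(all(tc$tail_len_min[unamb] == planted[unamb]))
  expect_true(all(tc$tail_len_min <= planted & planted <= tc$tail_len_max))
  # recovered unambiguous tail lengths match the planted 4-6 nt range
  expect_true(all(tc$tail_len_min[unamb & tc$is_oligoA] %in% 4:6))
  # untailed reads sit exactly at their planted site
  expect_true(all(tc$templated_end_rel[planted == 0L] ==
                  sites[planted == 0L]))
  # the +248 site carries the 3-nt templated-A ambiguity
  amb248 <- !unamb & tc$is_oligoA
  expect_true(all(sites[amb248] == 248L))
  expect_true(all(tc$tail_len_max[amb248] - tc$tail_len_min[amb248] == 3L))
})

test_that("tail spectrum is a conservation-respecting 2-D census", {
  sim <- default_sim()
  l <- sim$truth$loci[1L, ]
  tc <- tail_calls(sim$tailed, sim$genome, anchor = l$anchor,
                   strand = l$strand)
  sp <- tail_spectrum(tc)
  expect_equal(sum(sp$count), sum(tc$is_oligoA))
  # two planted tail sites -> modes at +243 and +248
  expect_setequal(unique(sp$templated_end), c(243L, 248L))
  # empty input -> empty spectrum
  empty <- tail_spectrum(tc[tc$is_oligoA == FALSE & FALSE, ])
  expect_equal(nrow(empty), 0L)
})

test_that("TSS motif search finds planted T-runs with exact geometry", {
  sim <- default_sim()
  truth <- sim$truth$loci
  # model loci: 21-T and 26-T runs immediately upstream of the planted TSS
  for (i in 1:2) {
    l <- truth[i, ]
    hits <- find_tss_motif(sim$genome, anchor = l$tss, strand = l$strand)
    expect_gt(nrow(hits), 0L)
    expect_equal(hits$run_length[1L], l$t_run)
    expect_equal(hits$predicted_tss[1L], l$tss)
    expect_equal(to_relative(hits$predicted_tss[1L], l$anchor, l$strand),
                 l$tss_rel)
  }
})

test_that("motif hits satisfy their invariants on random AT-rich genomes", {
  set.seed(23)
  for (r in 1:20) {
    g <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE,
                      prob = c(0.35, 0.11, 0.11, 0.43)), collapse = "")
    for (strand in c("+", "-")) {
      anchor <- sample(300:1700, 1L)
      hits <- find_tss_motif(g, anchor, strand, window = 140L, min_run = 5L)
      if (!nrow(hits)) next
      for (k in seq_len(nrow(hits))) {
        tss <- hits$predicted_tss[k]
        base_at <- function(p) {
          b <- substr(g, p + 1L, p + 1L)
          if (strand == "+") b else chartr("ACGT", "TGCA", b)
        }
        expect_equal(base_at(tss), "G")
        up <- if (strand == "+") tss - 1L else tss + 1L
        expect_equal(base_at(up), "T")
        expect_gte(hits$run_length[k], 5L)
        expect_lte(hits$distance_to_anchor[k], 140L)
      }
      # ranking: run length descending, distance ascending on ties
      expect_true(all(diff(hits$run_length) <= 0))
    }
  }
})

test_that("no sufficient T-run means no motif hit", {
  g <- paste(rep("ACGT", 200), collapse = "")  # no T-run longer than 1
  expect_equal(nrow(find_tss_motif(g, 400L, "+", min_run = 8L)), 0L)
})

test_that("the PFM is the exact mean of one-hot windows", {
  sim <- default_sim()
  truth <- sim$truth$loci
  mir <- truth[truth$class == "mirna", ]
  hits <- data.frame(predicted_tss = mir$tss, strand = mir$strand)
  span <- 30L
  pfm <- build_pfm(hits, sim$genome, upstream_span = span)
  expect_equal(dim(pfm), c(4L, span + 1L))
  expect_true(all(abs(colSums(pfm) - 1) < 1e-9))
  expect_equal(pfm["G", "+1"], 1)
  # every planted T-run is at least 10 nt: positions -1..-10 are all T
  for (p in as.character(-1:-10)) expect_equal(pfm["T", p], 1)
  # independent recomputation as a mean of one-hot matrices
  g <- as.character(sim$genome)[[1]]
  wins <- vapply(seq_len(nrow(hits)), function(i) {
    if (hits$strand[i] == "+")
      substr(g, hits$predicted_tss[i] - span + 1L, hits$predicted_tss[i] + 1L)
    else
      revcomp(substr(g, hits$predicted_tss[i] + 1L,
                     hits$predicted_tss[i] + span + 1L))
  }, character(1))
  onehot <- function(w) {
    m <- matrix(0, 4L, span + 1L,
                dimnames = list(c("A", "C", "G", "T"), NULL))
    b <- strsplit(w, "", fixed = TRUE)[[1L]]
    for (j in seq_along(b)) m[b[j], j] <- 1
    m
  }
  expected <- Reduce(`+`, lapply(wins, onehot)) / length(wins)
  expect_equal(unname(pfm), unname(expected))
})

test_that("single-locus PFMs are one-hot and off-segment windows drop", {
  sim <- default_sim()
  l <- sim$truth$loci[1L, ]
  pfm <- build_pfm(data.frame(predicted_tss = l$tss, strand = l$strand),
                   sim$genome, upstream_span = 10L)
  expect_true(all(pfm %in% c(0, 1)))
  expect_warning(
    build_pfm(data.frame(predicted_tss = c(l$tss, 3L),
                         strand = c(l$strand, "+")),
              sim$genome, upstream_span = 10L),
    "off segment")
})
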