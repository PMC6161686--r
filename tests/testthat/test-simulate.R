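test_that("simulation is fully deterministic under (scenario, seed)", {
  sc <- sim_scenario(seed = 3, n_mirna_loci = 4L, n_decoy_hairpins = 2L,
                     sirna_reads = 500L, background_reads = 300L,
                     ncrna_reads = 100L, mrna_reads = 100L)
  a <- simulate_dataset(sc)
  b <- simulate_dataset(sc)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$truth$loci, b$truth$loci)
  expect_identical(a$reads, b$reads)
  expect_identical(a$tailed, b$tailed)
  expect_identical(a$coverage, b$coverage)
})

test_that("background composition matches the configured AT fraction", {
  sim <- default_sim()
  g <- strsplit(as.character(sim$genome)[[1]], "", fixed = TRUE)[[1L]]
  # outside planted features (hairpins are deliberately GC-rich)
  mask <- rep(TRUE, length(g))
  for (i in seq_len(nrow(sim$features)))
    mask[(sim$features$start[i] + 1L):sim$features$end[i]] <- FALSE
  at <- mean(g[mask] %in% c("A", "T"))
  expect_lt(abs(at - 0.78), 0.02)
})

test_that("planted hairpin arms are reverse complements", {
  sim <- default_sim()
  g <- as.character(sim$genome)[[1]]
  truth <- sim$truth$loci
  for (i in which(truth$class == "mirna" &
                  is.na(truth$violation))[c(1:5, 8)]) {
    l <- truth[i, ]
    ws <- mirlocus:::window_seq(g, l$window_start, l$window_end, l$strand)
    m5 <- substr(ws, l$m5_s + 1L, l$m5_e)
    m3 <- substr(ws, l$m3_s + 1L, l$m3_e)
    # duplex geometry: mir5p pairs revcomp(mir3p) at the overhang offset
    expect_equal(substr(m5, 1L, l$m - l$o),
                 substr(revcomp(m3), l$o + 1L, l$m), info = l$locus_id)
  }
})

test_that("zero miRNA loci still yields a genome with repeats", {
  sc <- sim_scenario(seed = 5, n_mirna_loci = 0L, n_decoy_hairpins = 0L)
  sim <- simulate_genome(sc)
  expect_equal(nrow(sim$truth$loci), 0L)
  expect_true(any(sim$features$ftype == "DIRS1"))
})

test_that("knockout depletes miRNA reads by the configured factor", {
  sim <- default_sim()
  truth <- sim$truth$loci
  mir <- truth[truth$class == "mirna", ]
  n_wt <- n_ko <- 0
  for (cond in c("0h", "16h")) {
    for (i in seq_len(nrow(mir))) {
      pat <- paste0("^", mir$locus_id[i], "_")
      n_wt <- n_wt + sum(grepl(pat, sim$reads[[paste0("wt_", cond)]]$read_id))
      n_ko <- n_ko + sum(grepl(pat, sim$reads[[paste0("ko_", cond)]]$read_id))
    }
  }
  # expectation n_wt / 50; allow generous sampling slack around it
  expect_gt(n_wt / max(n_ko, 1), 25)
  expect_lt(n_wt / max(n_ko, 1), 100)
})

test_that("full 5'-end homogeneity gives a single modal start", {
  sc <- sim_scenario(seed = 8, n_mirna_loci = 2L, n_decoy_hairpins = 0L,
                     homogeneity_5p = 1, sirna_reads = 200L,
                     background_reads = 100L, ncrna_reads = 0L,
                     mrna_reads = 0L)
  sim <- simulate_genome(sc)
  r <- simulate_small_reads(sim, "wt", "0h", sc)
  l <- sim$truth$loci[1L, ]
  p5 <- r[grepl(paste0("^", l$locus_id, "_5p"), r$read_id), ]
  expect_gt(nrow(p5), 0L)
  expect_true(all(p5$start - l$window_start == l$m5_s))
})

test_that("repeat siRNA loci are genotype-invariant up to sampling", {
  sim <- default_sim()
  n_wt <- sum(grepl("^dirs_", sim$reads$wt_0h$read_id))
  n_ko <- sum(grepl("^dirs_", sim$reads$ko_0h$read_id))
  # two-Poisson comparison: |difference| within 4 sd of the pooled rate
  expect_lt(abs(n_wt - n_ko), 4 * sqrt(n_wt + n_ko))
  # and both strands are produced
  d <- sim$reads$wt_0h[grepl("^dirs_", sim$reads$wt_0h$read_id), ]
  expect_gt(min(table(d$strand)) / nrow(d), 0.4)
})

test_that("knockout coverage is enriched by the configured factor", {
  sim <- default_sim()
  truth <- sim$truth$loci
  l <- truth[truth$locus_id == "mir05", ]  # minus-strand locus
  span <- sort(c(l$tss, l$pri_end))
  pos <- span[1L]:span[2L]
  wt <- mean(mirlocus:::track_depth(sim$coverage$wt[[l$strand]], pos))
  ko <- mean(mirlocus:::track_depth(sim$coverage$ko[[l$strand]], pos))
  expect_lt(abs(ko / wt - 8), 1.2)
  # positions outside any pri span or mRNA feature carry no coverage
  expect_equal(mirlocus:::track_depth(sim$coverage$wt[["+"]],
                                      c(0L, 1L, 2L)), c(0, 0, 0))
})

test_that("A-run gap positions have zero coverage in both genotypes", {
  sim <- default_sim()
  l <- sim$truth$loci[sim$truth$loci$readthrough, ][1L, ]
  gap <- l$gap_start:(l$gap_end - 1L)
  expect_true(all(mirlocus:::track_depth(sim$coverage$wt[[l$strand]],
                                         gap) == 0))
  expect_true(all(mirlocus:::track_depth(sim$coverage$ko[[l$strand]],
                                         gap) == 0))
  # and the gapped sequence is an A run on the locus strand
  g <- as.character(sim$genome)[[1]]
  expect_equal(substr(g, l$gap_start + 1L, l$gap_end),
               strrep("A", l$gap_end - l$gap_start))
})

test_that("background coverage over mRNA features is genotype-invariant", {
  sim <- default_sim()
  mrna <- sim$features[sim$features$ftype == "mRNA", ][1L, ]
  pos <- mrna$start:(mrna$end - 1L)
  wt <- mirlocus:::track_depth(sim$coverage$wt[[mrna$strand]], pos)
  ko <- mirlocus:::track_depth(sim$coverage$ko[[mrna$strand]], pos)
  expect_equal(wt, ko)
})

test_that("tailed reads are genome prefix plus an all-A suffix", {
  sim <- default_sim()
  g <- as.character(sim$genome)[[1]]
  tl <- attr(sim$tailed, "truth")
  expect_true(all(tl[tl > 0] >= 4L & tl[tl > 0] <= 6L))
  for (i in seq_len(nrow(sim$tailed))) {
    r <- sim$tailed[i, ]
    templ <- substr(g, r$start + 1L, r$end)
    if (r$strand == "-") templ <- revcomp(templ)
    expect_equal(r$seq, paste0(templ, strrep("A", tl[i])))
  }
})

test_that("tail_fraction zero produces no tails", {
  sc <- sim_scenario(seed = 2, tail_fraction = 0)
  sim <- simulate_genome(sc)
  tails <- simulate_tailed_reads(sim, sc)
  expect_true(all(attr(tails, "truth") == 0L))
  expect_true(all(nchar(tails$seq) == tails$end - tails$start))
})
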