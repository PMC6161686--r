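test_that("build_stack totals match a brute-force recount", {
  sim <- default_sim()
  truth <- sim$truth$loci
  for (id in c("mir08", "mir05")) {  # one plus, one minus strand locus
    l <- truth[truth$locus_id == id, ]
    st <- build_stack(sim$reads$wt_0h, l)
    r <- sim$reads$wt_0h
    w <- r$end - r$start
    ov <- pmin(r$end, l$window_end) - pmax(r$start, l$window_start)
    n <- sum(r$strand == l$strand & ov >= 0.75 * w)
    expect_equal(st$total, n, info = id)
    expect_equal(sum(st$table$count), st$total)
  }
  # no overlapping reads -> empty stack
  empty <- build_stack(sim$reads$wt_0h,
                       list(window_start = -250L, window_end = -200L,
                            strand = "+", locus_id = "nothing"))
  expect_equal(empty$total, 0L)
})

test_that("reads map into locus-forward coordinates on both strands", {
  sim <- default_sim()
  truth <- sim$truth$loci
  l <- truth[truth$locus_id == "mir06", ]  # minus strand
  expect_equal(l$strand, "-")
  st <- build_stack(pool_reads(sim$reads$wt_0h, sim$reads$wt_16h), l)
  # the modal 5' starts sit at the planted arm offsets
  top <- st$table[order(-st$table$count), ]
  expect_true(l$m5_s %in% top$start[1:4])
  expect_true(l$m3_s %in% top$start[1:4])
})

test_that("arm calling computes modal reads and homogeneity", {
  st <- make_test_structure(arm = 30L, loop = 10L)  # loop at 30..39
  tab <- data.frame(start = c(5L, 5L, 6L, 45L, 47L),
                    length = c(21L, 22L, 21L, 21L, 21L),
                    count = c(5L, 1L, 4L, 6L, 4L))
  arms <- call_arms(make_test_stack(tab), st)
  expect_equal(arms$p5$total, 10L)
  expect_equal(arms$p3$total, 10L)
  # 5p: start 5 carries 6 of 10 reads; modal read is (5, 21) with count 5
  expect_equal(arms$p5$homogeneity, 0.6)
  expect_equal(arms$p5$modal_start, 5L)
  expect_equal(arms$p5$modal_length, 21L)
  # 3p: (45,21) has count 6 -> homogeneity 0.6
  expect_equal(arms$p3$homogeneity, 0.6)
  expect_equal(arms$p3$modal_start, 45L)
})

test_that("modal ties break toward smaller start, then longer read", {
  st <- make_test_structure(arm = 30L, loop = 10L)
  tab <- data.frame(start = c(5L, 7L, 45L, 45L),
                    length = c(21L, 21L, 20L, 22L),
                    count = c(2L, 2L, 2L, 2L))
  arms <- call_arms(make_test_stack(tab), st)
  expect_equal(arms$p5$modal_start, 5L)
  expect_equal(arms$p3$modal_length, 22L)
})

test_that("criterion boundaries follow the published thresholds", {
  arm <- function(total = 0L, h = NA_real_)
    list(total = total, homogeneity = h, modal_start = 10L,
         modal_length = 21L, modal_count = total)
  # read support: at least 10 reads on both arms, 9 fails
  expect_true(criterion_read_support(list(p5 = arm(10L), p3 = arm(10L)))$pass)
  expect_false(criterion_read_support(list(p5 = arm(9L), p3 = arm(200L)))$pass)
  expect_false(criterion_read_support(list(p5 = arm(0L), p3 = arm(0L)))$pass)
  # homogeneity: at least half the arm reads share the modal 5' end
  expect_true(criterion_homogeneity(list(p5 = arm(20L, 0.5),
                                         p3 = arm(20L, 0.5)))$pass)
  expect_false(criterion_homogeneity(list(p5 = arm(20L, 0.49),
                                          p3 = arm(20L, 0.9)))$pass)
  # overhangs: strict accepts only (2,2); relaxed accepts 0..4
  expect_true(criterion_overhang(c(2L, 2L), "strict2")$pass)
  expect_false(criterion_overhang(c(0L, 4L), "strict2")$pass)
  expect_true(criterion_overhang(c(0L, 4L), "relaxed0to4")$pass)
  expect_false(criterion_overhang(c(5L, 2L), "relaxed0to4")$pass)
  expect_false(criterion_overhang(c(NA_integer_, 2L), "strict2")$pass)
})

test_that("knockout dependence uses pseudocounted cpm fold changes", {
  st <- make_test_structure(arm = 30L, loop = 10L)
  mk <- function(n5, n3, lib) make_test_stack(
    data.frame(start = c(5L, 45L), length = 21L, count = c(n5, n3)),
    library_size = lib)
  # wt 500 cpm, ko 10 cpm, pseudocount 1 -> log2(11/501) ~ -5.51
  r <- ko_dependence(mk(500L, 500L, 1e6), mk(10L, 10L, 1e6), st)
  expect_equal(unname(r$log2fc), rep(log2(11 / 501), 2), tolerance = 1e-12)
  expect_true(r$pass)
  # identical stacks -> 0 -> fail
  r <- ko_dependence(mk(100L, 100L, 1e6), mk(100L, 100L, 1e6), st)
  expect_equal(unname(r$log2fc), c(0, 0))
  expect_false(r$pass)
  # library sizes matter: same counts, smaller ko library -> enrichment
  r <- ko_dependence(mk(100L, 100L, 1e6), mk(100L, 100L, 1e5), st)
  expect_gt(r$log2fc[[1]], 0)
})

test_that("developmental flag responds to fold change and pseudocount", {
  st <- make_test_structure(arm = 30L, loop = 10L)
  mk <- function(n, lib = 1e6) make_test_stack(
    data.frame(start = c(5L, 45L), length = 21L, count = c(n, n)),
    library_size = lib)
  expect_false(developmental_regulation(mk(100L), mk(100L), st)$flag)
  r <- developmental_regulation(mk(100L), mk(800L), st)
  expect_true(r$flag)
  expect_equal(unname(r$log2fc[[r$dominant_arm]]), log2(801 / 101))
  # increasing the pseudocount shrinks |log2fc|
  r10 <- developmental_regulation(mk(100L), mk(800L), st, pseudocount = 10)
  expect_lt(abs(r10$log2fc[[1]]), abs(r$log2fc[[1]]))
})

test_that("planted homogeneity is recovered from simulated stacks", {
  sim <- default_sim()
  truth <- sim$truth$loci
  g <- as.character(sim$genome)[[1]]
  ids <- truth$locus_id[truth$class == "mirna" & !truth$mor][3:8]
  hs <- vapply(ids, function(id) {
    l <- truth[truth$locus_id == id, ]
    st <- fold(mirlocus:::window_seq(g, l$window_start, l$window_end,
                                     l$strand))
    arms <- call_arms(build_stack(pool_reads(sim$reads$wt_0h,
                                             sim$reads$wt_16h), l), st)
    (arms$p5$homogeneity + arms$p3$homogeneity) / 2
  }, numeric(1))
  # scenario homogeneity 0.9; jittered tails pull the average down slightly
  expect_lt(abs(mean(hs) - 0.9), 0.07)
})

test_that("locus verdicts are invariant under read order permutation", {
  sim <- default_sim()
  truth <- sim$truth$loci
  l <- truth[truth$locus_id == "mir09", ]
  g <- as.character(sim$genome)[[1]]
  st <- fold(mirlocus:::window_seq(g, l$window_start, l$window_end,
                                   l$strand), l$locus_id)
  wt <- pool_reads(sim$reads$wt_0h, sim$reads$wt_16h)
  ko <- pool_reads(sim$reads$ko_0h, sim$reads$ko_16h)
  set.seed(77)
  wt_perm <- wt[sample.int(nrow(wt)), ]
  attr(wt_perm, "library_size") <- attr(wt, "library_size")
  a <- classify_locus(l, st, build_stack(wt, l), build_stack(ko, l))
  b <- classify_locus(l, st, build_stack(wt_perm, l), build_stack(ko, l))
  expect_identical(a$tier, b$tier)
  expect_identical(a$criteria, b$criteria)
})

test_that("raising thresholds never increases high-confidence calls", {
  sim <- default_sim()
  base <- default_calls()
  n_base <- sum(base$summary$tier == "high_confidence")
  stricter <- list(call_thresholds(min_reads = 30L),
                   call_thresholds(min_homogeneity = 0.8),
                   call_thresholds(max_ko_log2fc = -8),
                   call_thresholds(min_pairing = 0.995))
  for (th in stricter) {
    n <- sum(call_all_loci(sim$genome, sim$truth$loci, sim$reads,
                           th)$summary$tier == "high_confidence")
    expect_lte(n, n_base)
  }
})

test_that("moR masking finds adjacent secondary pairs and labels them", {
  sim <- default_sim()
  calls <- default_calls()
  truth <- sim$truth$loci
  for (i in which(truth$mor)) {
    cl <- calls$calls[[i]]
    expect_equal(length(cl$pairs), 2L)
    labels <- vapply(cl$pairs, `[[`, character(1), "label")
    expect_setequal(labels, c("-1", "-2"))
    # base-proximal pair starts 5' of the loop-proximal pair
    s <- vapply(cl$pairs, function(p) p$arms$p5$modal_start, integer(1))
    expect_lt(s[labels == "-1"], s[labels == "-2"])
    # planted: primary (more abundant) pair is the base-proximal one
    expect_equal(cl$pairs[[1L]]$label, "-1")
  }
  # single-duplex loci never yield a second pair
  for (i in which(truth$class == "mirna" & !truth$mor))
    expect_equal(length(calls$calls[[i]]$pairs), 1L)
})

test_that("secondary pairs below the read threshold are rejected", {
  sim <- default_sim()
  truth <- sim$truth$loci
  i <- which(truth$mor)[1L]
  l <- truth[i, ]
  g <- as.character(sim$genome)[[1]]
  st <- fold(mirlocus:::window_seq(g, l$window_start, l$window_end,
                                   l$strand), l$locus_id)
  stack <- build_stack(pool_reads(sim$reads$wt_0h, sim$reads$wt_16h), l)
  # rebuild the secondary arms with exactly 9 reads each (and no residual
  # jitter strays): below the 10-read threshold the pair must be rejected
  thin <- stack
  tab <- thin$table
  near <- function(a) abs(tab$start - a) <= 4L
  sec <- near(l$m5b_s) | near(l$m3b_s)
  stray <- abs(tab$start - l$m5_s) == 3L | abs(tab$start - l$m3_s) == 3L
  tab <- tab[!sec & !stray, ]
  tab <- rbind(tab, data.frame(start = c(l$m5b_s, l$m3b_s),
                               length = l$m, count = 9L))
  thin$table <- tab[order(tab$start, tab$length), ]
  thin$total <- sum(thin$table$count)
  pairs <- detect_mor_pairs(thin, st, call_arms(thin, st))
  expect_equal(length(pairs), 1L)
})

test_that("candidate tier covers occluded read support, reject otherwise", {
  sim <- default_sim()
  truth <- sim$truth$loci
  l <- truth[truth$locus_id == "mir10", ]
  g <- as.character(sim$genome)[[1]]
  st <- fold(mirlocus:::window_seq(g, l$window_start, l$window_end,
                                   l$strand), l$locus_id)
  wt <- build_stack(pool_reads(sim$reads$wt_0h, sim$reads$wt_16h), l)
  ko <- build_stack(pool_reads(sim$reads$ko_0h, sim$reads$ko_16h), l)
  full <- classify_locus(l, st, wt, ko)
  expect_equal(full$tier, "high_confidence")
  # thin the 3p arm to 9 reads in both genotypes: an occluded true locus
  # that still shows knockout dependence drops to candidate (the published
  # mir-1178 situation)
  thin_arm <- function(stack, n_keep) {
    is3 <- stack$table$start >= l$m3_s - 3L
    tab3 <- stack$table[is3, , drop = FALSE]
    tab3 <- tab3[order(-tab3$count), , drop = FALSE]
    total <- 0L
    for (k in seq_len(nrow(tab3))) {
      take <- min(tab3$count[k], n_keep - total)
      tab3$count[k] <- take
      total <- total + take
    }
    stack$table <- rbind(stack$table[!is3, , drop = FALSE],
                         tab3[tab3$count > 0L, , drop = FALSE])
    stack$total <- sum(stack$table$count)
    stack
  }
  cand <- classify_locus(l, st, thin_arm(wt, 9L), thin_arm(ko, 0L))
  expect_equal(cand$tier, "candidate")
  expect_false(cand$criteria$i_read_support$pass)
})
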