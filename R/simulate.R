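# Seeded generator of an AT-rich genome with planted miRNA loci, decoy
# hairpins, repeat-derived siRNA loci, small RNA read stacks, long RNA
# coverage, and oligo(A)-tailed processing intermediates, together with the
# ground truth needed for recovery tests.

#' Simulation scenario
#'
#' Returns the default scenario emulating the study conditions: a ~78% AT
#' genome, small RNA libraries of 18-40 nt reads peaking at 21 nt dominated
#' by repeat-derived siRNAs, miRNA hairpins with 2-nt 3' overhang duplex
#' geometry, ~50-fold miRNA depletion plus ~8-fold pri-transcript enrichment
#' in the Dicer-knockout, developmental upregulation at 16 h, oligo(A) tails
#' of 4-6 nt on 3' processing intermediates, and T-run promoter motifs of
#' 10-26 nt (21 and 26 nt at the two model loci) upstream of planted TSSs.
#'
#' @param seed integer seed governing every random draw.
#' @param ... overrides for any scenario field.
#' @return a list of class `sim_scenario`.
#' @export
sim_scenario <- function(seed = 1, ...) {
  sc <- list(
    seed = as.integer(seed),
    genome_length = 50000L,
    at_fraction = 0.78,
    n_mirna_loci = 20L,
    n_decoy_hairpins = 10L,
    n_sirna_repeat_loci = 5L,
    arm_length = 20:22,
    arm_length_prob = c(0.2, 0.6, 0.2),
    loop_length = c(8L, 20L),
    overhang = 2L,
    basal_stem = c(4L, 8L),
    stem_gc = 0.9,
    homogeneity_5p = 0.9,
    reads_per_locus = 20L,       # wt 0h expectation per miRNA locus
    nb_dispersion = 0.1,
    ko_mirna_depletion = 50,
    ko_pri_enrichment = 8,
    dev_fold_16h_vs_0h = 3,
    mor_secondary_frac = 0.8,
    tail_fraction = 0.5,
    tail_length = c(4L, 6L),
    n_tail_reads = 80L,
    t_run_range = c(10L, 26L),
    tss_offset_range = c(60L, 140L),
    pri_end_range = c(150L, 300L),
    a_run_gap = TRUE,
    a_gap_len = 30L,
    # bulk small RNA library composition, per condition
    sirna_reads = 30000L,
    complex_repeat_reads = 310L,
    ko_complex_fold = 3,
    background_reads = 14000L,
    ncrna_reads = 1500L,
    mrna_reads = 800L,
    # long RNA coverage
    coverage_depth_wt = 5,
    coverage_noise = TRUE,
    longrna_library_size = 1e6,
    mirna_minus_strand = c(5L, 6L, 7L)  # loci planted on the minus strand
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(sc))
  if (length(unknown)) stop("unknown scenario field: ",
                            paste(unknown, collapse = ", "))
  sc[names(dots)] <- dots
  stopifnot(sc$at_fraction >= 0, sc$at_fraction <= 1,
            sc$ko_mirna_depletion > 0, sc$ko_pri_enrichment > 0,
            sc$tail_fraction >= 0, sc$tail_fraction <= 1)
  class(sc) <- "sim_scenario"
  sc
}

# deterministic sub-seeds per operation/condition, kept below 2^31
sim_seed <- function(scenario, stage) {
  codes <- c(genome = 11L, wt_0h = 21L, wt_16h = 22L, ko_0h = 23L,
             ko_16h = 24L, tails = 31L, cov_wt = 41L, cov_ko = 42L,
             cov_wt_0h = 43L, cov_wt_16h = 44L, cov_ko_0h = 45L,
             cov_ko_16h = 46L, cov_wt_pooled = 47L, cov_ko_pooled = 48L)
    code <- codes[[stage]]
  (scenario$seed * 1009L + code * 101L) %% 2147483647L
}

sample_bases <- function(n, at_fraction) {
  sample(c("A", "T", "C", "G"), n, replace = TRUE,
         prob = c(at_fraction / 2, at_fraction / 2,
                  (1 - at_fraction) / 2, (1 - at_fraction) / 2))
}

rcount <- function(n, mu, dispersion) {
  if (dispersion <= 0) return(stats::rpois(n, mu))
  stats::rnbinom(n, mu = mu, size = 1 / dispersion)
}

# Build one hairpin construct in locus-forward orientation.
# Returns the hairpin string plus hairpin-local duplex geometry.
make_hairpin <- function(m, loop_len, b, o, gc, mor = FALSE,
                         disrupt_pairing = FALSE) {
  n_arms <- if (mor) 2L else 1L
  S <- b + o + n_arms * m
  stem <- sample(c("G", "C", "A", "T"), S, replace = TRUE,
                 prob = c(gc / 2, gc / 2, (1 - gc) / 2, (1 - gc) / 2))
  u <- b + o
  if (disrupt_pairing) # 9-pair symmetric A/A internal loop in the duplex:
    stem[(u + 7L):(u + 15L)] <- "A"  # A pairs nothing in an all-GC stem
  hp <- c(stem, rep("A", loop_len), rev(chartr("ACGT", "TGCA", stem)))
  len <- length(hp)
  if (disrupt_pairing)
    hp[len - ((u + 6L):(u + 14L))] <- "A"
  geom <- list(m5 = c(u, u + m), m3 = c(len - u + o - m, len - u + o))
  if (mor) {
    geom <- list(m5 = c(u, u + m), m3 = c(len - u + o - m, len - u + o),
                 m5b = c(u + m, u + 2L * m),
                 m3b = c(len - u + o - 2L * m, len - u + o - m))
  }
  c(list(seq = paste(hp, collapse = ""), len = len, u = u, m = m,
         o = o, b = b), geom)
}

DECOY_VIOLATIONS <- c("read_support", "homogeneity", "overhang",
                      "energy", "pairing")

# Does the folded window reproduce the planted duplex geometry (and, for
# decoys, exactly the planted violation)? Used to rejection-sample stems:
# random GC-rich stems occasionally admit co-optimal folds (palindromic
# runs) that would scramble the planted geometry.
validate_hairpin <- function(cons, hp_start_c, hp, flank, violation) {
  wseq <- paste(cons[(hp_start_c - flank):(hp_start_c + hp$len - 1L + flank)],
                collapse = "")
  st <- fold(wseq)
  duplex <- list(mir5p = hp$m5 + flank, mir3p = hp$m3 + flank)
  ov <- overhangs(st, duplex)
  pf <- pairing_fraction(st, duplex)
  epn <- mfe_per_nt(st)
  ov_ok <- !any(is.na(ov)) && all(ov == hp$o)
  lp <- tryCatch(hairpin_loop(st), error = function(e) NULL)
  i5e <- if (!is.null(hp$m5b)) hp$m5b[2L] else hp$m5[2L]
  i3s <- if (!is.null(hp$m3b)) hp$m3b[1L] else hp$m3[1L]
  ov_ok <- ov_ok && !is.null(lp) &&
    lp[1L] >= i5e + flank - 2L && lp[2L] <= i3s + flank + 2L
  v <- if (is.na(violation)) "" else violation
  if (v == "energy")  return(ov_ok && pf >= 0.6 && epn >= -0.5)
  if (v == "pairing") return(ov_ok && pf < 0.6 && epn < -0.5)
  ok <- ov_ok && pf >= 0.6 && epn < -0.5
  if (!is.null(hp$m5b)) {
    d2 <- list(mir5p = hp$m5b + flank, mir3p = hp$m3b + flank)
    ov2 <- overhangs(st, d2)
    ok <- ok && !any(is.na(ov2)) && all(ov2 == hp$o) &&
      pairing_fraction(st, d2) >= 0.6
  }
  ok
}

#' Simulate a genome with planted loci
#'
#' Plants high-confidence miRNA loci (hairpins with reverse-complement arms,
#' a T-run + G TSS upstream, and a defined pri-transcript 3' end), decoy
#' hairpins each violating exactly one calling criterion, dispersed
#' DIRS1-like and TRE3-like repeat families, assorted structural ncRNA and
#' mRNA features, and an AT-rich background. Locus 1 is a mir-1176-like
#' model locus (TSS at relative -281 behind a 21-T run, pri 3' end at +388,
#' two 3'-intermediate sites at +243 and +248 with three templated As before
#' +248); locus 2 is a mir-1177-like readthrough locus (TSS at -116 behind a
#' 26-T run, an A-run coverage gap, and a downstream gene).
#'
#' @param scenario a [sim_scenario()].
#' @return list with `genome` (DNAStringSet), `features` (data.frame) and
#'   `truth` (list: `loci` data.frame plus `scenario`).
#' @export
simulate_genome <- function(scenario) {
  set.seed(sim_seed(scenario, "genome"))
  L <- scenario$genome_length
  g <- sample_bases(L, scenario$at_fraction)
  flank <- 20L

  feats <- list()
  loci <- list()
  cursor <- 1L  # 1-based index into g

  place <- function(block_len) {
    gap <- sample(80:200, 1L)
    start <- cursor + gap
    if (start + block_len > L - 100L)
      stop("loci cannot be placed without overlap: genome too short")
    cursor <<- start + block_len
    start - 1L  # 0-based offset of the block
  }

  add_feat <- function(id, ftype, start, end, strand) {
    feats[[length(feats) + 1L]] <<-
      data.frame(id = id, ftype = ftype, segment_id = "chr1",
                 start = start, end = end, strand = strand,
                 stringsAsFactors = FALSE)
  }

  n_mir <- scenario$n_mirna_loci
  n_dec <- scenario$n_decoy_hairpins
  violations <- rep(DECOY_VIOLATIONS, length.out = n_dec)

  for (i in seq_len(n_mir + n_dec)) {
    is_decoy <- i > n_mir
    violation <- if (is_decoy) violations[i - n_mir] else NA_character_
    id <- if (is_decoy) sprintf("decoy%02d", i - n_mir)
          else sprintf("mir%02d", i)
    mor <- !is_decoy && i %in% c(3L, 4L)
    m <- sample(scenario$arm_length, 1L, prob = scenario$arm_length_prob)
    loop_len <- sample(scenario$loop_length[1]:scenario$loop_length[2], 1L)
    b <- sample(scenario$basal_stem[1]:scenario$basal_stem[2], 1L)
    o <- scenario$overhang
    gc <- scenario$stem_gc
    disrupt <- FALSE
    if (!is.na(violation)) {
      if (violation == "overhang") o <- 5L
      if (violation == "energy")  gc <- 0.1
      if (violation == "pairing") { b <- 20L; gc <- 1.0; disrupt <- TRUE }
    }
    hp <- make_hairpin(m, loop_len, b, o, gc, mor = mor,
                       disrupt_pairing = disrupt)

    strand <- if (!is_decoy && i %in% scenario$mirna_minus_strand) "-" else "+"
    # model loci 1 and 2 carry the worked-example geometry
    tss_offset <- if (i == 1L) 281L else if (i == 2L) 116L else
      sample(scenario$tss_offset_range[1]:scenario$tss_offset_range[2], 1L)
    t_run <- if (i == 1L) 21L else if (i == 2L) 26L else
      sample(scenario$t_run_range[1]:scenario$t_run_range[2], 1L)
    pri_end_rel <- if (i == 1L) 388L else if (i == 2L) 460L else
      sample(scenario$pri_end_range[1]:scenario$pri_end_range[2], 1L)
    readthrough <- !is_decoy && i == 2L && scenario$a_run_gap

    # locus-forward construct: [pad | T-run | G(tss) ... hairpin ... 3' region]
    anchor_l <- tss_offset  # local position of mir-5p first nt wrt tss at 0
    hp_l <- anchor_l - hp$u  # hairpin local start
    if (hp_l < flank + 2L) stop("tss offset too small for hairpin placement")
    pad <- t_run + 6L
    Lc <- pad + 1L + max(anchor_l + pri_end_rel + 60L, hp_l + hp$len + flank)
    cons <- sample_bases(Lc, scenario$at_fraction)
    tss_l <- pad  # local 0-based position of the TSS G
    cons[(tss_l - t_run + 1L):tss_l] <- "T"
    cons[tss_l - t_run] <- "A"           # bound the run exactly
    cons[tss_l + 1L] <- "G"
    # shift: local coords below are relative to the TSS position tss_l+? --
    # define loc(x) = construct index of "distance x downstream of tss"
    loc <- function(x) tss_l + 1L + x  # 1-based construct index, x >= 0
    anchor_c <- loc(anchor_l)           # construct 1-based index of mir5p nt1
    hp_start_c <- anchor_c - hp$u
    # keep guard bases next to the hairpin unpairable with stem ends
    cons[(hp_start_c - 3L):(hp_start_c - 1L)] <- "A"
    cons[(hp_start_c + hp$len):(hp_start_c + hp$len + 2L)] <- "A"
    for (try in 1:40) {
      cons[hp_start_c:(hp_start_c + hp$len - 1L)] <-
        strsplit(hp$seq, "", fixed = TRUE)[[1L]]
      if (validate_hairpin(cons, hp_start_c, hp, flank, violation)) break
      if (try == 40L) stop("could not realize planted hairpin geometry: ", id)
      hp <- make_hairpin(m, loop_len, b, o, gc, mor = mor,
                         disrupt_pairing = disrupt)
    }

    tail_site1 <- tail_site2 <- NA_integer_
    gap_s <- gap_e <- dsg_s <- dsg_e <- wt_end_rel <- NA_integer_
    rloc <- function(v) anchor_c + v - 1L  # construct index of rel +v
    if (i == 1L) {
      # 3' intermediate sites at +243 (unambiguous) and +248 (three
      # templated As immediately before the cut, +249 bounded)
      s1 <- rloc(243L); s2 <- rloc(248L)
      cons[s1] <- "C"; cons[s1 + 1L] <- "T"
      cons[s2 - 3L] <- "C"; cons[(s2 - 2L):s2] <- "A"; cons[s2 + 1L] <- "G"
      tail_site1 <- 243L; tail_site2 <- 248L
    }
    if (readthrough) {
      wt_end_rel <- 197L
      gap_rel <- c(220L, 250L)
      cons[rloc(gap_rel[1]):rloc(gap_rel[2])] <- "A"
      cons[rloc(gap_rel[2] + 1L)] <- "G"  # bound the A run
      dsg_rel <- c(280L, 440L)
      gap_s <- gap_rel[1]; gap_e <- gap_rel[2] + 1L
      dsg_s <- dsg_rel[1]; dsg_e <- dsg_rel[2] + 1L
    }

    # insert into the genome (reverse-complemented for minus-strand loci)
    g0 <- place(Lc)
    if (strand == "+") {
      g[(g0 + 1L):(g0 + Lc)] <- cons
      gen <- function(x_local) g0 + x_local            # 0-based genomic
    } else {
      g[(g0 + 1L):(g0 + Lc)] <- rev(chartr("ACGT", "TGCA", cons))
      gen <- function(x_local) g0 + Lc - 1L - x_local
    }
    # genomic 0-based coordinates (position of that base)
    tss_g <- gen(tss_l)               # the G residue
    anchor_g <- gen(anchor_c - 1L)    # mir5p first nt
    hp_g <- sort(c(gen(hp_start_c - 1L), gen(hp_start_c + hp$len - 2L)))
    win_g <- c(hp_g[1L] - flank, hp_g[2L] + 1L + flank)
    pri_end_g <- gen(anchor_c - 1L + pri_end_rel - 1L)  # last covered nt
    add_feat(id, "hairpin_candidate", hp_g[1L], hp_g[2L] + 1L, strand)
    if (readthrough) {
      dg <- sort(c(gen(anchor_c - 1L + dsg_s - 1L),
                   gen(anchor_c - 1L + dsg_e - 2L)))
      add_feat(paste0(id, "_dsg"), "gene_downstream", dg[1L], dg[2L] + 1L,
               strand)
      dsg_s <- dg[1L]; dsg_e <- dg[2L] + 1L
      gp <- sort(c(gen(anchor_c - 1L + gap_s - 1L),
                   gen(anchor_c - 1L + gap_e - 2L)))
      gap_s <- gp[1L]; gap_e <- gp[2L] + 1L
    }

    loci[[length(loci) + 1L]] <- data.frame(
      locus_id = id,
      class = if (is_decoy) "decoy" else "mirna",
      violation = violation, strand = strand,
      window_start = win_g[1L], window_end = win_g[2L],
      hp_start = hp_g[1L], hp_end = hp_g[2L] + 1L,
      hp_len = hp$len, u = hp$u, m = hp$m, o = hp$o, mor = mor,
      # duplex geometry in window-local (locus-forward) 0-based coords
      m5_s = hp$m5[1L] + flank, m5_e = hp$m5[2L] + flank,
      m3_s = hp$m3[1L] + flank, m3_e = hp$m3[2L] + flank,
      m5b_s = if (mor) hp$m5b[1L] + flank else NA_integer_,
      m5b_e = if (mor) hp$m5b[2L] + flank else NA_integer_,
      m3b_s = if (mor) hp$m3b[1L] + flank else NA_integer_,
      m3b_e = if (mor) hp$m3b[2L] + flank else NA_integer_,
      anchor = anchor_g, tss = tss_g, t_run = t_run,
      tss_rel = -tss_offset, pri_end_rel = pri_end_rel,
      pri_end = pri_end_g,
      wt_end_rel = wt_end_rel, readthrough = readthrough,
      gap_start = gap_s, gap_end = gap_e,
      dsg_start = dsg_s, dsg_end = dsg_e,
      tail_site1 = tail_site1, tail_site2 = tail_site2,
      # homogeneity decoys keep the planted modal dominant (0.35 vs 0.5
      # criterion) so only the 5'-end precision criterion is violated;
      # decoys are not developmentally regulated, so they get double the
      # per-condition baseline to match the pooled depth of true loci
      homogeneity = if (!is.na(violation) && violation == "homogeneity")
        0.35 else scenario$homogeneity_5p,
      reads_per_cond = if (is_decoy) {
        if (violation == "read_support") 4L else 2L * scenario$reads_per_locus
      } else scenario$reads_per_locus,
      dev_fold = if (is_decoy) 1 else scenario$dev_fold_16h_vs_0h,
      ko_depleted = !is_decoy,
      stringsAsFactors = FALSE)
  }

  # dispersed repeat families
  dirs_family <- sample_bases(1400L, scenario$at_fraction)
  for (r in seq_len(scenario$n_sirna_repeat_loci)) {
    copy <- dirs_family
    mut <- sample(length(copy), round(0.02 * length(copy)))
    copy[mut] <- sample_bases(length(mut), scenario$at_fraction)
    g0 <- place(length(copy))
    g[(g0 + 1L):(g0 + length(copy))] <- copy
    add_feat(sprintf("DIRS1_%d", r), "DIRS1", g0, g0 + length(copy),
             sample(c("+", "-"), 1L))
  }
  tre_family <- sample_bases(800L, scenario$at_fraction)
  for (r in 1:2) {
    g0 <- place(length(tre_family))
    g[(g0 + 1L):(g0 + length(tre_family))] <- tre_family
    add_feat(sprintf("TRE3_%d", r), "complex_repeat", g0,
             g0 + length(tre_family), sample(c("+", "-"), 1L))
  }

  # structural ncRNAs and mRNAs
  nc_plan <- list(tRNA = c(3L, 75L), rRNA = c(2L, 120L), snoRNA = c(2L, 90L),
                  snRNA = c(2L, 110L), SRP = c(1L, 300L), classI = c(2L, 110L))
  for (ft in names(nc_plan)) {
    for (k in seq_len(nc_plan[[ft]][1L])) {
      w <- nc_plan[[ft]][2L]
      g0 <- place(w)
      add_feat(sprintf("%s_%d", ft, k), ft, g0, g0 + w, sample(c("+", "-"), 1L))
    }
  }
  for (k in 1:3) {
    w <- 1000L
    g0 <- place(w)
    add_feat(sprintf("mRNA_%d", k), "mRNA", g0, g0 + w, sample(c("+", "-"), 1L))
  }

  features <- do.call(rbind, feats)
  loci_df <- do.call(rbind, loci)
  if (is.null(loci_df))
    loci_df <- data.frame(
      locus_id = character(), class = character(), violation = character(),
      strand = character(), window_start = integer(),
      window_end = integer(), hp_start = integer(), hp_end = integer(),
      hp_len = integer(), u = integer(), m = integer(), o = integer(),
      mor = logical(), m5_s = integer(), m5_e = integer(),
      m3_s = integer(), m3_e = integer(), m5b_s = integer(),
      m5b_e = integer(), m3b_s = integer(), m3b_e = integer(),
      anchor = integer(), tss = integer(), t_run = integer(),
      tss_rel = integer(), pri_end_rel = integer(), pri_end = integer(),
      wt_end_rel = integer(), readthrough = logical(),
      gap_start = integer(), gap_end = integer(), dsg_start = integer(),
      dsg_end = integer(), tail_site1 = integer(), tail_site2 = integer(),
      homogeneity = numeric(), reads_per_cond = integer(),
      dev_fold = numeric(), ko_depleted = logical())
  truth <- list(loci = loci_df, scenario = scenario)
  genome_str <- paste(g, collapse = "")
  genome <- Biostrings::DNAStringSet(stats::setNames(genome_str, "chr1"))
  list(genome = genome, features = features, truth = truth)
}

# locus-local [s, s+len) (window-forward coords) -> genomic interval + strand
loc_read_to_genomic <- function(s, len, win_start, win_end, strand) {
  if (strand == "+") cbind(start = win_start + s, end = win_start + s + len)
  else cbind(start = win_end - (s + len), end = win_end - s)
}

# window sequence in locus-forward orientation
window_seq <- function(genome_str, win_start, win_end, strand) {
  s <- substr(genome_str, win_start + 1L, win_end)
  if (strand == "-") revcomp(s) else s
}

mirna_read_lengths <- function(n, m) {
  m + sample(c(-1L, 0L, 1L), n, replace = TRUE, prob = c(0.2, 0.6, 0.2))
}

bulk_read_lengths <- function(n, p21 = 0.7) {
  is21 <- stats::runif(n) < p21
  out <- rep(21L, n)
  out[!is21] <- sample(c(18:20, 22:26), sum(!is21), replace = TRUE)
  out
}

jitter_starts <- function(n, modal, homogeneity) {
  off <- integer(n)
  jit <- stats::runif(n) >= homogeneity
  off[jit] <- sample(c(-3L:-1L, 1L:3L), sum(jit), replace = TRUE)
  modal + off
}

arm_reads <- function(n, modal_start, m, homogeneity, locus, prefix,
                      mode = c("sample", "exact", "lowhom")) {
  mode <- match.arg(mode)
  if (n <= 0L) return(NULL)
  if (mode == "exact") {
    # planted counts are the violation under test: hold 5' ends and lengths
    s <- rep(modal_start, n)
    len <- rep(m, n)
  } else if (mode == "lowhom") {
    # low 5'-end homogeneity with a deterministically dominant modal, so
    # the duplex geometry stays callable while the criterion fails
    n_modal <- max(1L, round(n * homogeneity))
    offs <- rep_len(c(-2L, -1L, 1L, 2L), max(0L, n - n_modal))
    s <- c(rep(modal_start, n_modal), modal_start + offs)
    len <- c(rep(m, n_modal), mirna_read_lengths(length(offs), m))
  } else {
    s <- jitter_starts(n, modal_start, homogeneity)
    len <- mirna_read_lengths(n, m)
  }
  gi <- loc_read_to_genomic(s, len, locus$window_start, locus$window_end,
                            locus$strand)
  data.frame(read_id = sprintf("%s_%s_%04d", locus$locus_id, prefix,
                               seq_len(n)),
             segment = "chr1", start = gi[, "start"], end = gi[, "end"],
             strand = locus$strand, seq = NA_character_,
             mismatches = 0L, hits = 1L, stringsAsFactors = FALSE)
}

place_bulk_reads <- function(n, feat_rows, genome_len, prefix, p21 = 0.7,
                             both_strands = TRUE, hits_max = 1L,
                             exclude = NULL) {
  if (n <= 0L) return(NULL)
  if (!is.null(feat_rows)) {
    row <- feat_rows[sample(nrow(feat_rows), n, replace = TRUE), ]
    len <- bulk_read_lengths(n, p21)
    s <- row$start + floor(stats::runif(n) * pmax(1L, row$end - row$start - len))
    strand <- if (both_strands) sample(c("+", "-"), n, replace = TRUE)
              else row$strand
  } else {
    # intergenic background: rejection-sample outside excluded intervals
    len <- bulk_read_lengths(n, p21)
    s <- integer(0); strand <- character(0)
    while (length(s) < n) {
      need <- (n - length(s)) * 2L
      cand <- floor(stats::runif(need) * (genome_len - 45L))
      if (!is.null(exclude) && length(exclude) > 0L) {
        hit <- IRanges::overlapsAny(
          IRanges::IRanges(start = cand + 1L, width = 40L), exclude)
        cand <- cand[!hit]
      }
      s <- c(s, cand)
      strand <- c(strand, sample(c("+", "-"), length(cand), replace = TRUE))
    }
    s <- s[seq_len(n)]; strand <- strand[seq_len(n)]
  }
  hits <- if (hits_max > 1L) sample(seq_len(hits_max), n, replace = TRUE,
                                    prob = c(0.7, rep(0.3 / (hits_max - 1),
                                                      hits_max - 1L)))
          else rep(1L, n)
  data.frame(read_id = sprintf("%s_%06d", prefix, seq_len(n)),
             segment = "chr1", start = as.integer(s),
             end = as.integer(s + len), strand = strand,
             seq = NA_character_, mismatches = 0L, hits = hits,
             stringsAsFactors = FALSE)
}

#' Simulate one small RNA library
#'
#' Draws reads for one (genotype, timepoint) condition: miRNA-locus duplex
#' reads with 5'-end homogeneity, moR secondary-duplex reads, decoy-locus
#' reads, genotype-invariant DIRS1-like siRNAs on both strands, TRE3-like
#' complex-repeat reads upregulated in the knockout, structural-ncRNA and
#' mRNA fragments, and intergenic background. In the knockout, miRNA-locus
#' counts are divided by `ko_mirna_depletion` and 5'-end homogeneity is
#' halved.
#'
#' @param sim output of [simulate_genome()] (or its `truth` element plus the
#'   genome, as a list).
#' @param genotype `"wt"` or `"ko"`.
#' @param timepoint `"0h"` or `"16h"`.
#' @param scenario a [sim_scenario()].
#' @return alignment data.frame (see [read_alignments()]) with attribute
#'   `library_size` = number of reads.
#' @export
simulate_small_reads <- function(sim, genotype = c("wt", "ko"),
                                 timepoint = c("0h", "16h"),
                                 scenario = sim$truth$scenario) {
  genotype <- match.arg(genotype)
  timepoint <- match.arg(timepoint)
  set.seed(sim_seed(scenario, paste(genotype, timepoint, sep = "_")))
  truth <- sim$truth
  genome_str <- as.character(sim$genome)[[1]]
  genome_len <- nchar(genome_str)
  features <- sim$features
  out <- list()

  for (i in seq_len(nrow(truth$loci))) {
    locus <- truth$loci[i, ]
    mu <- locus$reads_per_cond
    if (timepoint == "16h") mu <- mu * locus$dev_fold
    h <- locus$homogeneity
    if (genotype == "ko" && locus$ko_depleted) {
      mu <- mu / scenario$ko_mirna_depletion
      h <- h / 2
    }
    mode <- "sample"
    if (!is.na(locus$violation) && locus$violation == "read_support") {
      # the violation planted here is the count itself: hold everything
      # else exact so no other criterion is disturbed
      mode <- "exact"
      n <- as.integer(round(mu))
      n5 <- n %/% 2L
    } else if (!is.na(locus$violation) && locus$violation == "homogeneity") {
      mode <- "lowhom"
      n <- rcount(1L, mu, scenario$nb_dispersion)
      n5 <- stats::rbinom(1L, n, 0.5)
    } else {
      n <- rcount(1L, mu, scenario$nb_dispersion)
      n5 <- stats::rbinom(1L, n, 0.5)
    }
    out[[length(out) + 1L]] <- arm_reads(n5, locus$m5_s, locus$m,
                                         h, locus, "5p", mode)
    out[[length(out) + 1L]] <- arm_reads(n - n5, locus$m3_s, locus$m,
                                         h, locus, "3p", mode)
    if (isTRUE(locus$mor)) {
      nb <- rcount(1L, mu * scenario$mor_secondary_frac,
                   scenario$nb_dispersion)
      nb5 <- stats::rbinom(1L, nb, 0.5)
      out[[length(out) + 1L]] <- arm_reads(nb5, locus$m5b_s, locus$m,
                                           h, locus, "5pb")
      out[[length(out) + 1L]] <- arm_reads(nb - nb5, locus$m3b_s, locus$m,
                                           h, locus, "3pb")
    }
  }

  dirs <- features[features$ftype == "DIRS1", ]
  tre <- features[features$ftype == "complex_repeat", ]
  nc <- features[features$ftype %in% c("tRNA", "rRNA", "snoRNA", "snRNA",
                                       "SRP", "classI"), ]
  mrna <- features[features$ftype == "mRNA", ]
  win <- truth$loci
  excl <- IRanges::reduce(IRanges::IRanges(
    start = c(features$start, win$window_start - 40L) + 1L,
    end = c(features$end, win$window_end + 40L)))

  n_tre <- scenario$complex_repeat_reads *
    if (genotype == "ko") scenario$ko_complex_fold else 1
  out[[length(out) + 1L]] <-
    place_bulk_reads(stats::rpois(1L, scenario$sirna_reads), dirs,
                     genome_len, paste0("dirs_", genotype, timepoint),
                     hits_max = 3L)
  out[[length(out) + 1L]] <-
    place_bulk_reads(stats::rpois(1L, n_tre), tre, genome_len,
                     paste0("tre_", genotype, timepoint), hits_max = 3L)
  out[[length(out) + 1L]] <-
    place_bulk_reads(stats::rpois(1L, scenario$ncrna_reads), nc, genome_len,
                     paste0("nc_", genotype, timepoint), p21 = 0.1,
                     both_strands = FALSE)
  out[[length(out) + 1L]] <-
    place_bulk_reads(stats::rpois(1L, scenario$mrna_reads), mrna, genome_len,
                     paste0("mrna_", genotype, timepoint), p21 = 0.3,
                     both_strands = TRUE)
  out[[length(out) + 1L]] <-
    place_bulk_reads(stats::rpois(1L, scenario$background_reads), NULL,
                     genome_len, paste0("bg_", genotype, timepoint),
                     p21 = 0.6, exclude = excl)

  reads <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  reads$end <- pmin(reads$end, genome_len)
  # fill sequences from the genome (read orientation)
  seqs <- substr(rep(genome_str, nrow(reads)), reads$start + 1L, reads$end)
  flip <- reads$strand == "-"
  seqs[flip] <- revcomp(seqs[flip])
  reads$seq <- seqs
  rownames(reads) <- NULL
  attr(reads, "library_size") <- nrow(reads)
  attr(reads, "genotype") <- genotype
  attr(reads, "timepoint") <- timepoint
  reads
}

#' Simulate oligo(A)-tailed 3' processing intermediates
#'
#' Generates reads ending at the planted 3'-intermediate sites of the
#' mir-1176-like locus; a `tail_fraction` of them carry an untemplated all-A
#' suffix of 4-6 nt appended after the templated end. One site sits directly
#' after three templated A residues, so tail length there is ambiguous by
#' construction.
#'
#' @param sim output of [simulate_genome()].
#' @param scenario a [sim_scenario()].
#' @return alignment data.frame; `seq` includes the tail while the interval
#'   covers only the templated span. Attribute `truth` records the planted
#'   tail length per read (0 = untailed).
#' @export
simulate_tailed_reads <- function(sim, scenario = sim$truth$scenario) {
  set.seed(sim_seed(scenario, "tails"))
  truth <- sim$truth
  genome_str <- as.character(sim$genome)[[1]]
  locus <- truth$loci[!is.na(truth$loci$tail_site1), ][1, ]
  n <- scenario$n_tail_reads
  if (n <= 0L) {
    df <- data.frame(read_id = character(), segment = character(),
                     start = integer(), end = integer(), strand = character(),
                     seq = character(), mismatches = integer(),
                     hits = integer())
    attr(df, "truth") <- integer(0)
    return(df)
  }
  site_rel <- sample(c(locus$tail_site1, locus$tail_site2), n, replace = TRUE)
  end_g <- from_relative(site_rel, locus$anchor, locus$strand)
  tailed <- stats::runif(n) < scenario$tail_fraction
  tl <- integer(n)
  tl[tailed] <- sample(scenario$tail_length[1]:scenario$tail_length[2],
                       sum(tailed), replace = TRUE)
  len <- sample(22:32, n, replace = TRUE)
  if (locus$strand == "+") {
    start <- end_g - len + 1L
    templ <- substr(rep(genome_str, n), start + 1L, end_g + 1L)
    iv <- cbind(start = start, end = end_g + 1L)
  } else {
    start <- end_g
    templ <- revcomp(substr(rep(genome_str, n), start + 1L, start + len))
    iv <- cbind(start = start, end = start + len)
  }
  seqs <- paste0(templ, strrep("A", tl))
  df <- data.frame(read_id = sprintf("tail_%04d", seq_len(n)),
                   segment = "chr1", start = iv[, "start"],
                   end = iv[, "end"], strand = locus$strand, seq = seqs,
                   mismatches = 0L, hits = 1L, stringsAsFactors = FALSE)
  attr(df, "truth") <- tl
  attr(df, "site_rel") <- site_rel
  df
}

#' Simulate long RNA coverage tracks
#'
#' Per-position depth over each pri-miRNA span: from the planted TSS to the
#' planted 3' end in wt, enriched `ko_pri_enrichment`-fold and (for
#' readthrough loci) extended into the downstream gene in the knockout.
#' Positions inside planted A-run gaps are forced to zero in both genotypes,
#' mimicking unsequenceable A-homopolymers. mRNA features get constant
#' genotype-invariant background coverage.
#'
#' @param sim output of [simulate_genome()].
#' @param genotype `"wt"` or `"ko"`.
#' @param timepoint kept for interface symmetry; coverage is pooled over
#'   timepoints as in per-million display tracks.
#' @param scenario a [sim_scenario()].
#' @return list with one [coverage_track()] per strand (`"+"`, `"-"`).
#' @export
simulate_coverage <- function(sim, genotype = c("wt", "ko"),
                              timepoint = "pooled",
                              scenario = sim$truth$scenario) {
  genotype <- match.arg(genotype)
  set.seed(sim_seed(scenario, paste0("cov_", genotype,
                                     if (timepoint == "pooled") "_pooled"
                                     else paste0("_", timepoint))))
  truth <- sim$truth
  L <- nchar(as.character(sim$genome)[[1]])
  counts <- list("+" = numeric(L), "-" = numeric(L))
  depth <- scenario$coverage_depth_wt *
    if (genotype == "ko") scenario$ko_pri_enrichment else 1

  for (i in seq_len(nrow(truth$loci))) {
    locus <- truth$loci[i, ]
    if (locus$class != "mirna") next
    span_end <- locus$pri_end
    if (locus$readthrough) {
      if (genotype == "wt") {
        span_end <- from_relative(locus$wt_end_rel, locus$anchor,
                                  locus$strand)
      } else {
        span_end <- if (locus$strand == "+") locus$dsg_end - 1L
                    else locus$dsg_start
      }
    }
    span <- sort(c(locus$tss, span_end))
    idx <- (span[1L]:span[2L]) + 1L
    d <- if (scenario$coverage_noise)
      pmax(1, stats::rpois(length(idx), depth)) else rep(depth, length(idx))
    counts[[locus$strand]][idx] <- counts[[locus$strand]][idx] + d
    if (locus$readthrough && !is.na(locus$gap_start))
      counts[[locus$strand]][(locus$gap_start:(locus$gap_end - 1L)) + 1L] <- 0
  }
  mrna <- sim$features[sim$features$ftype == "mRNA", ]
  for (k in seq_len(nrow(mrna)))
    counts[[mrna$strand[k]]][(mrna$start[k]:(mrna$end[k] - 1L)) + 1L] <-
      counts[[mrna$strand[k]]][(mrna$start[k]:(mrna$end[k] - 1L)) + 1L] + 3
  lapply(stats::setNames(c("+", "-"), c("+", "-")), function(st)
    coverage_track("chr1", st, 0L, counts[[st]],
                   scenario$longrna_library_size))
}

#' Simulate a complete dataset
#'
#' Convenience wrapper: genome + features + truth, the four small RNA
#' libraries (wt/ko x 0h/16h), tailed intermediate reads, and coverage
#' tracks per genotype.
#'
#' @param scenario a [sim_scenario()].
#' @return list with elements `genome`, `features`, `truth`, `reads` (named
#'   list wt_0h/wt_16h/ko_0h/ko_16h), `tailed`, `coverage` (named list
#'   wt/ko, each per strand).
#' @export
simulate_dataset <- function(scenario = sim_scenario()) {
  sim <- simulate_genome(scenario)
  sim$reads <- list(
    wt_0h = simulate_small_reads(sim, "wt", "0h", scenario),
    wt_16h = simulate_small_reads(sim, "wt", "16h", scenario),
    ko_0h = simulate_small_reads(sim, "ko", "0h", scenario),
    ko_16h = simulate_small_reads(sim, "ko", "16h", scenario))
  sim$tailed <- simulate_tailed_reads(sim, scenario)
  sim$coverage <- list(wt = simulate_coverage(sim, "wt", scenario = scenario),
                       ko = simulate_coverage(sim, "ko", scenario = scenario))
  sim
}

#' Write a simulated dataset to disk
#'
#' Writes FASTA genome, GFF3 features, TSV alignments per condition,
#' bedGraph coverage per genotype and strand, and the ground truth as JSON.
#'
#' @param sim output of [simulate_dataset()].
#' @param outdir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_simulation <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- c(
    write_fasta(sim$genome, file.path(outdir, "genome.fa")),
    write_gff3(sim$features, file.path(outdir, "features.gff3")))
  for (cond in names(sim$reads))
    files <- c(files, write_alignments(
      sim$reads[[cond]], file.path(outdir, sprintf("reads_%s.tsv", cond))))
  files <- c(files, write_alignments(
    sim$tailed, file.path(outdir, "reads_tailed.tsv")))
  for (gt in names(sim$coverage))
    for (st in names(sim$coverage[[gt]]))
      files <- c(files, write_bedgraph(
        sim$coverage[[gt]][[st]],
        file.path(outdir, sprintf("coverage_%s_%s.bedGraph", gt,
                                  if (st == "+") "plus" else "minus"))))
  jsonlite::write_json(sim$truth$loci,
                       file.path(outdir, "truth.json"), digits = NA)
  invisible(c(files, file.path(outdir, "truth.json")))
}
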