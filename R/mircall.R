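# The criteria engine: read stacks on candidate hairpins, duplex calling,
# the five high-confidence miRNA criteria, knockout dependence,
# developmental regulation, and miRNA-offset (moR) secondary duplex pairs.

#' Calling thresholds
#'
#' Defaults encode the high-confidence criteria: at least 10 reads per arm,
#' 2-nt 3' overhangs (strict; 0-4 relaxed), >= 50% of arm reads sharing the
#' modal 5' end, per-nt folding energy strictly below threshold, >= 60% of
#' the duplex paired, and clear knockout downregulation (log2 fold change
#' <= -2 with pseudocount 1 on counts per million).
#'
#' @param ... overrides for any threshold.
#' @return named list of thresholds.
#' @export
call_thresholds <- function(...) {
  th <- list(min_reads = 10L, overhang_mode = "strict2",
             min_homogeneity = 0.5, energy_per_nt = NULL,  # NULL = by backend
             min_pairing = 0.60, max_ko_log2fc = -2,
             min_dev_abs_log2fc = 1, pseudocount = 1,
             stack_overlap = 0.75, arm_overlap = 0.5,
             mor_gap = 3L, mor_mask = 2L, flank = 20L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(th))
  if (length(unknown)) stop("unknown threshold: ",
                            paste(unknown, collapse = ", "))
  th[names(dots)] <- dots
  th
}

#' Build a read stack over a locus window
#'
#' Reads overlapping the window by at least `min_overlap` of their aligned
#' length are stacked as (5' start, length) counts in locus-forward
#' window-local coordinates (minus-strand loci are flipped into locus
#' orientation).
#'
#' @param reads alignment data.frame; only reads on the locus strand stack.
#' @param locus list or one-row data.frame with `window_start`, `window_end`,
#'   `strand` (and optionally `segment_id`, `locus_id`).
#' @param min_overlap minimum fraction of the read inside the window.
#' @param library_size library size for per-million scaling; defaults to the
#'   `library_size` attribute of `reads`, falling back to `nrow(reads)`.
#' @return object of class `read_stack` with a `table` of
#'   (start, length, count), `total`, and `library_size`.
#' @export
build_stack <- function(reads, locus, min_overlap = 0.75,
                        library_size = NULL) {
  if (is.null(library_size)) {
    library_size <- attr(reads, "library_size")
    if (is.null(library_size)) library_size <- max(1L, nrow(reads))
  }
  ws <- locus$window_start; we <- locus$window_end
  keep <- reads$strand == locus$strand
  if (!is.null(reads$segment) && !is.null(locus$segment_id))
    keep <- keep & reads$segment == locus$segment_id
  r <- reads[keep, , drop = FALSE]
  w <- r$end - r$start
  ov <- pmin(r$end, we) - pmax(r$start, ws)
  r <- r[ov >= min_overlap * w, , drop = FALSE]
  if (nrow(r)) {
    s <- if (locus$strand == "+") r$start - ws else we - r$end
    len <- r$end - r$start
    tab <- stats::aggregate(list(count = rep(1L, nrow(r))),
                            by = list(start = s, length = len), FUN = sum)
    tab <- tab[order(tab$start, tab$length), , drop = FALSE]
    rownames(tab) <- NULL
  } else {
    tab <- data.frame(start = integer(), length = integer(),
                      count = integer())
  }
  structure(list(locus_id = if (!is.null(locus$locus_id)) locus$locus_id
                            else NA_character_,
                 window = c(ws, we), strand = locus$strand, table = tab,
                 total = sum(tab$count), library_size = library_size),
            class = "read_stack")
}

#' @export
print.read_stack <- function(x, ...) {
  cat(sprintf("read_stack %s [%d,%d)%s: %d reads, %d distinct, lib %g\n",
              x$locus_id, x$window[1], x$window[2], x$strand, x$total,
              nrow(x$table), x$library_size))
  invisible(x)
}

# Pool stacks over conditions (counts add; library sizes add).
pool_stacks <- function(...) {
  stacks <- list(...)
  out <- stacks[[1L]]
  if (length(stacks) > 1L) {
    tab <- do.call(rbind, lapply(stacks, function(s) s$table))
    if (nrow(tab)) {
      tab <- stats::aggregate(count ~ start + length, data = tab, FUN = sum)
      tab <- tab[order(tab$start, tab$length), , drop = FALSE]
      rownames(tab) <- NULL
    }
    out$table <- tab
    out$total <- sum(tab$count)
    out$library_size <- sum(vapply(stacks, function(s) s$library_size,
                                   numeric(1)))
  }
  out
}

# Principal hairpin loop of a structure: the loop whose closing pair is
# enclosed by the deepest stem. Shallow side hairpins (e.g. folded AT-rich
# flanks of the window) are tolerated; two equally deep loops mean the
# structure has no single dominant stem-loop and is rejected.
hairpin_loop <- function(structure) {
  pm <- structure$pair_map
  n <- length(pm)
  opens <- which(!is.na(pm) & seq_len(n) < pm)
  loops <- list(); depth <- integer(0)
  for (i in opens) {
    j <- pm[i]
    inner <- if (j - i > 1L) pm[(i + 1L):(j - 1L)] else integer(0)
    if (all(is.na(inner))) {
      loops[[length(loops) + 1L]] <- c(i - 1L, j)  # 0-based loop bounds
      depth <- c(depth, sum(opens <= i & pm[opens] >= j))
    }
  }
  if (length(loops) == 0L) stop("not a simple hairpin: no loop found")
  top <- which(depth == max(depth))
  if (length(top) == 1L) return(loops[[top]])
  # sibling loops at the stem tip (fold wobble) merge into one loop region;
  # widely separated equally-deep loops mean a branched structure
  span <- range(unlist(loops[top]))
  if (span[2L] - span[1L] > 40L)
    stop("not a simple hairpin: ", length(top),
         " separate loops with no dominant stem")
  span
}

#' Call the 5p and 3p arms of a read stack
#'
#' Reads are assigned to the arm containing at least half of their span (5p
#' is the 5' side of the hairpin loop). Per arm, the modal read is the most
#' frequent (start, length), ties broken toward the smaller start then the
#' longer read; homogeneity is the largest fraction of arm reads sharing a
#' single 5' start.
#'
#' @param stack a [build_stack()] result.
#' @param structure folded `hairpin_structure` of the same window.
#' @return list with elements `p5` and `p3`, each with `arm`, `modal_start`,
#'   `modal_length`, `modal_count`, `total`, `homogeneity`.
#' @export
call_arms <- function(stack, structure) {
  lp <- hairpin_loop(structure)
  mid <- (lp[1L] + lp[2L]) / 2
  tab <- stack$table
  arm_of <- function(s, len) {
    frac5 <- (pmin(s + len, mid) - pmin(s, mid)) / len
    ifelse(frac5 >= 0.5, "5p", "3p")
  }
  one_arm <- function(arm) {
    sub <- if (nrow(tab)) tab[arm_of(tab$start, tab$length) == arm, ,
                              drop = FALSE]
           else tab
    total <- sum(sub$count)
    if (total == 0L)
      return(list(arm = arm, modal_start = NA_integer_,
                  modal_length = NA_integer_, modal_count = 0L,
                  total = 0L, homogeneity = NA_real_))
    o <- order(-sub$count, sub$start, -sub$length)
    modal <- sub[o[1L], ]
    by_start <- tapply(sub$count, sub$start, sum)
    list(arm = arm, modal_start = modal$start,
         modal_length = modal$length, modal_count = modal$count,
         total = total, homogeneity = max(by_start) / total)
  }
  list(p5 = one_arm("5p"), p3 = one_arm("3p"))
}

#' Read-support criterion (i)
#' @param arms output of [call_arms()].
#' @param min_reads minimum reads per arm (both arms must reach it).
#' @return list with `pass`, `n5`, `n3`, `threshold`.
#' @export
criterion_read_support <- function(arms, min_reads = 10L) {
  list(pass = arms$p5$total >= min_reads && arms$p3$total >= min_reads,
       n5 = arms$p5$total, n3 = arms$p3$total, threshold = min_reads)
}

#' 3'-overhang criterion (ii)
#' @param ov output of [overhangs()] for the called duplex.
#' @param mode `"strict2"` (both exactly 2) or `"relaxed0to4"` (both in 0-4).
#' @return list with `pass`, `overhangs`, `mode`. Undefined overhangs fail.
#' @export
criterion_overhang <- function(ov, mode = c("strict2", "relaxed0to4")) {
  mode <- match.arg(mode)
  pass <- if (any(is.na(ov))) FALSE
          else if (mode == "strict2") all(ov == 2L)
          else all(ov >= 0L & ov <= 4L)
  list(pass = pass, overhangs = ov, mode = mode)
}

#' 5'-end homogeneity criterion (iii)
#' @param arms output of [call_arms()].
#' @param min_frac minimum fraction per arm (inclusive).
#' @return list with `pass`, `h5`, `h3`, `threshold`.
#' @export
criterion_homogeneity <- function(arms, min_frac = 0.5) {
  h5 <- arms$p5$homogeneity; h3 <- arms$p3$homogeneity
  list(pass = !is.na(h5) && !is.na(h3) && h5 >= min_frac && h3 >= min_frac,
       h5 = h5, h3 = h3, threshold = min_frac)
}

arm_cpm <- function(arms, library_size) {
  c(p5 = arms$p5$total, p3 = arms$p3$total) / library_size * 1e6
}

#' Knockout dependence of a locus
#'
#' Per-arm log2 fold change of knockout vs wild type on pseudocounted
#' counts-per-million; passes iff both arms are at or below `max_log2fc`.
#'
#' @param stack_wt,stack_ko stacks of the same locus in the two genotypes
#'   (with their library sizes).
#' @param structure folded structure (for arm assignment).
#' @param pseudocount added to both cpm values.
#' @param max_log2fc pass threshold (clear downregulation).
#' @return list with `pass`, `log2fc` (per arm), `wt_cpm`, `ko_cpm`.
#' @export
ko_dependence <- function(stack_wt, stack_ko, structure, pseudocount = 1,
                          max_log2fc = -2) {
  if (is.null(stack_wt$library_size) || is.null(stack_ko$library_size))
    stop("missing library size")
  arms_wt <- call_arms(stack_wt, structure)
  arms_ko <- call_arms(stack_ko, structure)
  wt <- arm_cpm(arms_wt, stack_wt$library_size)
  ko <- arm_cpm(arms_ko, stack_ko$library_size)
  lfc <- log2((ko + pseudocount) / (wt + pseudocount))
  list(pass = all(lfc <= max_log2fc), log2fc = lfc, wt_cpm = wt, ko_cpm = ko)
}

#' Developmental regulation of a locus
#'
#' Flags a locus as developmentally regulated iff the absolute log2 fold
#' change between timepoints on the dominant arm reaches the threshold.
#'
#' @param stack_0h,stack_16h stacks of the same locus at the two timepoints.
#' @param structure folded structure.
#' @param pseudocount added to both cpm values.
#' @param min_abs_log2fc flag threshold.
#' @return list with `flag`, `log2fc` (per arm), `dominant_arm`.
#' @export
developmental_regulation <- function(stack_0h, stack_16h, structure,
                                     pseudocount = 1, min_abs_log2fc = 1) {
  arms_0 <- call_arms(stack_0h, structure)
  arms_16 <- call_arms(stack_16h, structure)
  c0 <- arm_cpm(arms_0, stack_0h$library_size)
  c16 <- arm_cpm(arms_16, stack_16h$library_size)
  lfc <- log2((c16 + pseudocount) / (c0 + pseudocount))
  dom <- if ((arms_0$p5$total + arms_16$p5$total) >=
             (arms_0$p3$total + arms_16$p3$total)) "p5" else "p3"
  list(flag = abs(lfc[[dom]]) >= min_abs_log2fc, log2fc = lfc,
       dominant_arm = dom)
}

duplex_from_arms <- function(arms) {
  if (is.na(arms$p5$modal_start) || is.na(arms$p3$modal_start)) return(NULL)
  d <- list(mir5p = c(arms$p5$modal_start,
                      arms$p5$modal_start + arms$p5$modal_length),
            mir3p = c(arms$p3$modal_start,
                      arms$p3$modal_start + arms$p3$modal_length))
  if (d$mir5p[2L] > d$mir3p[1L]) return(NULL)  # arms collide: no duplex
  d
}

#' Detect miRNA-offset (moR) secondary duplex pairs
#'
#' Masks the reads of the primary duplex (5' starts within `mask` nt of each
#' primary modal start), re-calls arms on the residue, and accepts a
#' secondary duplex iff both residual arms pass read support and homogeneity
#' and each secondary arm is adjacent (gap <= `gap` nt, no overlap) to the
#' primary arm on its side. The pair closest to the base of the stem-loop is
#' labeled "-1", the loop-proximal one "-2".
#'
#' @param stack a [build_stack()] result.
#' @param structure folded structure.
#' @param primary_arms [call_arms()] of the primary duplex.
#' @param th thresholds from [call_thresholds()].
#' @return list of 1-2 entries, each with `label`, `arms`, `duplex`.
#' @export
detect_mor_pairs <- function(stack, structure, primary_arms,
                             th = call_thresholds()) {
  out <- list(list(label = NA_character_, arms = primary_arms,
                   duplex = duplex_from_arms(primary_arms)))
  tab <- stack$table
  m5 <- primary_arms$p5$modal_start; m3 <- primary_arms$p3$modal_start
  if (is.na(m5) || is.na(m3)) { out[[1L]]$label <- "-1"; return(out) }
  keep <- abs(tab$start - m5) > th$mor_mask & abs(tab$start - m3) > th$mor_mask
  res <- stack
  res$table <- tab[keep, , drop = FALSE]
  res$total <- sum(res$table$count)
  sec <- call_arms(res, structure)
  ok <- criterion_read_support(sec, th$min_reads)$pass &&
    criterion_homogeneity(sec, th$min_homogeneity)$pass
  adj <- FALSE
  if (ok) {
    p5_end <- m5 + primary_arms$p5$modal_length
    p3_end <- m3 + primary_arms$p3$modal_length
    gap5 <- if (sec$p5$modal_start >= p5_end) sec$p5$modal_start - p5_end
            else m5 - (sec$p5$modal_start + sec$p5$modal_length)
    gap3 <- if (sec$p3$modal_start >= p3_end) sec$p3$modal_start - p3_end
            else m3 - (sec$p3$modal_start + sec$p3$modal_length)
    adj <- gap5 >= 0L && gap5 <= th$mor_gap && gap3 >= 0L && gap3 <= th$mor_gap
  }
  if (ok && adj && !is.null(duplex_from_arms(sec))) {
    # base-proximal pair = smaller 5p modal start (locus-forward coords)
    primary_basal <- m5 <= sec$p5$modal_start
    out[[1L]]$label <- if (primary_basal) "-1" else "-2"
    out[[2L]] <- list(label = if (primary_basal) "-2" else "-1",
                      arms = sec, duplex = duplex_from_arms(sec))
  } else {
    out[[1L]]$label <- "-1"
  }
  out
}

# Restrict a stack to the reads nearest (by 5' start) to one pair's modal
# starts, when two adjacent duplex pairs share a hairpin.
split_stack_by_pair <- function(stack, anchors, pair_of, idx) {
  tab <- stack$table
  out <- stack
  if (nrow(tab)) {
    d <- abs(outer(tab$start, anchors, "-"))
    pick <- apply(d, 1L, which.min)
    out$table <- tab[pair_of[pick] == idx, , drop = FALSE]
    out$total <- sum(out$table$count)
  }
  out
}

# Evaluate the per-pair criteria (i, ii, iii, v + knockout dependence) on a
# pair-restricted stack; iv (energy) is a property of the whole hairpin.
evaluate_pair <- function(stack_wt, stack_ko, structure, th, ethr) {
  arms <- call_arms(stack_wt, structure)
  duplex <- duplex_from_arms(arms)
  cri <- list(i_read_support = criterion_read_support(arms, th$min_reads),
              iii_homogeneity = criterion_homogeneity(arms,
                                                      th$min_homogeneity))
  if (!is.null(duplex)) {
    ov <- overhangs(structure, duplex)
    cri$ii_overhang <- criterion_overhang(ov, th$overhang_mode)
    cri$ii_overhang_relaxed <- criterion_overhang(ov, "relaxed0to4")
    pf <- pairing_fraction(structure, duplex)
    cri$v_pairing <- list(pass = passes_pairing(pf, th$min_pairing),
                          fraction = pf, threshold = th$min_pairing)
  } else {
    cri$ii_overhang <- list(pass = FALSE, overhangs = c(NA, NA),
                            mode = th$overhang_mode)
    cri$ii_overhang_relaxed <- list(pass = FALSE, overhangs = c(NA, NA),
                                    mode = "relaxed0to4")
    cri$v_pairing <- list(pass = FALSE, fraction = NA_real_,
                          threshold = th$min_pairing)
  }
  cri$iv_energy <- list(pass = passes_energy(structure, ethr),
                        mfe_per_nt = mfe_per_nt(structure), threshold = ethr)
  ko <- ko_dependence(stack_wt, stack_ko, structure, th$pseudocount,
                      th$max_ko_log2fc)
  core_pass <- cri$iii_homogeneity$pass && cri$iv_energy$pass &&
    cri$v_pairing$pass && ko$pass
  tier <- if (core_pass && cri$i_read_support$pass && cri$ii_overhang$pass)
    "high_confidence"
  else if (core_pass && cri$ii_overhang$pass && !cri$i_read_support$pass)
    "candidate"
  else if (core_pass && cri$i_read_support$pass &&
           cri$ii_overhang_relaxed$pass)
    "candidate"
  else "reject"
  list(arms = arms, duplex = duplex, criteria = cri, ko = ko, tier = tier)
}

#' Classify one candidate locus
#'
#' Calls the duplex pairs of a candidate hairpin from its pooled wild-type
#' read stack (1 pair normally, 2 for moR-style loci) and applies the five
#' high-confidence criteria plus knockout dependence to each pair
#' separately, as adjacent pairs are distinct processing products. Tier per
#' pair: `high_confidence` iff read support, strict overhang, homogeneity,
#' energy, pairing and knockout dependence all pass; `candidate` iff
#' everything passes except read support (a true locus occluded by abundant
#' siRNAs), or the overhang passes only in relaxed mode; otherwise
#' `reject`. The locus tier is the best pair tier.
#'
#' @param locus list/row with window coordinates and strand.
#' @param structure folded `hairpin_structure` of the locus window.
#' @param stack_wt pooled wild-type stack.
#' @param stack_ko pooled knockout stack.
#' @param stack_wt_0h,stack_wt_16h per-timepoint wild-type stacks (optional;
#'   enables the developmental-regulation flag).
#' @param th thresholds from [call_thresholds()].
#' @return list of class `locus_call`: `locus_id`, `tier`, `criteria` (per
#'   criterion: measured value(s) + pass flag + threshold), `pairs` (1-2
#'   labeled duplexes), `ko`, `dev`.
#' @export
classify_locus <- function(locus, structure, stack_wt, stack_ko,
                           stack_wt_0h = NULL, stack_wt_16h = NULL,
                           th = call_thresholds()) {
  ethr <- if (is.null(th$energy_per_nt)) {
    if (structure$backend == "internal") -0.5 else -0.2
  } else th$energy_per_nt
  arms <- call_arms(stack_wt, structure)
  pairs <- detect_mor_pairs(stack_wt, structure, arms, th)

  if (length(pairs) == 2L) {
    anchors <- c(pairs[[1L]]$arms$p5$modal_start,
                 pairs[[2L]]$arms$p5$modal_start,
                 pairs[[1L]]$arms$p3$modal_start,
                 pairs[[2L]]$arms$p3$modal_start)
    pair_of <- c(1L, 2L, 1L, 2L)
    evals <- lapply(1:2, function(k)
      evaluate_pair(split_stack_by_pair(stack_wt, anchors, pair_of, k),
                    split_stack_by_pair(stack_ko, anchors, pair_of, k),
                    structure, th, ethr))
  } else {
    evals <- list(evaluate_pair(stack_wt, stack_ko, structure, th, ethr))
  }
  for (k in seq_along(pairs)) {
    pairs[[k]]$arms <- evals[[k]]$arms
    pairs[[k]]$duplex <- evals[[k]]$duplex
    pairs[[k]]$criteria <- evals[[k]]$criteria
    pairs[[k]]$tier <- evals[[k]]$tier
  }
  dev <- if (!is.null(stack_wt_0h) && !is.null(stack_wt_16h))
    developmental_regulation(stack_wt_0h, stack_wt_16h, structure,
                             th$pseudocount, th$min_dev_abs_log2fc)
  else NULL

  tiers <- vapply(evals, function(e) e$tier, character(1))
  tier <- if (any(tiers == "high_confidence")) "high_confidence"
          else if (any(tiers == "candidate")) "candidate" else "reject"
  best <- which(tiers == tier)[1L]

  structure(list(locus_id = if (!is.null(locus$locus_id)) locus$locus_id
                            else NA_character_,
                 tier = tier, criteria = evals[[best]]$criteria,
                 pairs = pairs, ko = evals[[best]]$ko, dev = dev),
            class = "locus_call")
}

#' @export
print.locus_call <- function(x, ...) {
  fails <- names(x$criteria)[!vapply(x$criteria, function(z) isTRUE(z$pass),
                                     logical(1))]
  cat(sprintf("locus_call %s: %s (%d duplex pair%s%s)\n", x$locus_id, x$tier,
              length(x$pairs), if (length(x$pairs) > 1) "s" else "",
              if (length(fails)) paste0("; failing: ",
                                        paste(fails, collapse = ","))
              else ""))
  invisible(x)
}

#' Call all candidate loci of a simulated or loaded dataset
#'
#' Folds each candidate hairpin window, builds pooled wild-type and knockout
#' stacks, and classifies every locus.
#'
#' @param genome DNAStringSet (or character) genome.
#' @param candidates data.frame of candidate loci with `locus_id`,
#'   `window_start`, `window_end`, `strand` (e.g. truth loci or
#'   hairpin_candidate features widened by `th$flank`).
#' @param reads named list with elements `wt_0h`, `wt_16h`, `ko_0h`,
#'   `ko_16h` of alignment data.frames (attribute `library_size` used).
#' @param th thresholds from [call_thresholds()].
#' @return list with `calls` (list of `locus_call`) and `summary`
#'   (data.frame, one row per locus).
#' @export
call_all_loci <- function(genome, candidates, reads,
                          th = call_thresholds()) {
  genome_str <- if (is.character(genome)) genome[[1]]
                else as.character(genome)[[1]]
  calls <- vector("list", nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    locus <- candidates[i, ]
    ws <- window_seq(genome_str, locus$window_start, locus$window_end,
                     locus$strand)
    st <- fold(ws, locus$locus_id)
    s_wt0 <- build_stack(reads$wt_0h, locus, th$stack_overlap)
    s_wt16 <- build_stack(reads$wt_16h, locus, th$stack_overlap)
    s_ko0 <- build_stack(reads$ko_0h, locus, th$stack_overlap)
    s_ko16 <- build_stack(reads$ko_16h, locus, th$stack_overlap)
    calls[[i]] <- classify_locus(locus, st,
                                 pool_stacks(s_wt0, s_wt16),
                                 pool_stacks(s_ko0, s_ko16),
                                 s_wt0, s_wt16, th)
  }
  summary <- do.call(rbind, lapply(calls, function(cl) {
    data.frame(locus_id = cl$locus_id, tier = cl$tier,
               n_pairs = length(cl$pairs),
               n5 = cl$criteria$i_read_support$n5,
               n3 = cl$criteria$i_read_support$n3,
               h5 = cl$criteria$iii_homogeneity$h5,
               h3 = cl$criteria$iii_homogeneity$h3,
               overhang3 = cl$criteria$ii_overhang$overhangs[1],
               overhang5 = cl$criteria$ii_overhang$overhangs[2],
               mfe_per_nt = cl$criteria$iv_energy$mfe_per_nt,
               pairing = cl$criteria$v_pairing$fraction,
               ko_log2fc_5p = cl$ko$log2fc[["p5"]],
               ko_log2fc_3p = cl$ko$log2fc[["p3"]],
               dev_flag = if (is.null(cl$dev)) NA else cl$dev$flag,
               stringsAsFactors = FALSE)
  }))
  list(calls = calls, summary = summary)
}
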