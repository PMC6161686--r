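#!/usr/bin/env Rscript
# Untemplated oligo(A) tails on 3' processing intermediates, and the T-run
# + G promoter motif upstream of the pri-miRNA transcription start sites,
# summarized as a position frequency matrix.

suppressPackageStartupMessages(library(mirlocus))

sim <- simulate_dataset(sim_scenario(seed = 1))
truth <- sim$truth$loci
mir <- truth[truth$class == "mirna", ]
dir.create("results", showWarnings = FALSE)

# --- oligo(A) tails at the model locus
l1 <- truth[1, ]
tc <- tail_calls(sim$tailed, sim$genome, anchor = l1$anchor,
                 strand = l1$strand)
write_report(tc, "results/tail_calls.tsv")
sp <- tail_spectrum(tc)
write_report(sp, "results/tail_spectrum.tsv")
amb <- tc$is_oligoA & tc$tail_len_max > tc$tail_len_min
cat(sprintf("tail calls: %d reads, %d oligo(A)-tailed (%d ambiguous at the templated-A site)\n",
            nrow(tc), sum(tc$is_oligoA), sum(amb)))
for (e in unique(sp$templated_end))
  cat(sprintf("  site %+d: %d tailed reads, lengths %s\n", e,
              sum(sp$count[sp$templated_end == e]),
              paste(sp$tail_len[sp$templated_end == e], collapse = "/")))

# --- TSS motif per locus, anchored at the 5'-most covered position
hits <- list()
for (i in seq_len(nrow(mir))) {
  l <- mir[i, ]
  e <- transcript_extent(sim$coverage$ko[[l$strand]],
                         list(anchor = l$anchor, strand = l$strand,
                              span_start = min(l$tss, l$pri_end) - 100L,
                              span_end = max(l$tss, l$pri_end) + 101L))
  if (is.null(e)) next
  anchor5 <- from_relative(e$five_prime_most, l$anchor, l$strand)
  h <- find_tss_motif(sim$genome, anchor5, l$strand)
  if (nrow(h))
    hits[[length(hits) + 1L]] <- cbind(locus_id = l$locus_id,
                                       strand = l$strand,
                                       tss_rel = to_relative(
                                         h$predicted_tss[1], l$anchor,
                                         l$strand),
                                       h[1, ])
}
hits <- do.call(rbind, hits)
write_report(hits, "results/tss_motifs.tsv")
cat(sprintf("\nTSS motifs: found at %d/%d miRNA loci (T-runs %d..%d nt)\n",
            nrow(hits), nrow(mir), min(hits$run_length),
            max(hits$run_length)))
for (id in c("mir01", "mir02")) {
  h <- hits[hits$locus_id == id, ]
  cat(sprintf("  %s: %d-T run, TSS (G) at relative %+d\n", id,
              h$run_length, h$tss_rel))
}

pfm <- build_pfm(hits, sim$genome, upstream_span = 30L)
write_report(cbind(base = rownames(pfm), as.data.frame(pfm)),
             "results/tss_pfm.tsv")
cat(sprintf("PFM over %d loci: G frequency at +1 = %.2f, mean T frequency at -1..-8 = %.2f\n",
            nrow(hits), pfm["G", "+1"],
            mean(pfm["T", as.character(-1:-8)])))
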