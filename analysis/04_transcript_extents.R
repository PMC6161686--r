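#!/usr/bin/env Rscript
# Pri-transcript extents from long RNA coverage: 5'/3' extremes in
# mir-5p-relative coordinates, knockout enrichment of locus transcripts,
# and readthrough into the downstream gene across the A-run coverage gap.

suppressPackageStartupMessages(library(mirlocus))

sim <- simulate_dataset(sim_scenario(seed = 1))
truth <- sim$truth$loci
mir <- truth[truth$class == "mirna", ]

ext <- extent_table(mir, sim$coverage)
dir.create("results", showWarnings = FALSE)
write_report(ext, "results/extents.tsv")

e1 <- ext[ext$locus_id == "mir01", ]
cat(sprintf("model locus mir01: knockout transcript spans %+d..%+d = %d nt\n",
            e1$ko_5p, e1$ko_3p, span_length(e1$ko_5p, e1$ko_3p)))
cat(sprintf("enrichment in knockout: %d/%d loci up, median log2FC %.2f\n",
            sum(ext$log2fc > 0), nrow(ext), median(ext$log2fc)))

l <- mir[mir$readthrough, ][1, ]
e2 <- ext[ext$locus_id == l$locus_id, ]
cat(sprintf("readthrough locus %s: wt 3' end %+d, knockout 3' end %+d\n",
            l$locus_id, e2$wt_3p, e2$ko_3p))
dsg <- list(start = l$dsg_start, end = l$dsg_end)
for (gt in c("wt", "ko")) {
  rt <- detect_readthrough(sim$coverage[[gt]][[l$strand]], l, dsg,
                           sim$genome)
  gapinfo <- if (nrow(rt$gaps))
    sprintf(" (gap %d nt, %.0f%% A, %s)", rt$gaps$length[1],
            100 * rt$gaps$a_fraction[1],
            if (rt$gaps$tolerated[1]) "tolerated" else "not tolerated")
  else ""
  cat(sprintf("  %s: bridged into downstream gene = %s%s\n", gt,
              rt$bridged, gapinfo))
}

# 3'-end census of the tailed intermediate reads at the model locus
l1 <- truth[1, ]
tc <- tail_calls(sim$tailed, sim$genome, anchor = l1$anchor,
                 strand = l1$strand)
ce <- end_census(tc$templated_end_rel)
cat(sprintf("3'-intermediate ends at mir01: dominant %+d of %d reads\n",
            attr(ce, "dominant"), attr(ce, "total")))
write_report(ce, "results/end_census_mir01.tsv")
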