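#!/usr/bin/env Rscript
# Build the synthetic study dataset: an AT-rich genome with 20 planted miRNA
# loci (including the two model loci with their published-style geometry),
# 10 single-violation decoy hairpins, 5 DIRS1-like siRNA repeat loci, four
# small RNA libraries (wt/knockout x growth/development) and long RNA
# coverage tracks. Everything downstream reads from results/sim/.

suppressPackageStartupMessages(library(mirlocus))

scenario <- sim_scenario(seed = 1)
sim <- simulate_dataset(scenario)
write_simulation(sim, "results/sim")

g <- strsplit(as.character(sim$genome)[[1]], "")[[1]]
truth <- sim$truth$loci
cat(sprintf("genome: %d nt, %.1f%% AT\n", length(g),
            100 * mean(g %in% c("A", "T"))))
cat(sprintf("planted: %d miRNA loci (%d moR, %d readthrough), %d decoys, %d repeat loci\n",
            sum(truth$class == "mirna"), sum(truth$mor),
            sum(truth$readthrough), sum(truth$class == "decoy"),
            sum(sim$features$ftype == "DIRS1")))
for (cond in names(sim$reads))
  cat(sprintf("library %-6s: %6d reads\n", cond, nrow(sim$reads[[cond]])))
cat(sprintf("tailed 3'-intermediate reads: %d (%d oligo(A)-tailed)\n",
            nrow(sim$tailed), sum(attr(sim$tailed, "truth") > 0)))
cat("wrote results/sim/ (FASTA, GFF3, TSV alignments, bedGraph, truth JSON)\n")
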