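#!/usr/bin/env Rscript

# Generates one synthetic genome under the default study conditions (one
# 45 kb prophage, GC -0.015, co-oriented longer genes, att repeats + tRNA,
# one moron cassette) plus a null genome, writes both as FASTA/GFF3/truth
# JSON, and re-measures the planted structure from the emitted files.

suppressMessages(library(prophagemine))
dir.create("results", showWarnings = FALSE)

cfg <- generator_config(seed = 42)
sim <- generate_genome(cfg)
paths <- write_synthetic(sim, "results/synthetic")
cat("wrote", paste(basename(paths), collapse = ", "), "to results/synthetic\n")

pp <- sim$truth$prophages
seqs <- sim$ann$sequence
gin <- gc_content(substring(seqs, pp$low, pp$high))
gout <- gc_content(paste0(substring(seqs, 1, pp$low - 1),
                          substring(seqs, pp$high + 1, nchar(seqs))))
g <- sim$ann$genes
inp <- g$low >= pp$low & g$high <= pp$high
cat(sprintf("planted prophage: %d-%d (%d bp)\n", pp$low, pp$high,
            pp$high - pp$low + 1))
cat(sprintf("GC inside %.4f / outside %.4f (delta %.4f, configured %.3f)\n",
            gin, gout, gin - gout, cfg$prophage_gc_delta))
cat(sprintf("genes inside: %d (%.0f%% co-oriented), median %.0f aa vs %.0f aa outside\n",
            sum(inp), 100 * max(table(g$strand[inp])) / sum(inp),
            median(g$aa_len[inp]), median(g$aa_len[!inp])))
cat(sprintf("att repeat %s at %d and %d; tRNA at %d-%d\n",
            sim$truth$att$repeat_seq, sim$truth$att$left_pos,
            sim$truth$att$right_pos, sim$truth$trna$low, sim$truth$trna$high))
cat(sprintf("moron cassette on %s (%d-%d, %s strand)\n",
            sim$truth$morons$gene_id, sim$truth$morons$low,
            sim$truth$morons$high, sim$truth$morons$strand))

null <- null_genome(generator_config(seed = 43))
cat(sprintf("\nnull genome: GC %.4f (host_gc %.2f), %d genes, no planted truth\n",
            gc_content(null$ann$sequence), cfg$host_gc,
            nrow(null$ann$genes)))
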