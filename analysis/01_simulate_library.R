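#!/usr/bin/env Rscript
# Stage 1: simulate the sequencing arm of the study.
# Draws an unbiased N30 library, partitions it into droplet and supernatant
# pools with a recruitment model that plants the observed signatures
# (terminal-G preference, long-A preference), and writes both pools as
# adapter-flanked FASTQ with polyG artifacts.

suppressPackageStartupMessages(library(coacervgeno))

outdir <- "results/sequencing"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
seed <- 20260901

adapter5 <- "ACACGACGCTCTTCCGATCT"
adapter3 <- "AGATCGGAAGAGCACACGTC"

lib <- generate_library(uniform_profile(30), n = 50000, seed = seed)
model <- recruitment_model(intercept = -4, coef_terminal_g = 1,
                           coef_longest_a = 1, coef_structure = -0.5)
pools <- recruit(lib, model, seed = seed + 1)

emit_fastq(pools$droplet, adapter5, adapter3, polyg_tail_prob = 0.1,
           seed = seed + 2, path = file.path(outdir, "droplet.fastq"))
emit_fastq(pools$supernatant, adapter5, adapter3, polyg_tail_prob = 0.1,
           seed = seed + 3, path = file.path(outdir, "supernatant.fastq"))

cat(sprintf("library: %d unbiased 30-mers\n", length(lib)))
cat(sprintf("droplet pool: %d reads (%.1f%%), supernatant: %d reads\n",
            length(pools$droplet), 100 * length(pools$droplet) / length(lib),
            length(pools$supernatant)))
cat("FASTQ written to", outdir, "\n")
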