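#!/usr/bin/env Rscript
# Build the synthetic paired WT/AAG reporter library that stands in for the
# designed oligo pool: 200 uORFs with Kozak-, position- and length-driven
# activities, plus per-uORF NMD fractions. Writes the design tables, sequences
# and ground truth under results/.

suppressPackageStartupMessages(library(uorfquant))

seed <- 2026L
dir.create("results", showWarnings = FALSE)

spec <- library_spec(n_uorfs = 200, noise_sd = 0.1, seed = seed)
gen <- generate_reporter_library(spec)

write_tsv(gen$library, "results/library_design.tsv")
write_tsv(gen$truth, "results/ground_truth.tsv")
write_tsv(gen$features, "results/uorf_features_planted.tsv")
write_fasta(setNames(gen$library$leader_seq, gen$library$construct_id),
            "results/library_leaders.fa")

eff <- gen$truth$true_effect_log2[gen$truth$variant == "WT"]
cat(sprintf("library: %d constructs (%d WT/AAG pairs)\n",
            nrow(gen$library), spec$n_uorfs))
cat(sprintf("planted effects: median %.2f log2 (%.1f-fold), %d repressors, %d enhancers\n",
            median(eff), 2^abs(median(eff)), sum(eff < 0), sum(eff > 0)))
cat(sprintf("planted NMD fraction: median %.2f\n",
            median(gen$truth$true_nmd_fraction)))
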