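#!/usr/bin/env Rscript
# Simulate three FACS-uORF replicates (9 bins, 1e6 reads each, log-normal sort
# noise) in wildtype and upf1-delta strains, run the full sort-seq estimator,
# and compare recovered uORF effects against the planted truth.

suppressPackageStartupMessages(library(uorfquant))

seed <- 2026L
gen <- generate_reporter_library(library_spec(n_uorfs = 200, noise_sd = 0.1,
                                              seed = seed))
ids <- unique(gen$library$pair_id)
pairs <- data.frame(uorf_id = ids, wt_id = paste0(ids, "_WT"),
                    aag_id = paste0(ids, "_AAG"))

run_strain <- function(strain, off) {
  reps <- lapply(1:3, function(r) {
    f <- simulate_facs_counts(gen$library, gen$truth, depth = 1e6,
                              strain = strain, seed = off + r)
    f$rna_counts <- simulate_rna_counts(gen$library, gen$truth, strain = strain,
                                        depth = 1e6, seed = off + 10 + r)
    f
  })
  facs_quant(reps, pairs, seed = off)
}

wt <- run_strain("wildtype", 100)
up <- run_strain("upf1_delta", 500)

write_tsv(wt$effects, "results/facs_effects_wildtype.tsv")
write_tsv(up$effects, "results/facs_effects_upf1.tsv")

truth <- gen$truth$true_effect_log2[match(pairs$wt_id, gen$truth$construct_id)]
err <- wt$effects$effect_log2 - truth
cat(sprintf("retained constructs: %d / %d\n", sum(wt$retained), 2 * length(ids)))
cat(sprintf("wildtype effects: median %.2f log2; median |error| vs truth %.3f\n",
            median(wt$effects$effect_log2, na.rm = TRUE),
            median(abs(err), na.rm = TRUE)))
cat(sprintf("significant calls: %d repressors, %d enhancers (FDR < 0.05, 3 replicates)\n",
            sum(wt$effects$direction == "repressor", na.rm = TRUE),
            sum(wt$effects$direction == "enhancer", na.rm = TRUE)))
cat(sprintf("RNA effect captures the NMD component: cor with planted = %.2f\n",
            cor(wt$effects$rna_effect_log2,
                (gen$truth$true_effect_log2 *
                   gen$truth$true_nmd_fraction)[match(pairs$wt_id,
                                                      gen$truth$construct_id)],
                use = "complete.obs")))
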