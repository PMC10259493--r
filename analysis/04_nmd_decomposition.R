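#!/usr/bin/env Rscript
# Decompose each significant repressor's effect into translational and NMD
# components from the paired wildtype / upf1-delta runs, then summarize %NMD
# over stop-codon context, uORF length, and stop-to-cap distance.

suppressPackageStartupMessages(library(uorfquant))

wt <- read_tsv("results/facs_effects_wildtype.tsv")
up <- read_tsv("results/facs_effects_upf1.tsv")
feats <- read_tsv("results/uorf_features_planted.tsv")
lib <- read_tsv("results/library_design.tsv")
truth <- read_tsv("results/ground_truth.tsv")

dec <- nmd_decompose(wt$effect_log2, up$effect_log2, wt$uorf_id)
dec$pct_nmd[!(wt$direction %in% "repressor")] <- NA  # repressors only
write_tsv(dec, "results/nmd_decomposition.tsv")

planted <- 100 * truth$true_nmd_fraction[match(paste0(wt$uorf_id, "_WT"),
                                               truth$construct_id)]
cat(sprintf("significant repressors decomposed: %d\n", sum(!is.na(dec$pct_nmd))))
cat(sprintf("median %%NMD: %.1f (planted median %.1f); median |error| %.1f points\n",
            median(dec$pct_nmd, na.rm = TRUE), median(planted),
            median(abs(dec$pct_nmd - planted), na.rm = TRUE)))

fi <- match(dec$uorf_id, feats$uorf_id)
ctx <- summarize_by_stop_context(dec$pct_nmd, feats$stop_codon[fi],
                                 feats$stop_plus1[fi])
write_tsv(ctx$stop_summary, "results/nmd_by_stop_codon.tsv")
write_tsv(ctx$stopnt_summary, "results/nmd_by_stop_context.tsv")
cat("median %NMD by stop codon:\n"); print(ctx$stop_summary)
cat(sprintf("Kruskal-Wallis across stop codons: p = %.3g\n", ctx$kw_stop_p))

len <- summarize_by_length(dec$pct_nmd, feats$length_aa[fi])
cat(sprintf("short (<= 12 aa) vs long uORFs: medians %.1f vs %.1f (WRT p = %.3g)\n",
            len$short_median, len$long_median, len$p))

wtlib <- lib[lib$variant == "WT", ]
li <- match(dec$uorf_id, wtlib$pair_id)
stop_cap <- wtlib$uorf_end[li]
m <- stop_cap_distance_model(dec$pct_nmd[!is.na(dec$pct_nmd)],
                             stop_cap[!is.na(dec$pct_nmd)])
cat(sprintf("%%NMD ~ stop-to-cap distance: slope %.3f, R2 %.3f, p %.3g\n",
            m$slope, m$r2, m$p))
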