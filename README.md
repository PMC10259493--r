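# uorfquant

Upstream open reading frames (uORFs) are short coding sequences in transcript
leaders (5' UTRs) that tune the expression of the downstream gene, mostly by
repressing translation and by triggering nonsense-mediated decay (NMD) of the
mRNA. `uorfquant` is an R package plus analysis workflow for quantifying uORF
regulatory activity from two massively parallel reporter assays in yeast:

* **FACS-uORF (sort-seq)** — cells carrying a library of paired wildtype /
  start-codon-mutant (WT/AAG) reporter leaders are sorted into nine bins by
  their YFP/mCherry ratio and the plasmids in each bin are sequenced. The
  package estimates per-construct expression, calls per-uORF effects, and —
  with a matched run in an NMD-deficient *upf1Δ* strain — decomposes each
  effect into translational and NMD components.
* **PoLib-seq (polysome profiling)** — the same library read out by sequencing
  sucrose-gradient fractions, quantifying each uORF's effect on ribosome
  loading.

It is aimed at people analysing sort-seq / MPRA count data or studying uORF
and NMD biology, and at anyone who wants a fully simulatable testbed for such
pipelines: a synthetic-library module generates reporter libraries with
planted ground truth (effect sizes, NMD fractions, sequence features) and
simulates the binned sequencing counts, so every estimator can be validated
end to end without any external data.

## The estimators

**Expression from binned counts.** With bin fluorescence values calibrated to
the brightest bin (`YFP_max = 1`) and bin read counts downsampled to the
proportions of cells sorted per bin, a construct's expression is the
read-weighted mean

```
YFP/mCherry = sum_b( YFP_b * n_b ) / sum_b( n_b )        (sorted bins only)
```

RNA levels are `RNA-rpm / DNA-rpm` against the unsorted plasmid pool.
Constructs with across-replicate SD > 0.05 or < 50 normalized reads are
dropped. Per-uORF effects are `log2(YFP_WT / YFP_AAG)`, tested per replicate
by Wilcoxon rank-sum on read-level bin values with Benjamini–Hochberg
correction; a uORF is a significant repressor/enhancer only if FDR < 0.05 in
every replicate with a consistent sign.

**NMD decomposition.** With effects measured in both strains,

```
NMD_uORF = WT_uORF - upf1Δ_uORF ,     %NMD = 100 * NMD_uORF / WT_uORF
```

so the total log2 effect splits additively into a translational component
(what remains in *upf1Δ*) and an NMD component.

**Ribosome loading.** Gradient fractions are pooled into translating
(2/3/4/5+ ribosomes) and non-translating (40S/60S/monosome) groups; a uORF's
loading effect is `log2[(T/U)_WT / (T/U)_AAG]`, tested by a
Cochran–Mantel–Haenszel test over replicate strata (5000-read pair cutoff).

**Feature modeling.** Fifteen sequence/position features per uORF (Kozak
context score, cap and CDS distances, length, unfolding energy around the
start codon, %AU after the stop, CAI, peptide pI and Pro/Gly frequency, stop
codon identity and +1 context, start/stop conservation, oORF flag) enter an
elastic-net regression minimizing

```
(1/2n)||y - Xw||^2 + lambda1*||w||_1 + lambda2*||w||^2,
lambda1 = alpha*l1_ratio,  lambda2 = 0.5*alpha*(1 - l1_ratio)
```

over 100 random 80/20 splits with min-max scaling, against a Kozak-only
single-feature baseline.

## Worked example

```r
library(uorfquant)

spec <- library_spec(n_uorfs = 40, noise_sd = 0.1, seed = 7)
gen  <- generate_reporter_library(spec)
ids  <- unique(gen$library$pair_id)
pairs <- data.frame(uorf_id = ids, wt_id = paste0(ids, "_WT"),
                    aag_id = paste0(ids, "_AAG"))
reps <- lapply(1:3, function(r)
  simulate_facs_counts(gen$library, gen$truth, depth = 1e6, seed = 100 + r))
res <- facs_quant(reps, pairs, seed = 1)
head(res$effects[, c("uorf_id", "effect_log2", "direction")], 4)
#>              uorf_id effect_log2 direction
#> uorf0001_WT uorf0001  -0.8835100 repressor
#> uorf0002_WT uorf0002  -1.3550904 repressor
#> uorf0003_WT uorf0003  -1.3527897 repressor
#> uorf0004_WT uorf0004  -0.7955469 repressor
```

Each row is one WT/AAG pair: `effect_log2` is the mean log2 expression change
caused by the intact uORF (−1.36 ≈ 2.6-fold repression) and `direction` the
significance call. Against the planted truth these estimates have a median
absolute error of 0.015 log2 units. The NMD split is plain arithmetic:

```r
nmd_decompose(-2.0, -1.3)
#> NMD component -0.7, %NMD 35.0
```

i.e. a uORF that represses 4-fold in wildtype but 2.5-fold without NMD owes
35% of its (log-scale) repression to decay.

The `analysis/` directory holds the numbered workflow
(`01_simulate_library.R` … `06_comparative.R`) that runs the full study on a
200-uORF synthetic library and writes its tables under `results/`.

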