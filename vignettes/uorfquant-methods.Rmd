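---
title: "Quantifying uORF regulation from binned reporter assays: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying uORF regulation from binned reporter assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uorfquant)
```

# The measurement model

FACS-uORF is a sort-seq assay: each cell carries one reporter construct, the
sorter assigns cells to bins by their YFP/mCherry ratio, and sequencing of the
per-bin plasmid pools yields, for every construct, a read distribution over
bins. Three normalizations precede estimation.

1. **Bin calibration.** The plate-reader (TECAN) mean fluorescence of each
   sorted bin is divided by the maximum, so the brightest bin has value 1 and
   all expression estimates live on a common normalized scale
   (`calibrate_bins()`).
2. **Cell-proportion downsampling.** Sequencing depth per bin is arbitrary, so
   bin totals are downsampled to be proportional to the number of cells sorted
   into each bin (`downsample_to_cell_proportions()`). We never upsample: the
   common total is the largest achievable, `floor(min_b reads_b / prop_b)`,
   and reads within a bin are removed by multivariate-hypergeometric
   subsampling so construct composition is preserved in expectation.
3. **rpm normalization** for read-support filtering and for RNA levels
   (`RNA-rpm / DNA-rpm` against the unsorted pool, `bin0`).

A construct's expression is then the read-weighted mean of the calibrated bin
values over the sorted bins. This estimator is exact for point distributions
and, because sorting noise spreads each construct's cells over neighbouring
bins, it interpolates between bin values in practice; its accuracy is bounded
by gate width at the extremes of the dynamic range (see *Limitations*).

**Effect calls.** The unit of uORF activity is `log2(YFP_WT / YFP_AAG)` for a
wildtype leader and its start-codon mutant. The only within-replicate sampling
unit is the read, so the per-replicate test compares the WT and AAG read-level
bin-value samples with a Wilcoxon rank-sum test (normal approximation with tie
and continuity corrections, computed directly from per-bin counts; bins
sharing a calibrated value are merged so ties are handled exactly once).
Benjamini–Hochberg adjustment is applied within each replicate across uORFs,
and a call requires FDR < 0.05 in **every** replicate with a consistent sign —
the conservative reading of "significant and consistent". Applying BH within
replicate (rather than pooled) follows the order of operations in the assay's
description; with three replicates required to agree, the distinction is
second-order.

**Noise filter.** Constructs with across-replicate expression SD > 0.05 (on
the [0, 1] normalized scale) or with fewer than 50 rpm-normalized reads in any
replicate are excluded before testing. Both thresholds are exposed as
arguments.

# NMD decomposition

Total repression in wildtype cells confounds translational inhibition with
NMD-mediated mRNA destruction. Measuring the same library in an NMD-null
(*upf1Δ*) strain isolates the translational component, and the decomposition
is additive in log space:

`NMD = WT − upf1Δ`, `%NMD = 100 · NMD / WT`, computed only for significant
repressors (the quantity is meaningless for enhancers and explodes as the
total effect approaches zero). Estimation noise can push %NMD outside
[0, 100]; we clamp and flag such values rather than dropping them, preserving
sample size while keeping anomalies auditable (`pct_nmd_raw` retains the
unclamped value).

# Ribosome loading (PoLib-seq)

Gradient fractions are pooled into *translating* (2, 3, 4, 5+ ribosomes) and
*non-translating* (40S, 60S, monosome); the top-of-gradient fraction is never
used. The loading effect is the log2 fold change of the translated/untranslated
ratio (WT vs AAG), with replicates **summed** for the point estimate but kept
as strata for the Cochran–Mantel–Haenszel significance test — pooling for the
estimate stabilizes small fractions, while stratification preserves the
per-replicate pairing for inference. Fraction rescaling (e.g. a monosome
fraction scaled by 0.8626 to equalize translating proportions across
replicates) is deterministic multiply-and-round rather than random
subsampling: reproducible, and only ratios matter downstream. The 5000-read
cutoff is applied to the WT+AAG pair jointly, summed over replicates and used
fractions, with an inclusive boundary.

The hand-rolled CMH statistic floors the continuity correction at zero
(`max(0, |Σ(a−E)| − 0.5)² / ΣV`), so strata with identical proportions give
p = 1 exactly; `stats::mantelhaen.test` agrees whenever the correction does
not floor and serves as the independent cross-check in the tests.

# Feature extraction

The fifteen modeling features realize the named categories — initiation
context, position, RNA structure, codon usage, peptide properties, stop
context, conservation — under these conventions:

* **Kozak score** is an exact lookup of the −4..−1 context, start codon and +1
  base in a measured context table (U/T spelling normalized); missing contexts
  are missing values, not imputations.
* **Positions** are 0-based half-open from the first transcribed nucleotide;
  `dist_stop_cds` is negative for oORFs.
* **ΔΔG of unfolding**: for each of n sampled structures, every base pair with
  an endpoint in the `[start−15, start+15)` window is deleted and the
  structure re-scored; ΔΔG = ΔG(opened) − ΔG(folded) ≥ 0, the cost of making
  the start codon accessible. The sign convention (positive = cost) is ours.
  The engine is pluggable: a ViennaRNA adapter (`vienna_fold_engine()`,
  RNAsubopt/RNAeval) for thermodynamic energies, and a deterministic
  maximum-pairing engine (`toy_fold_engine()`: Nussinov DP, minimum loop 3,
  −1 kcal/pair, "sampling" = all co-optimal structures up to n) that the test
  suite validates against brute-force enumeration of maximal non-crossing
  pairings.
* **%AU** uses the 9 nt immediately after the stop codon (the +2..+10 window
  counting the stop's last base as +1); the alternative reading (+2 from the
  stop's first base) would overlap the stop itself, so we reject it.
* **CAI** is the geometric mean of relative-adaptiveness weights (stop
  excluded). The weight table is an argument; the analysis drivers default to
  a seeded synthetic table, and `seqinr::caitab$sc` is the natural choice for
  real *S. cerevisiae* data.
* **pI** is the bisection root of the Henderson–Hasselbalch net charge with
  EMBOSS-style pKa values (termini always ionizable), to 10⁻³ pH.
* **Conservation** is the mean PhastCons score over the three codon bases;
  constructs from a species without a track receive the dataset-wide mean.
* The stop codon enters as two dummies (UAA baseline) and the +1 base as a
  single A/U-vs-G/C indicator — the minimal encoding that keeps the matrix at
  fifteen columns.

# Elastic-net protocol

The objective is `(1/2n)||y − Xw||² + λ₁||w||₁ + λ₂||w||²` with
`λ₁ = αℓ`, `λ₂ = 0.5α(1−ℓ)`, solved by cyclic coordinate descent with an
unpenalized intercept (tolerance 10⁻⁹ on the objective decrease; the
soft-threshold closed form on orthonormal designs and glmnet under the
equivalent parameterization are both test oracles). Each of 100 trials draws a
fresh 80/20 split, min-max scales on the training data only (test values may
scale outside [0, 1]; no clipping), fits, and scores held-out R²; an ordinary
single-feature regression on the Kozak score over the same split is the
baseline. Defaults α = 0.01, ℓ = 0.5 were fixed a priori as a mild penalty;
`enr_grid_search()` exists because hand-tuning is not reproducible. Per-feature
significance across trials (one-sample signed-rank of trial weights against
zero, BH-adjusted) is this package's construction and is labelled as such.

# The synthetic-data generator

The generator is the package's study design, not a tuning knob. Defaults:
200 uORF pairs; leaders 80–180 nt (the oligo-synthesis cap); 15% near-cognate
start codons; planted activity weights on Kozak score (−1.5), cap distance
(+0.8) and length (−0.3) over design-scaled features, intercept −0.2, Gaussian
noise 0.1 log2 — giving a mostly-repressive library with a median near 2.3-fold
repression; NMD fractions Beta(1.4, 2.6) (median ≈ ⅓ of repression via decay);
AAG baseline expression uniform on [0.75, 1.1] of the normalized scale.
Sorting noise is log-normal with σ = 0.15 (FACS ratio noise is
multiplicative); gates default to population quantiles, which is how operators
set them. NMD acts on RNA abundance, translation acts on bin placement given
RNA, and protein expression is their product — the same decoupling the
paired-strain design exploits. Backgrounds are scrubbed of accidental AUGs (a
G→C edit that can create neither AUG nor stop codons) so annotations stay
unambiguous.

What the simulator does **not** emulate: PCR jackpotting and UMI-less
duplication, oligo synthesis errors, base-call errors (counts are multinomial
at the stated depth), cross-contamination between bins, day effects between
replicates, and any correlation structure among features beyond what the
sequence construction induces. Passing recovery tests therefore demonstrate
estimator correctness under the assay's sampling model, not robustness to
every laboratory artifact.

Problem sizes in the tests and acceptance script — 200 pairs at 10⁶ reads ×
3 replicates, 500 × 15 feature matrices, 100 trials — match the scale at which
the recovery properties are stated and run in seconds.

# Numerical choices and degenerate inputs

* Exact two-sided tests use the point-probability convention throughout,
  matching base R.
* The rank-sum test is exact (enumeration) for combined n ≤ 20 without ties,
  otherwise normal approximation with tie and continuity corrections; the
  grouped-count variant merges bins with equal values before ranking.
* Degenerate inputs resolve to the uninformative answer rather than errors
  where a scan must continue: all-tied samples give p = 1, zero-margin CMH
  strata are dropped with a warning, zero-read constructs give missing
  expression, constant responses give R² = 0.
* The two-fold classification in the TSS analysis is on mean log2 activities,
  inclusive at |Δ| = 1 (with a 10⁻⁹ float guard).
* Conservation grouping uses strict `PCS > 0.5`; ties at the threshold are
  non-conserved by the stated inequality.
* Downsampling, library generation and all simulators take explicit integer
  seeds and are byte-reproducible.

# Limitations

The weighted-mean estimator is bounded by the calibrated bin-value range, so
constructs at the edges of the dynamic range are biased toward the interior;
with 9 bins this compresses extreme effects (the tests quantify accuracy on a
fine gate grid separately from effect-level recovery on the 9-bin default).
%NMD is a ratio of noisy estimates and is only stable for clear repressors.
The maximum-pairing folding engine is a combinatorial stand-in with a single
energy rule — use the ViennaRNA adapter for thermodynamically meaningful ΔΔG.
The mutation-artifact audit mechanizes three stated patterns (U·AUG→UAA,
AUGNAUG, nested non-AUG) and nothing else; it is a flagging aid, not a
classifier.
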