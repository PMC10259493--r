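#' FACS-uORF quantification
#'
#' From binned sort-seq counts to per-construct expression estimates and
#' per-uORF effect calls: reads-per-million normalization, TECAN bin
#' calibration (highest bin = 1), downsampling of bin read totals to
#' sorted-cell proportions, read-weighted mean YFP/mCherry per construct,
#' RNA level as RNA-rpm/DNA-rpm, replicate-noise filtering, and paired WT/AAG
#' effect calls by per-replicate Wilcoxon rank-sum tests with
#' Benjamini-Hochberg correction.
#'
#' @name facs_quant
NULL

#' Reads-per-million normalization
#'
#' @param counts Non-negative count vector with positive total.
#' @return counts * 1e6 / sum(counts).
#' @export
normalize_rpm <- function(counts) {
  total <- sum(counts)
  if (total <= 0) stop("cannot rpm-normalize an all-zero sample")
  counts * 1e6 / total
}

#' Relative RNA level
#'
#' @param rna_rpm,dna_rpm rpm vectors over constructs.
#' @return RNA-rpm / DNA-rpm; constructs with zero DNA representation are NA.
#' @export
rna_level <- function(rna_rpm, dna_rpm) {
  out <- rna_rpm / dna_rpm
  out[dna_rpm <= 0] <- NA_real_
  out
}

#' Calibrate per-bin fluorescence to the highest bin
#'
#' @param tecan_readings Per-bin mean YFP/mCherry readings (>= 2 bins).
#' @return Readings divided by their maximum (top bin = 1).
#' @export
calibrate_bins <- function(tecan_readings) {
  stopifnot(length(tecan_readings) >= 2)
  m <- max(tecan_readings)
  if (!is.finite(m) || m <= 0) stop("non-positive maximum TECAN reading")
  tecan_readings / m
}

# draw a multivariate hypergeometric sample: keep `k` of the reads in `counts`
mvhyper_keep <- function(counts, k) {
  kept <- integer(length(counts))
  pool <- sum(counts)
  remaining <- k
  for (i in seq_along(counts)) {
    if (remaining == 0) break
    pool <- pool - counts[i]
    kept[i] <- stats::rhyper(1, counts[i], pool, remaining)
    remaining <- remaining - kept[i]
  }
  kept
}

#' Downsample bin counts to sorted-cell proportions
#'
#' Per-bin column totals after downsampling are proportional to the cells
#' sorted into each bin; no bin is upsampled (the common total is the largest
#' achievable, `floor(min_b reads_b / prop_b)`). Within each bin, reads are
#' removed by multivariate-hypergeometric subsampling across constructs.
#'
#' @param bin_counts construct x sorted-bin count matrix (no bin0 column).
#' @param cells_sorted Cells per bin (positive where bins are non-empty).
#' @param seed Integer seed.
#' @return Downsampled count matrix of the same shape.
#' @export
downsample_to_cell_proportions <- function(bin_counts, cells_sorted, seed = 1L) {
  stopifnot(ncol(bin_counts) == length(cells_sorted), all(cells_sorted >= 0))
  set.seed(seed)
  prop <- cells_sorted / sum(cells_sorted)
  totals <- colSums(bin_counts)
  active <- prop > 0
  if (any(totals[active] == 0)) {
    warning("bin with sorted cells but zero reads; downsampling target is 0")
  }
  target_total <- floor(min(totals[active] / prop[active]))
  out <- bin_counts
  out[, !active] <- 0L
  for (b in which(active)) {
    tb <- floor(target_total * prop[b])
    if (tb >= totals[b]) next
    out[, b] <- mvhyper_keep(bin_counts[, b], tb)
  }
  out
}

#' Read-weighted mean expression of one construct
#'
#' @param bin_counts_row Reads per sorted bin (bin0 excluded).
#' @param bin_yfp Calibrated per-bin YFP/mCherry values.
#' @return sum(yfp_b * n_b) / sum(n_b); NA when the construct has no sorted
#'   reads.
#' @export
weighted_expression <- function(bin_counts_row, bin_yfp) {
  stopifnot(length(bin_counts_row) == length(bin_yfp))
  n <- sum(bin_counts_row)
  if (n == 0) return(NA_real_)
  sum(bin_yfp * bin_counts_row) / n
}

#' Filter constructs with noisy or weakly supported estimates
#'
#' @param yfp Matrix construct x replicate of expression estimates.
#' @param reads Matrix construct x replicate of normalized read support.
#' @param sd_max Largest allowed across-replicate SD of yfp.
#' @param min_reads Minimum normalized reads in every replicate.
#' @return Logical retention vector (named by rownames of `yfp`).
#' @export
filter_noisy <- function(yfp, reads, sd_max = 0.05, min_reads = 50) {
  stopifnot(ncol(yfp) >= 2, all(dim(yfp) == dim(reads)))
  sds <- apply(yfp, 1, stats::sd)
  keep <- !is.na(sds) & sds <= sd_max &
    apply(reads, 1, function(r) all(!is.na(r) & r >= min_reads)) &
    apply(yfp, 1, function(v) all(!is.na(v)))
  stats::setNames(keep, rownames(yfp))
}

# rank-sum p for one pair in one replicate, from per-bin read counts; bins
# sharing a calibrated yfp value are merged so ties are handled exactly once
pair_wrt_p <- function(wt_counts, aag_counts, bin_yfp) {
  o <- order(bin_yfp)
  wt <- wt_counts[o]; aag <- aag_counts[o]; v <- bin_yfp[o]
  grp <- cumsum(c(TRUE, diff(v) > 0))
  wt <- tapply(wt, grp, sum); aag <- tapply(aag, grp, sum)
  if (sum(wt) == 0 || sum(aag) == 0) return(NA_real_)
  wilcoxon_rank_sum_counts(wt, aag)
}

#' Per-uORF effect calls from paired WT/AAG estimates
#'
#' Per replicate, a Wilcoxon rank-sum test compares the WT and AAG read-level
#' YFP samples (each downsampled read contributes its bin's calibrated YFP
#' value); Benjamini-Hochberg adjustment is applied within each replicate
#' across uORFs. A uORF is significant iff FDR < `fdr_max` in every replicate
#' with a consistent effect sign. The effect size is the across-replicate mean
#' of log2(yfp_WT / yfp_AAG); the RNA effect is analogous on RNA levels.
#'
#' @param estimates list with matrices `yfp` (construct x replicate) and
#'   optionally `rna` (construct x replicate RNA levels).
#' @param bin_counts list of downsampled construct x sorted-bin matrices, one
#'   per replicate.
#' @param bin_yfp list (or matrix) of calibrated bin values per replicate.
#' @param pairs data.frame(uorf_id, wt_id, aag_id).
#' @param retained Logical retention vector from [filter_noisy()].
#' @param fdr_max FDR threshold.
#' @return data.frame: uorf_id, effect_log2, rna_effect_log2, per-replicate
#'   p/fdr columns, significant, direction (repressor/enhancer/ns), testable.
#' @export
compute_uorf_effects <- function(estimates, bin_counts, bin_yfp, pairs,
                                 retained, fdr_max = 0.05) {
  n_rep <- length(bin_counts)
  if (is.matrix(bin_yfp)) bin_yfp <- asplit(bin_yfp, 2)
  testable <- retained[pairs$wt_id] & retained[pairs$aag_id]
  testable[is.na(testable)] <- FALSE

  p <- matrix(NA_real_, nrow(pairs), n_rep)
  eff_rep <- matrix(NA_real_, nrow(pairs), n_rep)
  for (r in seq_len(n_rep)) {
    bc <- bin_counts[[r]]
    by <- bin_yfp[[r]]
    for (i in which(testable)) {
      p[i, r] <- pair_wrt_p(bc[pairs$wt_id[i], ], bc[pairs$aag_id[i], ], by)
    }
    eff_rep[, r] <- log2(estimates$yfp[pairs$wt_id, r] /
                         estimates$yfp[pairs$aag_id, r])
  }
  fdr <- apply(p, 2, bh_adjust)
  if (is.null(dim(fdr))) fdr <- matrix(fdr, ncol = n_rep)
  sig <- testable &
    apply(fdr, 1, function(q) all(!is.na(q) & q < fdr_max)) &
    apply(eff_rep, 1, function(e) all(!is.na(e)) && length(unique(sign(e))) == 1 &&
            all(e != 0))
  effect <- rowMeans(eff_rep)
  effect[!testable] <- NA_real_
  rna_effect <- rep(NA_real_, nrow(pairs))
  if (!is.null(estimates$rna)) {
    rna_effect <- rowMeans(log2(estimates$rna[pairs$wt_id, , drop = FALSE] /
                                estimates$rna[pairs$aag_id, , drop = FALSE]))
    rna_effect[!testable] <- NA_real_
  }
  direction <- ifelse(!testable, NA_character_,
                      ifelse(sig & effect < 0, "repressor",
                             ifelse(sig & effect > 0, "enhancer", "ns")))
  out <- data.frame(uorf_id = pairs$uorf_id, effect_log2 = effect,
                    rna_effect_log2 = rna_effect, significant = sig,
                    direction = direction, testable = testable,
                    stringsAsFactors = FALSE)
  colnames(p) <- paste0("p_rep", seq_len(n_rep))
  colnames(fdr) <- paste0("fdr_rep", seq_len(n_rep))
  colnames(eff_rep) <- paste0("effect_rep", seq_len(n_rep))
  cbind(out, p, fdr, eff_rep)
}

#' Run the full FACS-uORF pipeline on replicate count data
#'
#' Applies, per replicate: TECAN calibration, downsampling to sorted-cell
#' proportions, read-weighted expression, rpm-based read support and RNA
#' levels; then the across-replicate noise filter and paired effect calls.
#'
#' @param replicates list of per-replicate lists with elements `bin_counts`
#'   (construct x bin matrix whose first column is the unsorted pool "bin0"),
#'   `bin_means` (raw TECAN readings for the sorted bins), `cells_sorted`, and
#'   optionally `rna_counts`.
#' @param pairs data.frame(uorf_id, wt_id, aag_id).
#' @param sd_max,min_reads Noise-filter settings (see [filter_noisy()]).
#' @param fdr_max FDR threshold for effect calls.
#' @param seed Integer seed (drives the downsampling draws).
#' @return list(estimates, retained, effects)
#' @export
facs_quant <- function(replicates, pairs, sd_max = 0.05, min_reads = 50,
                       fdr_max = 0.05, seed = 1L) {
  n_rep <- length(replicates)
  stopifnot(n_rep >= 2)
  nc <- nrow(replicates[[1]]$bin_counts)
  ids <- rownames(replicates[[1]]$bin_counts)
  yfp <- reads <- rna <- matrix(NA_real_, nc, n_rep, dimnames = list(ids, NULL))
  down <- vector("list", n_rep)
  byfp <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    rep_r <- replicates[[r]]
    sorted <- rep_r$bin_counts[, -1, drop = FALSE]
    byfp[[r]] <- calibrate_bins(rep_r$bin_means)
    down[[r]] <- downsample_to_cell_proportions(sorted, rep_r$cells_sorted,
                                                seed = seed + r)
    yfp[, r] <- apply(down[[r]], 1, weighted_expression, bin_yfp = byfp[[r]])
    reads[, r] <- normalize_rpm(rowSums(down[[r]])) # rpm read support
    if (!is.null(rep_r$rna_counts)) {
      rna[, r] <- rna_level(normalize_rpm(rep_r$rna_counts),
                            normalize_rpm(rep_r$bin_counts[, 1]))
    }
  }
  has_rna <- !all(is.na(rna))
  estimates <- list(yfp = yfp, reads = reads, rna = if (has_rna) rna else NULL)
  retained <- filter_noisy(yfp, reads, sd_max = sd_max, min_reads = min_reads)
  effects <- compute_uorf_effects(estimates, down, byfp, pairs, retained,
                                  fdr_max = fdr_max)
  list(estimates = estimates, retained = retained, effects = effects)
}
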