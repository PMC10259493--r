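#' Polysome-loading quantification (PoLib-seq)
#'
#' Pools sucrose-gradient fractions into translating (2, 3, 4, 5+ ribosomes)
#' and non-translating (40S, 60S, monosome) groups per replicate (the top
#' fraction is never used), estimates each uORF's effect on ribosome loading
#' as the log2 fold change of the translated/untranslated ratio (WT vs AAG,
#' replicates summed), and tests significance with the Cochran-Mantel-Haenszel
#' test over replicate strata with Benjamini-Hochberg correction.
#'
#' @name polib_quant
NULL

TRANSLATING_FRACTIONS <- c("2", "3", "4", "5plus")
NONTRANSLATING_FRACTIONS <- c("40S", "60S", "mono")

#' Pool gradient fractions into translating / non-translating groups
#'
#' @param counts construct x fraction x replicate array (or a single-replicate
#'   construct x fraction matrix). Fraction labels must come from
#'   {top, 40S, 60S, mono, 2, 3, 4, 5plus}; "top" is dropped.
#' @return construct x {translating, nontranslating} x replicate array.
#' @export
pool_fractions <- function(counts) {
  if (length(dim(counts)) == 2) {
    counts <- array(counts, dim = c(dim(counts), 1),
                    dimnames = c(dimnames(counts), list("rep1")))
  }
  labs <- dimnames(counts)[[2]]
  known <- c("top", TRANSLATING_FRACTIONS, NONTRANSLATING_FRACTIONS)
  if (!all(labs %in% known)) {
    stop("unknown fraction label(s): ", paste(setdiff(labs, known), collapse = ", "))
  }
  missing <- setdiff(c(TRANSLATING_FRACTIONS, NONTRANSLATING_FRACTIONS), labs)
  if (length(missing)) stop("missing fraction(s): ", paste(missing, collapse = ", "))
  out <- array(0, dim = c(dim(counts)[1], 2, dim(counts)[3]),
               dimnames = list(dimnames(counts)[[1]],
                               c("translating", "nontranslating"),
                               dimnames(counts)[[3]]))
  out[, 1, ] <- apply(counts[, TRANSLATING_FRACTIONS, , drop = FALSE], c(1, 3), sum)
  out[, 2, ] <- apply(counts[, NONTRANSLATING_FRACTIONS, , drop = FALSE], c(1, 3), sum)
  out
}

#' Deterministically rescale one fraction of one replicate
#'
#' Used to equalize translating/non-translating proportions across replicates
#' (e.g. the monosome fraction of one replicate scaled by 0.8626). Counts are
#' multiplied by the factor and rounded to the nearest integer; the resulting
#' per-replicate translating proportions are reported via a message so the
#' calibration target can be checked.
#'
#' @param counts construct x fraction x replicate array.
#' @param replicate Replicate index or name.
#' @param fraction Fraction label.
#' @param factor Scale in (0, 1].
#' @return The rescaled array.
#' @export
rescale_fraction <- function(counts, replicate, fraction, factor) {
  stopifnot(factor > 0, factor <= 1)
  counts[, fraction, replicate] <- round(counts[, fraction, replicate] * factor)
  pooled <- pool_fractions(counts)
  ptr <- apply(pooled, 3, function(m) sum(m[, "translating"]) / sum(m))
  message("translating proportion by replicate after rescaling: ",
          paste(sprintf("%.3f", ptr), collapse = ", "))
  counts
}

#' Read-support cutoff for a WT/AAG comparison
#'
#' A pair is testable iff its total reads (both members, all non-top
#' fractions, all replicates summed) reach `min_total`; the bound is
#' inclusive.
#'
#' @param pooled construct x group x replicate array from [pool_fractions()].
#' @param pairs data.frame(uorf_id, wt_id, aag_id).
#' @param min_total Read cutoff.
#' @return Logical testable flag per pair.
#' @export
apply_read_cutoff <- function(pooled, pairs, min_total = 5000) {
  per_construct <- apply(pooled, 1, sum)
  tot <- per_construct[pairs$wt_id] + per_construct[pairs$aag_id]
  stats::setNames(!is.na(tot) & tot >= min_total, pairs$uorf_id)
}

#' Ribosome-loading effect of a uORF
#'
#' @param wt,aag Length-2 vectors c(translating, nontranslating), replicates
#'   summed.
#' @return log2[(T_WT/U_WT) / (T_AAG/U_AAG)]; negative values mean the uORF
#'   represses loading. NA when any pooled count is zero.
#' @export
loading_effect <- function(wt, aag) {
  if (any(c(wt, aag) <= 0)) return(NA_real_)
  log2((wt[1] / wt[2]) / (aag[1] / aag[2]))
}

#' CMH significance for one pair across replicate strata
#'
#' @param strata list of per-replicate 2x2 tables, rows = (WT, AAG), columns =
#'   (translating, nontranslating).
#' @return Two-sided p-value (continuity-corrected CMH, chi-square 1 df).
#' @export
cmh_significance <- function(strata) {
  cmh_2x2xk(strata, correct = TRUE)
}

#' Full PoLib-seq pipeline
#'
#' @param counts construct x fraction x replicate array of reads (capped and
#'   uncapped reads already summed per construct).
#' @param pairs data.frame(uorf_id, wt_id, aag_id).
#' @param min_total Read cutoff per pair.
#' @param fdr_max FDR threshold.
#' @return data.frame: uorf_id, loading_effect_log2, p, fdr, testable,
#'   significant, direction.
#' @export
polib_quant <- function(counts, pairs, min_total = 5000, fdr_max = 0.05) {
  pooled <- pool_fractions(counts)
  testable <- apply_read_cutoff(pooled, pairs, min_total)
  n_rep <- dim(pooled)[3]
  eff <- p <- rep(NA_real_, nrow(pairs))
  consistent <- rep(NA, nrow(pairs))
  for (i in which(testable)) {
    wt <- pooled[pairs$wt_id[i], , , drop = FALSE]
    aag <- pooled[pairs$aag_id[i], , , drop = FALSE]
    eff[i] <- loading_effect(apply(wt, 2, sum), apply(aag, 2, sum))
    strata <- lapply(seq_len(n_rep), function(r)
      rbind(WT = wt[1, , r], AAG = aag[1, , r]))
    ok <- vapply(strata, function(s) all(rowSums(s) > 0) && all(s[, 2] > 0),
                 logical(1))
    dirs <- vapply(strata[ok], function(s)
      sign(s[1, 1] / s[1, 2] - s[2, 1] / s[2, 2]), numeric(1))
    consistent[i] <- length(dirs) > 0 && length(unique(dirs[dirs != 0])) <= 1 &&
      any(dirs != 0)
    p[i] <- suppressWarnings(cmh_significance(strata))
  }
  fdr <- bh_adjust(p)
  sig <- !is.na(p) & !is.na(eff) & fdr < fdr_max & consistent %in% TRUE
  direction <- ifelse(!testable | is.na(eff), NA_character_,
                      ifelse(sig & eff < 0, "repressor",
                             ifelse(sig & eff > 0, "enhancer", "ns")))
  data.frame(uorf_id = pairs$uorf_id, loading_effect_log2 = eff,
             p = p, fdr = fdr, testable = testable, significant = sig,
             direction = direction, stringsAsFactors = FALSE)
}
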