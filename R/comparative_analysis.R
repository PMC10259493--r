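#' Downstream comparative analyses
#'
#' Dependence of uORF activity on the transcription start site (alternative
#' leader isoforms), conservation-based grouping of uORF effects, ortholog
#' concordance between species, and mechanized flagging of the sequence
#' contexts in which the AUG-to-AAG mutation itself creates artifacts.
#'
#' @name comparative_analysis
NULL

#' TSS dependence of uORF activity across leader isoforms
#'
#' For each uORF measured in two alternative transcript leaders, a Welch
#' two-sample t-test compares the per-replicate log2(WT/AAG) activities, with
#' Benjamini-Hochberg adjustment across pairs. Pairs with adjusted p <=
#' `fdr_max` and at least a two-fold activity difference (|difference of mean
#' log2 activities| >= 1, boundary inclusive) are classified as more or less
#' repressive in the shorter leader; a two-sided exact binomial test asks
#' whether the two directions are balanced.
#'
#' @param act_long,act_short Matrices (pairs x replicates) of per-replicate
#'   activities in the longer and shorter leader.
#' @param uorf_id Optional identifiers.
#' @param fdr_max Adjusted-p threshold.
#' @return list(table, n_more_repressive_short, n_less_repressive_short,
#'   binom_p)
#' @export
tss_dependence <- function(act_long, act_short, uorf_id = NULL, fdr_max = 0.05) {
  act_long <- as.matrix(act_long); act_short <- as.matrix(act_short)
  stopifnot(nrow(act_long) == nrow(act_short),
            ncol(act_long) >= 2, ncol(act_short) >= 2)
  n <- nrow(act_long)
  ok <- stats::complete.cases(act_long) & stats::complete.cases(act_short)
  p <- rep(NA_real_, n)
  p[ok] <- vapply(which(ok), function(i)
    welch_t_test(act_long[i, ], act_short[i, ]), numeric(1))
  fdr <- bh_adjust(p)
  diff <- rowMeans(act_short) - rowMeans(act_long)
  twofold <- !is.na(diff) & abs(diff) >= 1 - 1e-9   # inclusive at two-fold
  sig <- !is.na(fdr) & fdr <= fdr_max
  class <- ifelse(!sig | !twofold, "ns",
                  ifelse(diff < 0, "more_repressive_short", "less_repressive_short"))
  class[!ok] <- NA_character_
  n_more <- sum(class %in% "more_repressive_short")
  n_less <- sum(class %in% "less_repressive_short")
  binom_p <- if (n_more + n_less > 0)
    binomial_exact_two_sided(n_more, n_more + n_less) else NA_real_
  list(table = data.frame(
         uorf_id = if (is.null(uorf_id)) seq_len(n) else uorf_id,
         mean_long = rowMeans(act_long), mean_short = rowMeans(act_short),
         diff_short_minus_long = diff, p = p, fdr = fdr, class = class,
         stringsAsFactors = FALSE),
       n_more_repressive_short = n_more,
       n_less_repressive_short = n_less,
       binom_p = binom_p)
}

#' Compare uORF effect magnitudes across conservation groups
#'
#' Natural uORFs are split at a PhastCons start-codon score of `threshold`
#' (strictly greater = conserved); an optional third group holds de novo
#' uORFs (NCC start codons mutated to AUG). Pairwise Wilcoxon rank-sum tests
#' compare |effect| between groups; conserved vs non-conserved contrasts of
#' cap distance and Kozak score are reported when provided.
#'
#' @param effect_log2 Effects of natural uORFs.
#' @param phastcons_start Start-codon conservation scores (same length).
#' @param de_novo_effect Optional effects of de novo AUG uORFs.
#' @param dist_cap_start,kozak_score Optional per-uORF features for the
#'   conserved vs non-conserved feature contrasts.
#' @param threshold Conservation split (strict >).
#' @return list(medians, n, p_cons_vs_noncons, p_cons_vs_denovo,
#'   p_noncons_vs_denovo, p_dist_cap, p_kozak)
#' @export
conservation_groups <- function(effect_log2, phastcons_start,
                                de_novo_effect = NULL,
                                dist_cap_start = NULL, kozak_score = NULL,
                                threshold = 0.5) {
  conserved <- phastcons_start > threshold
  g <- list(conserved = abs(effect_log2[conserved]),
            non_conserved = abs(effect_log2[!conserved]))
  if (!is.null(de_novo_effect)) g$de_novo <- abs(de_novo_effect)
  meds <- vapply(g, stats::median, numeric(1))
  pw <- function(a, b) if (length(a) && length(b)) wilcoxon_rank_sum(a, b) else NA_real_
  out <- list(medians = meds, n = lengths(g),
              p_cons_vs_noncons = pw(g$conserved, g$non_conserved),
              p_cons_vs_denovo = if (!is.null(g$de_novo))
                pw(g$conserved, g$de_novo) else NA_real_,
              p_noncons_vs_denovo = if (!is.null(g$de_novo))
                pw(g$non_conserved, g$de_novo) else NA_real_)
  out$p_dist_cap <- if (!is.null(dist_cap_start))
    pw(dist_cap_start[conserved], dist_cap_start[!conserved]) else NA_real_
  out$p_kozak <- if (!is.null(kozak_score))
    pw(kozak_score[conserved], kozak_score[!conserved]) else NA_real_
  out
}

#' Concordance of ortholog uORF effects between species
#'
#' Pairs where either member's across-replicate SD exceeds `noise_sd_max` are
#' dropped; the remainder are summarized by the fraction with concordant
#' effect direction and the squared Pearson correlation of effect sizes.
#'
#' @param effect_a,effect_b Ortholog effects (log2).
#' @param sd_a,sd_b Across-replicate SDs per member.
#' @param noise_sd_max Noise filter.
#' @return list(n_used, concordance, r2)
#' @export
ortholog_concordance <- function(effect_a, effect_b, sd_a, sd_b,
                                 noise_sd_max = 0.15) {
  keep <- !is.na(effect_a) & !is.na(effect_b) &
    sd_a <= noise_sd_max & sd_b <= noise_sd_max
  a <- effect_a[keep]; b <- effect_b[keep]
  list(n_used = sum(keep),
       concordance = if (sum(keep)) mean(sign(a) == sign(b)) else NA_real_,
       r2 = if (sum(keep) >= 3) stats::cor(a, b)^2 else NA_real_)
}

#' Flag sequence contexts where start-codon mutation creates artifacts
#'
#' Three mechanized audit rules for apparent enhancer uORFs:
#' (a) an AUG preceded by U, where AUG -> AAG creates a UAA stop codon
#'     (converting an unannotated N-terminal extension into a uORF);
#' (b) AUGNAUG spacing, where mutating the first AUG places an A at the -3
#'     position of the next AUG's Kozak context;
#' (c) a non-AUG uORF nested strictly inside an AUG uORF's span.
#'
#' @param leader WT leader sequence.
#' @param annotations data.frame(uorf_id, uorf_start, uorf_end, start_codon)
#'   with 0-based half-open coordinates.
#' @return data.frame(uorf_id, flag_uaa_created, flag_aug_n_aug, flag_nested)
#' @export
flag_mutation_artifacts <- function(leader, annotations) {
  leader <- normalize_nt(leader)
  ann <- annotations
  ann$start_codon <- normalize_nt(ann$start_codon)
  is_aug <- ann$start_codon == "ATG"
  flag_a <- flag_b <- flag_c <- logical(nrow(ann))
  for (i in seq_len(nrow(ann))) {
    s <- ann$uorf_start[i]
    if (is_aug[i]) {
      flag_a[i] <- s >= 1 && substr(leader, s, s) == "T"
      flag_b[i] <- substr(leader, s + 5, s + 7) == "ATG"
    } else {
      inside <- is_aug & ann$uorf_start < ann$uorf_start[i] &
        ann$uorf_end > ann$uorf_end[i]
      flag_c[i] <- any(inside)
    }
  }
  data.frame(uorf_id = ann$uorf_id, flag_uaa_created = flag_a,
             flag_aug_n_aug = flag_b, flag_nested = flag_c,
             stringsAsFactors = FALSE)
}
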