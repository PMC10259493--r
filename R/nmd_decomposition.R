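#' Decomposing uORF repression into NMD and translational components
#'
#' With paired measurements in wildtype and upf1-delta yeast, a uORF's total
#' log2(WT/AAG) effect splits additively: the effect remaining in upf1-delta
#' is the translational (TE) component, the difference is the NMD component,
#' and %NMD = 100 * NMD / total quantifies the share of repression due to
#' nonsense-mediated decay. %NMD is only meaningful for significant
#' repressors; values pushed outside [0, 100] by noise are clamped and
#' flagged.
#'
#' @name nmd_decomposition
NULL

#' Decompose total uORF effects into NMD and TE components
#'
#' @param wt_effect log2(WT/AAG) in wildtype (vector).
#' @param upf1_effect log2(WT/AAG) in upf1-delta (= TE component).
#' @param uorf_id Optional identifiers.
#' @return data.frame: uorf_id, wt_effect, te_effect, nmd_effect
#'   (= wt - upf1, additive in log2), pct_nmd (clamped to [0, 100], NA for
#'   non-repressors), pct_nmd_raw, clamped flag.
#' @export
nmd_decompose <- function(wt_effect, upf1_effect, uorf_id = NULL) {
  stopifnot(length(wt_effect) == length(upf1_effect))
  nmd <- wt_effect - upf1_effect
  raw <- ifelse(!is.na(wt_effect) & wt_effect < 0, 100 * nmd / wt_effect,
                NA_real_)
  clamped <- !is.na(raw) & (raw < 0 | raw > 100)
  data.frame(
    uorf_id = if (is.null(uorf_id)) seq_along(wt_effect) else uorf_id,
    wt_effect = wt_effect, te_effect = upf1_effect, nmd_effect = nmd,
    pct_nmd = pmin(pmax(raw, 0), 100), pct_nmd_raw = raw, clamped = clamped,
    stringsAsFactors = FALSE)
}

#' %NMD by stop codon and stop+1 nucleotide
#'
#' @param pct_nmd %NMD values.
#' @param stop_codon Stop codon per uORF (UAA/UAG/UGA, T/U spelling free).
#' @param stop_plus1 Nucleotide following the stop.
#' @param min_n Groups smaller than this are reported but untested.
#' @return list(stop_summary, stopnt_summary, kw_stop_p, kw_by_family) with
#'   group medians, sizes, a Kruskal-Wallis p across the three stop codons,
#'   and a Kruskal-Wallis p across +1 nucleotides within each stop family.
#' @export
summarize_by_stop_context <- function(pct_nmd, stop_codon, stop_plus1, min_n = 3) {
  stop_codon <- gsub("T", "U", toupper(stop_codon))
  stop_plus1 <- gsub("T", "U", toupper(stop_plus1))
  keep <- !is.na(pct_nmd)
  pct <- pct_nmd[keep]; sc <- stop_codon[keep]; s1 <- stop_plus1[keep]
  stop_summary <- do.call(rbind, lapply(sort(unique(sc)), function(s) {
    data.frame(stop_codon = s, n = sum(sc == s),
               median_pct_nmd = stats::median(pct[sc == s]))
  }))
  key <- paste0(sc, s1)
  stopnt_summary <- do.call(rbind, lapply(sort(unique(key)), function(k) {
    data.frame(stop_context = k, n = sum(key == k),
               median_pct_nmd = stats::median(pct[key == k]))
  }))
  grp <- split(pct, sc)
  kw_stop_p <- if (length(grp) >= 2 && all(lengths(grp) >= min_n))
    kruskal_wallis(grp) else NA_real_
  kw_by_family <- vapply(sort(unique(sc)), function(s) {
    g <- split(pct[sc == s], s1[sc == s])
    if (length(g) >= 2 && all(lengths(g) >= min_n)) kruskal_wallis(g)
    else NA_real_
  }, numeric(1))
  list(stop_summary = stop_summary, stopnt_summary = stopnt_summary,
       kw_stop_p = kw_stop_p, kw_by_family = kw_by_family)
}

#' %NMD by uORF length class
#'
#' @param pct_nmd %NMD values.
#' @param length_aa uORF lengths in amino acids (stop excluded).
#' @param threshold Boundary: lengths <= threshold are "short" (inclusive).
#' @return list(short_median, long_median, n_short, n_long, p) with a
#'   Wilcoxon rank-sum p (NA when a group is empty).
#' @export
summarize_by_length <- function(pct_nmd, length_aa, threshold = 12) {
  keep <- !is.na(pct_nmd)
  pct <- pct_nmd[keep]; len <- length_aa[keep]
  short <- pct[len <= threshold]; long <- pct[len > threshold]
  p <- if (length(short) && length(long)) wilcoxon_rank_sum(short, long)
       else NA_real_
  list(short_median = if (length(short)) stats::median(short) else NA_real_,
       long_median = if (length(long)) stats::median(long) else NA_real_,
       n_short = length(short), n_long = length(long), p = p)
}

#' Regression of %NMD on stop-to-cap distance
#'
#' Ordinary least squares of %NMD on the distance from the 5' cap to the uORF
#' stop codon.
#'
#' @param pct_nmd %NMD values.
#' @param distance Stop-to-cap distances (nt).
#' @return list(slope, intercept, r2, p); r2 is the squared Pearson
#'   correlation.
#' @export
stop_cap_distance_model <- function(pct_nmd, distance) {
  keep <- !is.na(pct_nmd) & !is.na(distance)
  y <- pct_nmd[keep]; x <- distance[keep]
  if (length(x) < 3) stop("need at least 3 complete observations")
  if (stats::var(x) == 0) stop("zero variance in distance")
  if (stats::var(y) == 0) {
    return(list(slope = 0, intercept = y[1], r2 = 0, p = 1))
  }
  fit <- stats::lm(y ~ x)
  s <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r2 = s$r.squared,
       p = unname(s$coefficients[2, 4]))
}
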