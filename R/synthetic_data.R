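#' Synthetic reporter libraries with planted ground truth
#'
#' The simulator emulates the structure of a paired wildtype/start-codon-mutant
#' (WT/AAG) uORF reporter library read out by 9-bin FACS sorting of a noisy
#' YFP/mCherry ratio, multinomial sequencing of the sorted bins, targeted
#' RNA-seq in two strains (wildtype and upf1-delta, in which the NMD component
#' of each uORF's effect is absent), and polysome-fraction sequencing. Every
#' downstream estimator in the package can therefore be tested against planted
#' truth.
#'
#' @name synthetic_data
NULL

NONAUG_CODONS <- c("ATT", "ATA", "ATC", "ACG", "GTG", "TTG", "CTG")
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Specification for a synthetic uORF reporter library
#'
#' @param n_uorfs Number of uORFs (the library holds `2 * n_uorfs` constructs:
#'   one WT and one AAG variant per uORF).
#' @param fraction_nonAUG Proportion of uORFs initiating at a near-cognate
#'   (NCC) codon rather than AUG.
#' @param leader_length_range Transcript-leader length interval in nt
#'   (library oligo design caps leaders at 180 nt).
#' @param planted_weights Named numeric vector mapping feature names to effect
#'   sizes on log2(WT/AAG) activity. Features are scaled to [0, 1] by their
#'   design range before weighting, so a weight is the log2 effect of moving a
#'   feature across its full range. Allowed names: kozak_score,
#'   dist_cap_start, dist_stop_cds, length_aa, pct_au_downstream, cai, pi,
#'   pro_gly_freq, stop_is_UAG, stop_is_UGA, stop1_is_AU, phastcons_start,
#'   phastcons_stop, is_oorf.
#' @param noise_sd Gaussian noise on true_effect_log2, in log2 units.
#' @param intercept Baseline log2 effect added to every uORF (a mildly
#'   repressive library matches the observation that most uORFs repress).
#' @param max_length_aa Longest uORF peptide, in codons (stop excluded).
#' @param seed Integer seed.
#' @return A `synthetic_library_spec` list.
#' @export
library_spec <- function(n_uorfs,
                         fraction_nonAUG = 0.15,
                         leader_length_range = c(80, 180),
                         planted_weights = c(kozak_score = -1.5,
                                             dist_cap_start = 0.8,
                                             length_aa = -0.3),
                         noise_sd = 0.1,
                         intercept = -0.2,
                         max_length_aa = 20,
                         seed = 1L) {
  stopifnot(n_uorfs >= 1,
            fraction_nonAUG >= 0, fraction_nonAUG <= 1,
            length(leader_length_range) == 2,
            leader_length_range[2] <= 180,
            leader_length_range[1] <= leader_length_range[2],
            noise_sd >= 0)
  allowed <- c("kozak_score", "dist_cap_start", "dist_stop_cds", "length_aa",
               "pct_au_downstream", "cai", "pi", "pro_gly_freq",
               "stop_is_UAG", "stop_is_UGA", "stop1_is_AU",
               "phastcons_start", "phastcons_stop", "is_oorf")
  bad <- setdiff(names(planted_weights), allowed)
  if (length(bad)) stop("unknown planted feature(s): ", paste(bad, collapse = ", "))
  # minimal geometry: 4 nt Kozak context + start + 1 codon + stop + 1 nt after
  if (leader_length_range[1] < 4 + 3 + 3 + 3 + 1) {
    stop("leader too short to host requested uORF geometry (need >= 14 nt)")
  }
  structure(list(n_uorfs = as.integer(n_uorfs),
                 fraction_nonAUG = fraction_nonAUG,
                 leader_length_range = as.integer(leader_length_range),
                 planted_weights = planted_weights,
                 noise_sd = noise_sd,
                 intercept = intercept,
                 max_length_aa = as.integer(max_length_aa),
                 seed = as.integer(seed)),
            class = "synthetic_library_spec")
}

#' Synthetic Kozak-context score table
#'
#' Emulates the Kozak sub-library readout: one expression score per
#' (-4..-1 context, start codon, +1 base) combination, on the normalized
#' reporter scale. Scores follow the canonical determinants of initiation
#' efficiency (A/G at -3, codon identity: AUG strong, NCC weak) plus a small
#' seeded perturbation so the table is not degenerate.
#'
#' @param seed Integer seed.
#' @return data.frame with columns context (4 nt), start_codon, plus1, score.
#' @export
synthetic_kozak_table <- function(seed = 99L) {
  set.seed(seed)
  nt <- c("A", "C", "G", "T")
  ctx <- do.call(paste0, expand.grid(nt, nt, nt, nt, stringsAsFactors = FALSE))
  codons <- c("ATG", NONAUG_CODONS)
  grid <- expand.grid(context = ctx, start_codon = codons, plus1 = nt,
                      stringsAsFactors = FALSE)
  m3 <- substr(grid$context, 2, 2)            # the -3 position
  m1 <- substr(grid$context, 4, 4)            # the -1 position
  base <- ifelse(grid$start_codon == "ATG", 0.75, 0.18)
  score <- base +
    0.18 * (m3 %in% c("A", "G")) +
    0.06 * (m1 == "A") +
    0.04 * (grid$plus1 %in% c("A", "T")) +
    stats::rnorm(nrow(grid), 0, 0.02)
  grid$score <- pmin(pmax(score, 0.03), 1.2)
  grid
}

# sample n sense (non-stop, non-ATG) codons
sample_sense_codons <- function(n) {
  nt <- c("A", "C", "G", "T")
  all_codons <- do.call(paste0, expand.grid(nt, nt, nt, stringsAsFactors = FALSE))
  pool <- setdiff(all_codons, c(STOP_CODONS, "ATG"))
  sample(pool, n, replace = TRUE)
}

# mutate any ATG whose 0-based start is not `keep_start` (G -> C cannot
# create a new ATG or a stop codon)
scrub_accidental_atg <- function(seq, keep_start) {
  repeat {
    hits <- gregexpr("ATG", seq, fixed = TRUE)[[1]]
    hits <- hits[hits > 0]
    hits <- hits[hits - 1L != keep_start]   # to 0-based
    if (!length(hits)) return(seq)
    substr(seq, hits[1] + 2L, hits[1] + 2L) <- "C"
  }
}

#' Generate a paired WT/AAG reporter library with planted ground truth
#'
#' Each uORF gets a random geometry (leader length, start position, peptide
#' length), start/stop codons and Kozak context; the leader background is
#' scrubbed of accidental AUGs so annotations are unambiguous. The true
#' log2(WT/AAG) activity is the planted-weight combination of the uORF's
#' scaled features plus Gaussian noise; the AAG variant differs from WT only
#' at the start codon and has zero effect by definition.
#'
#' @param spec A [library_spec()].
#' @param kozak_table Kozak score table (default [synthetic_kozak_table()]).
#' @return list with elements `library` (one row per construct: construct_id,
#'   pair_id, variant, species, leader_seq, uorf_start, uorf_end, start_codon,
#'   stop_codon, stop_plus1, length_aa), `truth` (construct_id, pair_id,
#'   variant, true_expression, true_effect_log2, true_nmd_fraction), and
#'   `features` (per-uORF feature values used for planting, including
#'   synthetic conservation scores).
#' @export
generate_reporter_library <- function(spec, kozak_table = synthetic_kozak_table()) {
  stopifnot(inherits(spec, "synthetic_library_spec"))
  set.seed(spec$seed)
  n <- spec$n_uorfs
  nt <- c("A", "C", "G", "T")
  ktab_key <- paste(kozak_table$context, kozak_table$start_codon, kozak_table$plus1)
  ktab_score <- stats::setNames(kozak_table$score, ktab_key)

  rows <- vector("list", n)
  feats <- vector("list", n)
  for (i in seq_len(n)) {
    L <- sample(seq(spec$leader_length_range[1], spec$leader_length_range[2]), 1)
    # geometry: start >= 4 (full Kozak context), stop + 1 nt inside leader
    max_aa <- min(spec$max_length_aa, (L - 4 - 3 - 3 - 1) %/% 3)
    aa <- sample(seq_len(max_aa), 1)
    ulen <- 3 + 3 * aa + 3                       # start + peptide + stop
    start <- sample(seq(4, L - ulen - 1), 1)     # 0-based start index
    start_codon <- if (stats::runif(1) < spec$fraction_nonAUG)
      sample(NONAUG_CODONS, 1) else "ATG"
    stop_codon <- sample(STOP_CODONS, 1)
    body <- paste(sample_sense_codons(aa), collapse = "")
    bg_left <- paste(sample(nt, start, replace = TRUE), collapse = "")
    n_right <- L - (start + ulen)
    bg_right <- paste(sample(nt, n_right, replace = TRUE), collapse = "")
    wt <- paste0(bg_left, start_codon, body, stop_codon, bg_right)
    keep <- if (start_codon == "ATG") start else -1L
    wt <- scrub_accidental_atg(wt, keep)

    uend <- start + ulen                          # 0-based half-open end
    ctx <- substr(wt, start - 3, start)           # -4..-1 (1-based substr)
    plus1 <- substr(wt, start + 4, start + 4)
    ks <- unname(ktab_score[paste(ctx, start_codon, plus1)])
    if (is.na(ks)) ks <- stats::median(kozak_table$score)
    stop_plus1 <- substr(wt, uend + 1, uend + 1)
    pep <- translate_codons(substr(wt, start + 4, start + 3 + 3 * aa))
    window <- substr(wt, uend + 1, min(uend + 9, L))

    rows[[i]] <- data.frame(
      uorf_id = sprintf("uorf%04d", i), leader_length = L,
      uorf_start = start, uorf_end = uend,
      start_codon = start_codon, stop_codon = stop_codon,
      stop_plus1 = stop_plus1, length_aa = aa,
      wt_seq = wt, stringsAsFactors = FALSE)
    feats[[i]] <- c(
      kozak_score = ks,
      dist_cap_start = start,
      dist_stop_cds = L - uend,
      length_aa = aa,
      pct_au_downstream = 100 * mean(strsplit(window, "")[[1]] %in% c("A", "T")),
      cai = NA_real_,                       # filled below (needs weight table)
      pi = isoelectric_point(pep),
      pro_gly_freq = pro_gly_frequency(pep),
      stop_is_UAG = as.numeric(stop_codon == "TAG"),
      stop_is_UGA = as.numeric(stop_codon == "TGA"),
      stop1_is_AU = as.numeric(stop_plus1 %in% c("A", "T")),
      phastcons_start = stats::rbeta(1, 0.8, 0.8),
      phastcons_stop = stats::rbeta(1, 0.8, 0.8),
      is_oorf = 0)
  }
  ann <- do.call(rbind, rows)
  X <- do.call(rbind, feats)
  # CAI against a flat synthetic weight table (uniform codon usage): use the
  # geometric-mean weight of each uORF body under seeded per-codon weights
  cw <- synthetic_codon_weights(spec$seed)
  X[, "cai"] <- vapply(seq_len(n), function(i) {
    cds <- substr(ann$wt_seq[i], ann$uorf_start[i] + 4,
                  ann$uorf_start[i] + 3 + 3 * ann$length_aa[i])
    cai(cds, cw)
  }, numeric(1))

  # planted effects: weights act on features scaled to design ranges
  ranges <- c(kozak_score = 1.2, dist_cap_start = 180, dist_stop_cds = 180,
              length_aa = spec$max_length_aa, pct_au_downstream = 100,
              cai = 1, pi = 14, pro_gly_freq = 1, stop_is_UAG = 1,
              stop_is_UGA = 1, stop1_is_AU = 1, phastcons_start = 1,
              phastcons_stop = 1, is_oorf = 1)
  eff <- rep(spec$intercept, n)
  for (f in names(spec$planted_weights)) {
    eff <- eff + spec$planted_weights[[f]] * X[, f] / ranges[[f]]
  }
  eff <- eff + stats::rnorm(n, 0, spec$noise_sd)
  nmd_frac <- stats::rbeta(n, 1.4, 2.6)     # median ~1/3 of repression via NMD
  base_expr <- stats::runif(n, 0.75, 1.1)   # AAG (uORF-less) expression level

  lib <- data.frame(
    construct_id = c(paste0(ann$uorf_id, "_WT"), paste0(ann$uorf_id, "_AAG")),
    pair_id = rep(ann$uorf_id, 2),
    variant = rep(c("WT", "AAG"), each = n),
    species = "synthetic",
    leader_seq = c(ann$wt_seq, make_aag_variant(ann$wt_seq, ann$uorf_start)),
    uorf_start = rep(ann$uorf_start, 2),
    uorf_end = rep(ann$uorf_end, 2),
    stringsAsFactors = FALSE)
  truth <- data.frame(
    construct_id = lib$construct_id,
    pair_id = lib$pair_id,
    variant = lib$variant,
    true_expression = pmin(c(base_expr * 2^eff, base_expr), 1.2),
    true_effect_log2 = c(eff, rep(0, n)),
    true_nmd_fraction = rep(nmd_frac, 2),
    stringsAsFactors = FALSE)
  list(library = lib, truth = truth,
       features = data.frame(uorf_id = ann$uorf_id, X,
                             start_codon = ann$start_codon,
                             stop_codon = ann$stop_codon,
                             stop_plus1 = ann$stop_plus1,
                             stringsAsFactors = FALSE),
       annotations = ann)
}

#' Mutate uORF start codons to AAG
#'
#' @param seqs Character vector of WT leader sequences.
#' @param starts 0-based start-codon indices.
#' @return Sequences differing from WT only at the start codon.
#' @export
make_aag_variant <- function(seqs, starts) {
  out <- seqs
  substr(out, starts + 1L, starts + 3L) <- "AAG"
  out
}

#' Synthetic codon relative-adaptiveness weights
#'
#' @param seed Integer seed.
#' @return Named numeric vector over the 61 sense codons, in (0, 1], with at
#'   least one codon per family at weight 1.
#' @export
synthetic_codon_weights <- function(seed = 7L) {
  set.seed(seed)
  nt <- c("A", "C", "G", "T")
  all_codons <- do.call(paste0, expand.grid(nt, nt, nt, stringsAsFactors = FALSE))
  sense <- setdiff(all_codons, STOP_CODONS)
  w <- stats::runif(length(sense), 0.1, 1)
  names(w) <- sense
  aa <- translate_codons_vec(sense)
  for (a in unique(aa)) {                 # best codon per family gets 1
    idx <- which(aa == a)
    w[idx[which.max(w[idx])]] <- 1
  }
  w
}

# strain-specific true protein expression for every construct
strain_expression <- function(library, truth, strain = c("wildtype", "upf1_delta")) {
  strain <- match.arg(strain)
  if (strain == "wildtype") return(truth$true_expression)
  # in upf1-delta the NMD component is abolished: only the TE component remains
  base <- truth$true_expression[match(paste0(truth$pair_id, "_AAG"),
                                      truth$construct_id)]
  te <- truth$true_effect_log2 * (1 - truth$true_nmd_fraction)
  ifelse(truth$variant == "WT", pmin(base * 2^te, 1.2), truth$true_expression)
}

#' Simulate binned FACS sorting and per-bin sequencing counts
#'
#' Each simulated cell carries one construct (multinomial on library
#' frequencies) and a log-normally perturbed YFP/mCherry ratio; cells fall
#' into bins by the gate edges; per-bin sequencing reads are drawn
#' multinomially from that bin's cell composition, with bin read totals
#' proportional to cells sorted (reads over all sorted bins sum to `depth`).
#' Also emits the simulated plate-reader (TECAN) mean expression per bin, the
#' cells sorted per bin, and an unsorted plasmid-pool ("bin0") count vector of
#' the same depth.
#'
#' @param library,truth From [generate_reporter_library()].
#' @param n_cells Cells sorted.
#' @param n_bins Number of sorted bins.
#' @param bin_edges Strictly increasing gate thresholds on the YFP/mCherry
#'   ratio (length `n_bins - 1`); default: population quantiles of the true
#'   construct expressions, giving roughly even occupancy.
#' @param sort_noise_sd SD of the log-normal sorting noise (log units).
#' @param depth Total sorted-bin sequencing reads.
#' @param strain "wildtype" or "upf1_delta" (NMD component removed).
#' @param lib_freq Library representation (default uniform).
#' @param seed Integer seed.
#' @return list(bin_counts = construct x bin matrix (bin0 first), bin_means =
#'   raw per-bin mean expression, cells_sorted, bin_edges)
#' @export
simulate_facs_counts <- function(library, truth, n_cells = 2e5, n_bins = 9,
                                 bin_edges = NULL, sort_noise_sd = 0.15,
                                 depth = 1e6, strain = "wildtype",
                                 lib_freq = NULL, seed = 1L) {
  stopifnot(depth > 0, n_bins >= 2)
  set.seed(seed)
  nc <- nrow(library)
  expr <- strain_expression(library, truth, strain)
  if (is.null(lib_freq)) lib_freq <- rep(1 / nc, nc)
  if (is.null(bin_edges)) {
    bin_edges <- unname(stats::quantile(expr, probs = seq_len(n_bins - 1) / n_bins))
    bin_edges <- bin_edges * (1 + 1e-9 * seq_along(bin_edges))  # enforce strict
  }
  stopifnot(length(bin_edges) == n_bins - 1, all(diff(bin_edges) > 0))

  cells <- as.vector(stats::rmultinom(1, n_cells, lib_freq))
  cidx <- rep.int(seq_len(nc), cells)
  obs <- expr[cidx] * exp(stats::rnorm(length(cidx), 0, sort_noise_sd))
  bin <- findInterval(obs, bin_edges) + 1L
  comp <- matrix(0, nc, n_bins)
  for (b in seq_len(n_bins)) {
    sel <- bin == b
    if (any(sel)) comp[, b] <- tabulate(cidx[sel], nbins = nc)
  }
  cells_sorted <- colSums(comp)
  bin_means <- vapply(seq_len(n_bins), function(b) {
    sel <- bin == b
    if (any(sel)) mean(obs[sel]) else {
      lo <- if (b == 1) min(obs) else bin_edges[b - 1]
      hi <- if (b == n_bins) max(obs) else bin_edges[b]
      (lo + hi) / 2
    }
  }, numeric(1))

  reads_per_bin <- as.vector(stats::rmultinom(1, depth, pmax(cells_sorted, 0)))
  counts <- matrix(0L, nc, n_bins)
  for (b in seq_len(n_bins)) {
    if (reads_per_bin[b] > 0 && cells_sorted[b] > 0) {
      counts[, b] <- as.vector(stats::rmultinom(1, reads_per_bin[b], comp[, b]))
    }
  }
  bin0 <- as.vector(stats::rmultinom(1, depth, lib_freq))
  out <- cbind(bin0, counts)
  dimnames(out) <- list(library$construct_id,
                        c("bin0", paste0("bin", seq_len(n_bins))))
  list(bin_counts = out, bin_means = bin_means,
       cells_sorted = cells_sorted, bin_edges = bin_edges)
}

#' Simulate targeted RNA-seq counts
#'
#' RNA abundance of a WT construct is reduced relative to its AAG pair by the
#' NMD component of its effect in the wildtype strain; in upf1-delta the NMD
#' component is removed (RNA ratio 1 for pure-NMD uORFs).
#'
#' @inheritParams simulate_facs_counts
#' @param depth Total RNA reads.
#' @return Named integer count vector summing to `depth`.
#' @export
simulate_rna_counts <- function(library, truth, strain = "wildtype",
                                depth = 1e6, lib_freq = NULL, seed = 1L) {
  set.seed(seed)
  nc <- nrow(library)
  if (is.null(lib_freq)) lib_freq <- rep(1 / nc, nc)
  nmd <- truth$true_effect_log2 * truth$true_nmd_fraction
  abund <- ifelse(truth$variant == "WT" & strain == "wildtype", 2^nmd, 1)
  counts <- as.vector(stats::rmultinom(1, depth, abund * lib_freq))
  stats::setNames(counts, library$construct_id)
}

#' Simulate polysome-fraction sequencing counts
#'
#' Reads are distributed over sucrose-gradient fractions such that the
#' translated/untranslated ratio of WT vs AAG reflects the translational (TE)
#' component of the planted effect; RNA abundance carries the NMD component
#' (the assay runs in wildtype cells).
#'
#' @inheritParams simulate_facs_counts
#' @param fractions Ordered fraction labels.
#' @param depth Total reads over all fractions.
#' @return construct x fraction integer matrix summing to `depth`.
#' @export
simulate_polysome_counts <- function(library, truth,
                                     fractions = c("top", "40S", "60S", "mono",
                                                   "2", "3", "4", "5plus"),
                                     depth = 2e6, lib_freq = NULL, seed = 1L) {
  set.seed(seed)
  nc <- nrow(library)
  if (is.null(lib_freq)) lib_freq <- rep(1 / nc, nc)
  te <- truth$true_effect_log2 * (1 - truth$true_nmd_fraction)
  nmd <- truth$true_effect_log2 * truth$true_nmd_fraction
  is_wt <- truth$variant == "WT"
  abund <- ifelse(is_wt, 2^nmd, 1) * lib_freq
  odds <- 0.45 / 0.55 * ifelse(is_wt, 2^te, 1)   # library-wide 45% translating
  p_trans <- odds / (1 + odds)
  split_t <- c("2" = 0.30, "3" = 0.28, "4" = 0.22, "5plus" = 0.20)
  split_u <- c("40S" = 0.25, "60S" = 0.25, "mono" = 0.50)
  prob <- matrix(0, nc, length(fractions), dimnames = list(library$construct_id, fractions))
  prob[, "top"] <- 0.02
  for (f in names(split_t)) prob[, f] <- 0.98 * p_trans * split_t[[f]]
  for (f in names(split_u)) prob[, f] <- 0.98 * (1 - p_trans) * split_u[[f]]
  prob <- prob * abund
  counts <- stats::rmultinom(1, depth, as.vector(prob))
  matrix(as.integer(counts), nc, length(fractions),
         dimnames = list(library$construct_id, fractions))
}

#' Simulate a feature matrix with planted linear signal
#'
#' Draws a design matrix with the marginal shapes of the 15 uORF modeling
#' features and a response `y = X w + e`, with noise scaled so that
#' `var(Xw) / var(e)` equals `snr`. Used for regression-recovery tests that do
#' not need full sequence simulation.
#'
#' @param n Number of uORFs (rows).
#' @param planted_weights Named weights over feature columns (names must be a
#'   subset of the 15 canonical features, see [uorf_feature_names()]).
#' @param snr Signal-to-noise variance ratio (Inf for noiseless).
#' @param seed Integer seed.
#' @return list(X, y, weights) with X an n x 15 matrix.
#' @export
simulate_feature_matrix <- function(n, planted_weights, snr = 5, seed = 1L) {
  set.seed(seed)
  fn <- uorf_feature_names()
  stopifnot(all(names(planted_weights) %in% fn))
  X <- cbind(
    kozak_score = stats::runif(n, 0.05, 1.2),
    dist_cap_start = stats::runif(n, 4, 170),
    dist_stop_cds = stats::runif(n, 1, 160),
    length_aa = sample(1:20, n, replace = TRUE),
    ddg_median = stats::rgamma(n, 2, 0.5),
    pct_au_downstream = 100 * stats::rbeta(n, 5, 3),
    cai = stats::runif(n, 0.2, 1),
    pi = stats::runif(n, 3.5, 11),
    pro_gly_freq = stats::rbeta(n, 1, 6),
    stop_is_UAG = stats::rbinom(n, 1, 1 / 3),
    stop_is_UGA = stats::rbinom(n, 1, 1 / 3),
    stop1_is_AU = stats::rbinom(n, 1, 0.5),
    phastcons_start = stats::rbeta(n, 0.8, 0.8),
    phastcons_stop = stats::rbeta(n, 0.8, 0.8),
    is_oorf = stats::rbinom(n, 1, 0.1))
  w <- stats::setNames(numeric(length(fn)), fn)
  w[names(planted_weights)] <- planted_weights
  signal <- as.vector(X %*% w)
  e_sd <- if (is.infinite(snr)) 0 else sqrt(stats::var(signal) / snr)
  y <- signal + stats::rnorm(n, 0, e_sd)
  list(X = X, y = y, weights = w)
}
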