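#' uORF sequence and position features
#'
#' The 15 features used for elastic-net modeling of uORF activity: Kozak
#' context score, cap-to-start and stop-to-CDS distances, peptide length,
#' median unfolding energy around the start codon, %AU downstream of the stop,
#' codon adaptation index, peptide isoelectric point, proline/glycine
#' frequency, stop-codon identity (two dummies, UAA baseline), a stop+1 A/U
#' indicator, mean conservation over the start and stop codons, and an
#' overlapping-ORF indicator.
#'
#' @name feature_extraction
NULL

GENETIC_CODE_1L <- c(
  TTT="F", TTC="F", TTA="L", TTG="L", CTT="L", CTC="L", CTA="L", CTG="L",
  ATT="I", ATC="I", ATA="I", ATG="M", GTT="V", GTC="V", GTA="V", GTG="V",
  TCT="S", TCC="S", TCA="S", TCG="S", CCT="P", CCC="P", CCA="P", CCG="P",
  ACT="T", ACC="T", ACA="T", ACG="T", GCT="A", GCC="A", GCA="A", GCG="A",
  TAT="Y", TAC="Y", TAA="*", TAG="*", CAT="H", CAC="H", CAA="Q", CAG="Q",
  AAT="N", AAC="N", AAA="K", AAG="K", GAT="D", GAC="D", GAA="E", GAG="E",
  TGT="C", TGC="C", TGA="*", TGG="W", CGT="R", CGC="R", CGA="R", CGG="R",
  AGT="S", AGC="S", AGA="R", AGG="R", GGT="G", GGC="G", GGA="G", GGG="G")

# split a nucleotide string into codons
split_codons <- function(cds) {
  cds <- normalize_nt(cds)
  if (nchar(cds) %% 3 != 0) stop("coding sequence length not a multiple of 3")
  substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
}

translate_codons_vec <- function(codons) unname(GENETIC_CODE_1L[codons])

# translate a coding nucleotide string (no stop) to a peptide
translate_codons <- function(cds) {
  if (nchar(cds) == 0) return("")
  paste(translate_codons_vec(split_codons(cds)), collapse = "")
}

# RNA -> DNA spelling, uppercase
normalize_nt <- function(x) gsub("U", "T", toupper(x))

#' Canonical modeling feature names (documented column order)
#' @return Character vector of the 15 feature names.
#' @export
uorf_feature_names <- function() {
  c("kozak_score", "dist_cap_start", "dist_stop_cds", "length_aa",
    "ddg_median", "pct_au_downstream", "cai", "pi", "pro_gly_freq",
    "stop_is_UAG", "stop_is_UGA", "stop1_is_AU",
    "phastcons_start", "phastcons_stop", "is_oorf")
}

#' Kozak-context score lookup
#'
#' Looks up the measured initiation-context score for the -4..-1 context, the
#' start codon, and the +1 base of a uORF. U/T spelling is normalized before
#' lookup.
#'
#' @param sequence Leader sequence (with >= 4 nt upstream of the start).
#' @param start_index 0-based index of the start codon's first base.
#' @param table data.frame with columns context, start_codon, plus1, score.
#' @return Score, or NA (with a warning) when the context is absent from the
#'   table or the start is < 4 nt from the cap.
#' @export
kozak_score <- function(sequence, start_index, table) {
  sequence <- normalize_nt(sequence)
  if (start_index < 4 || start_index + 4 > nchar(sequence)) {
    warning("Kozak context unavailable (start too close to an end)")
    return(NA_real_)
  }
  ctx <- substr(sequence, start_index - 3, start_index)
  codon <- substr(sequence, start_index + 1, start_index + 3)
  plus1 <- substr(sequence, start_index + 4, start_index + 4)
  key <- paste(ctx, codon, plus1)
  tab_key <- paste(normalize_nt(table$context), normalize_nt(table$start_codon),
                   normalize_nt(table$plus1))
  hit <- match(key, tab_key)
  if (is.na(hit)) {
    warning("Kozak context not in table: ", key)
    return(NA_real_)
  }
  table$score[hit]
}

#' Cap-to-start and stop-to-CDS distances
#'
#' Coordinates are 0-based half-open, position 0 = first transcribed
#' nucleotide; the main CDS begins at `cds_start` (default: leader length).
#'
#' @param leader Leader sequence or its length.
#' @param uorf_start 0-based start-codon index.
#' @param uorf_end 0-based half-open end of the stop codon.
#' @param cds_start 0-based main-ORF start (default just past the leader).
#' @return c(dist_cap_start, dist_stop_cds); dist_stop_cds is negative for
#'   oORFs whose stop lies inside the CDS.
#' @export
positional_distances <- function(leader, uorf_start, uorf_end, cds_start = NULL) {
  L <- if (is.character(leader)) nchar(leader) else leader
  if (is.null(cds_start)) cds_start <- L
  if (uorf_start < 0 || uorf_start >= cds_start || uorf_end <= uorf_start) {
    stop("uORF coordinates outside sequence")
  }
  c(dist_cap_start = uorf_start, dist_stop_cds = cds_start - uorf_end)
}

#' Percent A/U in the +2..+10 window downstream of a stop codon
#'
#' The window is the 9 nt immediately following the stop codon's last base
#' (counting the stop's last base as +1), truncated at the sequence end.
#'
#' @param sequence Nucleotide string.
#' @param stop_end 0-based half-open end of the stop codon (index just past
#'   its last base).
#' @return Percent A/U in the window; NA for an empty window.
#' @export
pct_au_downstream <- function(sequence, stop_end) {
  sequence <- normalize_nt(sequence)
  from <- stop_end + 1                 # 1-based first base after the stop
  to <- min(stop_end + 9, nchar(sequence))
  if (from > to) return(NA_real_)
  win <- strsplit(substr(sequence, from, to), "")[[1]]
  100 * mean(win %in% c("A", "T"))
}

#' Codon adaptation index
#'
#' Geometric mean of per-codon relative-adaptiveness weights over the uORF
#' coding region (stop codon excluded).
#'
#' @param cds Coding nucleotide string (length divisible by 3) or a character
#'   vector of codons.
#' @param weights Named weights in (0, 1] over codons.
#' @return CAI, or NA for a zero-length coding region.
#' @export
cai <- function(cds, weights) {
  codons <- if (length(cds) == 1 && nchar(cds[1]) != 3) {
    if (nchar(cds) == 0) return(NA_real_)
    split_codons(cds)
  } else normalize_nt(cds)
  if (!length(codons)) return(NA_real_)
  w <- weights[codons]
  if (anyNA(w)) stop("codon(s) missing from weight table: ",
                     paste(unique(codons[is.na(w)]), collapse = ", "))
  exp(mean(log(w)))
}

#' Default side-chain and termini pKa values
#' @return Named list of pKa values (EMBOSS-style set).
#' @export
default_pka <- function() {
  list(Nterm = 8.6, Cterm = 3.6, C = 8.5, D = 3.9, E = 4.1,
       H = 6.5, K = 10.8, R = 12.5, Y = 10.1)
}

#' Peptide isoelectric point
#'
#' pH at which the Henderson-Hasselbalch net charge of the peptide (termini
#' always ionizable) crosses zero, found by bisection to 1e-3 pH units.
#'
#' @param peptide One-letter amino-acid string.
#' @param pka pKa table, see [default_pka()].
#' @return Isoelectric point (pH units).
#' @export
isoelectric_point <- function(peptide, pka = default_pka()) {
  aa <- strsplit(toupper(peptide), "")[[1]]
  npos <- c(Nterm = 1, H = sum(aa == "H"), K = sum(aa == "K"), R = sum(aa == "R"))
  nneg <- c(Cterm = 1, C = sum(aa == "C"), D = sum(aa == "D"),
            E = sum(aa == "E"), Y = sum(aa == "Y"))
  charge <- function(pH) {
    pos <- sum(vapply(names(npos), function(g)
      npos[[g]] / (1 + 10^(pH - pka[[g]])), numeric(1)))
    neg <- sum(vapply(names(nneg), function(g)
      nneg[[g]] / (1 + 10^(pka[[g]] - pH)), numeric(1)))
    pos - neg
  }
  lo <- 0; hi <- 14
  while (hi - lo > 1e-3) {
    mid <- (lo + hi) / 2
    if (charge(mid) > 0) lo <- mid else hi <- mid
  }
  round((lo + hi) / 2, 3)
}

#' Proline + glycine frequency of a peptide
#'
#' @param peptide One-letter amino-acid string (non-empty).
#' @return (count P + count G) / length.
#' @export
pro_gly_frequency <- function(peptide) {
  stopifnot(nchar(peptide) > 0)
  aa <- strsplit(toupper(peptide), "")[[1]]
  mean(aa %in% c("P", "G"))
}

#' Mean conservation score over positions
#'
#' @param track Named numeric vector mapping position to score (or NULL).
#' @param positions Positions to average (e.g. the 3 codon bases).
#' @param fallback Dataset-wide mean substituted when no score is available
#'   (the rule used for constructs from a species without a conservation
#'   track).
#' @return Arithmetic mean of available scores, else `fallback`.
#' @export
phastcons_mean <- function(track, positions, fallback) {
  vals <- if (is.null(track)) rep(NA_real_, length(positions))
          else unname(track[as.character(positions)])
  if (all(is.na(vals))) return(fallback)
  mean(vals, na.rm = TRUE)
}

## ---- folding engines -------------------------------------------------------

can_pair <- function(a, b) {
  paste0(a, b) %in% c("AT", "TA", "GC", "CG", "GT", "TG")
}

# Nussinov maximum-pairing DP matrix (min_loop unpaired bases between a pair)
nussinov_dp <- function(bases, min_loop = 3) {
  n <- length(bases)
  M <- matrix(0L, n, n)
  if (n < min_loop + 2) return(M)
  for (span in (min_loop + 1):(n - 1)) {
    for (i in seq_len(n - span)) {
      j <- i + span
      best <- M[i, j - 1]                      # j unpaired
      ks <- i:(j - min_loop - 1)
      ks <- ks[can_pair(bases[ks], bases[j])]
      if (length(ks)) {
        left <- M[cbind(rep(i, length(ks)), pmax(ks - 1, 1))]
        left[ks == i] <- 0L
        right <- M[cbind(ks + 1, j - 1)]
        best <- max(best, max(left + right + 1L))
      }
      M[i, j] <- best
    }
  }
  M
}

# enumerate up to `limit` co-optimal maximal pairings on [i, j]
nussinov_trace <- function(bases, M, i, j, min_loop, limit) {
  if (j - i < min_loop + 1) return(list(matrix(integer(0), 0, 2)))
  out <- list()
  if (M[i, j] == M[i, j - 1]) {               # j unpaired
    out <- nussinov_trace(bases, M, i, j - 1, min_loop, limit)
  }
  if (length(out) >= limit) return(out[seq_len(limit)])
  ks <- i:(j - min_loop - 1)
  ks <- ks[can_pair(bases[ks], bases[j])]
  for (k in ks) {
    lv <- if (k > i) M[i, k - 1] else 0L
    rv <- if (k + 1 <= j - 1) M[k + 1, j - 1] else 0L
    if (lv + rv + 1L != M[i, j]) next
    lefts <- if (k > i) nussinov_trace(bases, M, i, k - 1, min_loop, limit)
             else list(matrix(integer(0), 0, 2))
    for (L in lefts) {
      rights <- if (k + 1 <= j - 1)
        nussinov_trace(bases, M, k + 1, j - 1, min_loop, limit)
      else list(matrix(integer(0), 0, 2))
      for (R in rights) {
        out[[length(out) + 1]] <- rbind(L, c(k, j), R)
        if (length(out) >= limit) return(out)
      }
    }
  }
  out
}

#' Toy secondary-structure engine (maximum base pairing)
#'
#' A deterministic folding engine for tests: structures are maximal
#' non-crossing canonical pairings (Nussinov algorithm, minimum loop length
#' `min_loop`), each pair contributing `energy_per_pair` kcal/mol;
#' "suboptimal sampling" returns all co-optimal maximal pairings up to n.
#'
#' @param min_loop Minimum unpaired bases enclosed by a pair.
#' @param energy_per_pair Energy per base pair (kcal/mol, negative).
#' @return Engine list with `sample_structures(sequence, n)` returning a list
#'   of 2-column pair matrices (1-based indices) and `evaluate(sequence,
#'   structure)` returning the structure's energy.
#' @export
toy_fold_engine <- function(min_loop = 3, energy_per_pair = -1) {
  list(
    sample_structures = function(sequence, n) {
      bases <- strsplit(normalize_nt(sequence), "")[[1]]
      ln <- length(bases)
      if (ln < min_loop + 2) return(list(matrix(integer(0), 0, 2)))
      M <- nussinov_dp(bases, min_loop)
      nussinov_trace(bases, M, 1L, ln, min_loop, n)
    },
    evaluate = function(sequence, structure) {
      energy_per_pair * nrow(structure)
    })
}

#' ViennaRNA folding engine adapter
#'
#' Wraps the RNAsubopt/RNAeval command-line tools: `sample_structures` draws n
#' structures from the Boltzmann ensemble (RNAsubopt -p), `evaluate` scores a
#' dot-bracket structure with RNAeval. Requires the ViennaRNA executables on
#' the PATH.
#'
#' @return Engine list satisfying the same contract as [toy_fold_engine()].
#' @export
vienna_fold_engine <- function() {
  list(
    sample_structures = function(sequence, n) {
      rna <- gsub("T", "U", normalize_nt(sequence))
      out <- system2("RNAsubopt", c("-p", n), input = rna, stdout = TRUE)
      db <- grep("^[.()]+$", out, value = TRUE)
      lapply(db, dotbracket_to_pairs)
    },
    evaluate = function(sequence, structure) {
      rna <- gsub("T", "U", normalize_nt(sequence))
      db <- pairs_to_dotbracket(structure, nchar(rna))
      out <- system2("RNAeval", stdout = TRUE, input = paste(rna, db, sep = "\n"))
      as.numeric(sub(".*\\((\\s*-?[0-9.]+)\\)\\s*$", "\\1", out[length(out)]))
    })
}

#' Convert dot-bracket notation to a pair matrix
#' @param db Dot-bracket string.
#' @return 2-column matrix of 1-based paired positions.
#' @export
dotbracket_to_pairs <- function(db) {
  ch <- strsplit(db, "")[[1]]
  stack <- integer(0)
  pairs <- matrix(integer(0), 0, 2)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") stack <- c(stack, i)
    else if (ch[i] == ")") {
      pairs <- rbind(pairs, c(stack[length(stack)], i))
      stack <- stack[-length(stack)]
    }
  }
  pairs
}

#' Convert a pair matrix to dot-bracket notation
#' @param pairs 2-column matrix of 1-based paired positions.
#' @param n Sequence length.
#' @return Dot-bracket string.
#' @export
pairs_to_dotbracket <- function(pairs, n) {
  ch <- rep(".", n)
  if (nrow(pairs)) {
    ch[pmin(pairs[, 1], pairs[, 2])] <- "("
    ch[pmax(pairs[, 1], pairs[, 2])] <- ")"
  }
  paste(ch, collapse = "")
}

#' Unfolding energy of the start-codon window
#'
#' For each of n sampled structures with energy dG, all base pairs with at
#' least one endpoint in the window around the start codon are deleted, the
#' opened structure is re-evaluated (dG'), and the cost of unfolding is
#' ddG = dG' - dG (>= 0 for nearest-neighbour-type energy models). The median
#' over structures is the modeling feature.
#'
#' @param sequence Leader plus downstream CDS nucleotides.
#' @param start_index 0-based start-codon index.
#' @param engine Folding engine (see [toy_fold_engine()]).
#' @param n Number of sampled structures.
#' @param window 0-based half-open window forced single-stranded; default
#'   `[start_index - 15, start_index + 15)`, clipped to the sequence.
#' @return list(ddg_median, ddg_values)
#' @export
ddg_unfolding <- function(sequence, start_index, engine, n = 100, window = NULL) {
  ln <- nchar(sequence)
  if (is.null(window)) window <- c(start_index - 15, start_index + 15)
  window <- c(max(window[1], 0), min(window[2], ln))
  structs <- engine$sample_structures(sequence, n)
  vals <- vapply(structs, function(s) {
    g0 <- engine$evaluate(sequence, s)
    if (nrow(s)) {
      # window is 0-based half-open; pair indices are 1-based
      inwin <- (s[, 1] - 1 >= window[1] & s[, 1] - 1 < window[2]) |
               (s[, 2] - 1 >= window[1] & s[, 2] - 1 < window[2])
      s <- s[!inwin, , drop = FALSE]
    }
    engine$evaluate(sequence, s) - g0
  }, numeric(1))
  list(ddg_median = stats::median(vals), ddg_values = vals)
}

#' Assemble the modeling feature matrix
#'
#' One row per uORF, columns in the order of [uorf_feature_names()]; rows with
#' any missing feature are dropped and reported.
#'
#' @param annotations data.frame with columns uorf_id, wt_seq (leader,
#'   optionally + CDS prefix), leader_length, uorf_start, uorf_end, length_aa,
#'   stop_codon, stop_plus1, and optionally is_oorf.
#' @param kozak_table Kozak score table.
#' @param codon_weights Named CAI weight vector.
#' @param conservation Either NULL, a list(track =, fallback =) for
#'   position-level scores, or a data.frame(uorf_id, phastcons_start,
#'   phastcons_stop) of precomputed means.
#' @param engine Folding engine; NULL skips ddg (feature filled with 0 and
#'   flagged) — intended only for folding-free experiments.
#' @param y Optional named response vector (effect_log2 by uorf_id).
#' @param n_structures Structures sampled per uORF for ddg.
#' @return list(X, y, dropped)
#' @export
assemble_feature_matrix <- function(annotations, kozak_table, codon_weights,
                                    conservation = NULL, engine = toy_fold_engine(),
                                    y = NULL, n_structures = 100) {
  n <- nrow(annotations)
  fn <- uorf_feature_names()
  X <- matrix(NA_real_, n, length(fn), dimnames = list(annotations$uorf_id, fn))
  for (i in seq_len(n)) {
    a <- annotations[i, ]
    seqi <- a$wt_seq
    ks <- suppressWarnings(kozak_score(seqi, a$uorf_start, kozak_table))
    d <- positional_distances(a$leader_length, a$uorf_start, a$uorf_end)
    cds <- substr(seqi, a$uorf_start + 4, a$uorf_start + 3 + 3 * a$length_aa)
    pep <- translate_codons(cds)
    ddg <- if (is.null(engine)) 0 else
      ddg_unfolding(seqi, a$uorf_start, engine, n = n_structures)$ddg_median
    pc <- c(start = NA_real_, stop = NA_real_)
    if (is.data.frame(conservation)) {
      j <- match(a$uorf_id, conservation$uorf_id)
      pc <- c(start = conservation$phastcons_start[j],
              stop = conservation$phastcons_stop[j])
    } else if (is.list(conservation)) {
      pc <- c(start = phastcons_mean(conservation$track,
                                     a$uorf_start + 0:2, conservation$fallback),
              stop = phastcons_mean(conservation$track,
                                    (a$uorf_end - 3) + 0:2, conservation$fallback))
    }
    X[i, ] <- c(ks, d[1], d[2], a$length_aa, ddg,
                pct_au_downstream(seqi, a$uorf_end),
                if (nchar(cds)) cai(cds, codon_weights) else NA_real_,
                isoelectric_point(pep), pro_gly_frequency(pep),
                as.numeric(normalize_nt(a$stop_codon) == "TAG"),
                as.numeric(normalize_nt(a$stop_codon) == "TGA"),
                as.numeric(normalize_nt(a$stop_plus1) %in% c("A", "T")),
                pc["start"], pc["stop"],
                as.numeric(isTRUE(a$is_oorf == 1) || isTRUE(d[2] < 0)))
  }
  keep <- stats::complete.cases(X)
  dropped <- annotations$uorf_id[!keep]
  if (length(dropped)) {
    message("dropping ", length(dropped), " uORF(s) with missing features: ",
            paste(utils::head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ..." else "")
  }
  yk <- if (!is.null(y)) unname(y[annotations$uorf_id[keep]]) else NULL
  list(X = X[keep, , drop = FALSE], y = yk, dropped = dropped)
}
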