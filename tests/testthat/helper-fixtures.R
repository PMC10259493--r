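# shared fixtures and brute-force oracles

make_pairs <- function(lib) {
  ids <- unique(lib$pair_id)
  data.frame(uorf_id = ids,
             wt_id = paste0(ids, "_WT"),
             aag_id = paste0(ids, "_AAG"),
             stringsAsFactors = FALSE)
}

simulate_replicates <- function(gen, n_rep = 3, depth = 1e6, seed0 = 100,
                                strain = "wildtype", rna = FALSE, ...) {
  lapply(seq_len(n_rep), function(r) {
    f <- simulate_facs_counts(gen$library, gen$truth, depth = depth,
                              strain = strain, seed = seed0 + r, ...)
    if (rna) {
      f$rna_counts <- simulate_rna_counts(gen$library, gen$truth,
                                          strain = strain, depth = depth,
                                          seed = seed0 + 50 + r)
    }
    f
  })
}

# --- enumeration oracles ------------------------------------------------------

# Fisher 2x2 two-sided p by full hypergeometric enumeration
oracle_fisher_2x2 <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  amin <- max(0, r1 + c1 - n); amax <- min(r1, c1)
  probs <- stats::dhyper(amin:amax, c1, n - c1, r1)
  p_obs <- stats::dhyper(tab[1, 1], c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# exact binomial two-sided p by point-probability enumeration
oracle_binom <- function(k, n, p0 = 0.5) {
  probs <- stats::dbinom(0:n, n, p0)
  sum(probs[probs <= probs[k + 1] * (1 + 1e-7)])
}

# exact two-sided rank-sum p by enumeration of all group assignments
oracle_wrt <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(nx)])
  combos <- utils::combn(nx + ny, nx)
  ws <- apply(combos, 2, function(idx) sum(r[idx]))
  p_lo <- mean(ws <= w_obs); p_hi <- mean(ws >= w_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# CMH statistic by the textbook formula (continuity corrected, floored)
oracle_cmh <- function(strata) {
  dev <- 0; v <- 0
  for (s in strata) {
    n <- sum(s)
    dev <- dev + s[1, 1] - sum(s[1, ]) * sum(s[, 1]) / n
    v <- v + prod(rowSums(s)) * prod(colSums(s)) / (n^2 * (n - 1))
  }
  stat <- max(0, abs(dev) - 0.5)^2 / v
  stats::pchisq(stat, 1, lower.tail = FALSE)
}

# all non-crossing canonical pairings of a sequence (min_loop enforced),
# returned as pair-count-maximal set of canonical strings
oracle_max_pairings <- function(seq, min_loop = 3) {
  bases <- strsplit(gsub("U", "T", toupper(seq)), "")[[1]]
  pairable <- function(a, b) paste0(a, b) %in% c("AT", "TA", "GC", "CG", "GT", "TG")
  enum <- function(i, j) {
    if (j - i < min_loop + 1) return(list(matrix(integer(0), 0, 2)))
    out <- enum(i, j - 1)                      # j unpaired
    for (k in i:(j - min_loop - 1)) {
      if (!pairable(bases[k], bases[j])) next
      lefts <- if (k > i) enum(i, k - 1) else list(matrix(integer(0), 0, 2))
      rights <- if (k + 1 <= j - 1) enum(k + 1, j - 1) else list(matrix(integer(0), 0, 2))
      for (L in lefts) for (R in rights) {
        out[[length(out) + 1]] <- rbind(L, c(k, j), R)
      }
    }
    out
  }
  all_p <- enum(1L, length(bases))
  sizes <- vapply(all_p, nrow, integer(1))
  maxp <- all_p[sizes == max(sizes)]
  sort(unique(vapply(maxp, function(m) {
    m <- m[order(m[, 1]), , drop = FALSE]
    paste(paste(m[, 1], m[, 2], sep = "-"), collapse = ";")
  }, character(1))))
}

canonical_pairs <- function(m) {
  if (!nrow(m)) return("")
  m <- cbind(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2]))
  m <- m[order(m[, 1]), , drop = FALSE]
  paste(paste(m[, 1], m[, 2], sep = "-"), collapse = ";")
}
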