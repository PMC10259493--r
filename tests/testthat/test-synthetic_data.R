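test_that("library generation pairs constructs and is seed-deterministic", {
  spec <- library_spec(n_uorfs = 10, seed = 3)
  gen <- generate_reporter_library(spec)
  expect_equal(nrow(gen$library), 20)
  expect_equal(sum(gen$library$variant == "WT"), 10)
  wt <- gen$library[gen$library$variant == "WT", ]
  aag <- gen$library[match(paste0(wt$pair_id, "_AAG"), gen$library$construct_id), ]
  for (i in seq_len(nrow(wt))) {
    s <- wt$uorf_start[i]
    expect_equal(substr(aag$leader_seq[i], s + 1, s + 3), "AAG")
    # differs only at the start codon
    masked_wt <- wt$leader_seq[i]
    substr(masked_wt, s + 1, s + 3) <- "AAG"
    expect_equal(masked_wt, aag$leader_seq[i])
  }
  gen2 <- generate_reporter_library(library_spec(n_uorfs = 10, seed = 3))
  expect_identical(gen, gen2)
  expect_false(identical(
    gen, generate_reporter_library(library_spec(n_uorfs = 10, seed = 4))))
})

test_that("WT sequences contain the annotated start codon and no stray AUGs", {
  gen <- generate_reporter_library(library_spec(n_uorfs = 30, seed = 8))
  wt <- gen$library[gen$library$variant == "WT", ]
  ann <- gen$annotations
  for (i in seq_len(nrow(wt))) {
    s <- wt$uorf_start[i]
    expect_equal(substr(wt$leader_seq[i], s + 1, s + 3), ann$start_codon[i])
    hits <- gregexpr("ATG", wt$leader_seq[i], fixed = TRUE)[[1]]
    hits <- hits[hits > 0] - 1L
    if (ann$start_codon[i] == "ATG") expect_equal(hits, s)
    else expect_length(hits, 0)
  }
})

test_that("ground truth respects the pairing and effect conventions", {
  gen <- generate_reporter_library(library_spec(n_uorfs = 25, seed = 1))
  tr <- gen$truth
  aag <- tr[tr$variant == "AAG", ]
  expect_true(all(aag$true_effect_log2 == 0))
  wt <- tr[tr$variant == "WT", ]
  base <- aag$true_expression[match(wt$pair_id, aag$pair_id)]
  expect_equal(wt$true_expression,
               pmin(base * 2^wt$true_effect_log2, 1.2), tolerance = 1e-12)
  expect_true(all(tr$true_nmd_fraction >= 0 & tr$true_nmd_fraction <= 1))
  expect_true(all(tr$true_expression >= 0 & tr$true_expression <= 1.2))
})

test_that("a planted negative Kozak weight induces a negative feature-effect correlation", {
  spec <- library_spec(n_uorfs = 200, planted_weights = c(kozak_score = -1.0),
                       noise_sd = 0, intercept = 0, seed = 21)
  gen <- generate_reporter_library(spec)
  wt <- gen$truth[gen$truth$variant == "WT", ]
  r <- cor(gen$features$kozak_score, wt$true_effect_log2)
  expect_lt(r, 0)
})

test_that("impossible uORF geometry is rejected with a message", {
  expect_error(library_spec(n_uorfs = 5, leader_length_range = c(10, 12)),
               "too short")
  expect_error(library_spec(n_uorfs = 5,
                            planted_weights = c(not_a_feature = 1)),
               "unknown planted feature")
})

test_that("FACS simulation conserves depth and bins deterministically without noise", {
  gen <- generate_reporter_library(library_spec(n_uorfs = 20, seed = 5))
  f <- simulate_facs_counts(gen$library, gen$truth, depth = 5e4, seed = 9)
  expect_equal(sum(f$bin_counts[, -1]), 5e4)     # sorted bins sum to depth
  expect_equal(sum(f$bin_counts[, 1]), 5e4)      # bin0 pool at same depth
  f2 <- simulate_facs_counts(gen$library, gen$truth, depth = 5e4, seed = 9)
  expect_identical(f, f2)
  # zero sorting noise and gates bracketing one construct: all reads in bin 5
  tr <- gen$truth
  target <- which.min(abs(tr$true_expression - median(tr$true_expression)))
  e <- tr$true_expression[target]
  edges <- c(e - 0.04, e - 0.03, e - 0.02, e - 0.01, e + 0.01, e + 0.02,
             e + 0.03, e + 0.04)
  f0 <- simulate_facs_counts(gen$library, gen$truth, bin_edges = edges,
                             sort_noise_sd = 0, depth = 5e4, seed = 2)
  row <- f0$bin_counts[target, -1]
  other <- tr$true_expression[-target]
  if (all(abs(other - e) > 0.05)) {
    expect_equal(sum(row[-5]), 0)
  } else {
    expect_equal(unname(which.max(row)), 5)
  }
})

test_that("RNA simulation carries only the NMD component and conserves depth", {
  gen <- generate_reporter_library(library_spec(n_uorfs = 40, seed = 13))
  pairs <- make_pairs(gen$library)
  for (strain in c("wildtype", "upf1_delta")) {
    r <- simulate_rna_counts(gen$library, gen$truth, strain = strain,
                             depth = 4e6, seed = 3)
    expect_equal(sum(r), 4e6)
    ratio <- r[pairs$wt_id] / r[pairs$aag_id]
    nmd <- with(gen$truth, true_effect_log2 * true_nmd_fraction)[
      match(pairs$wt_id, gen$truth$construct_id)]
    expected <- if (strain == "wildtype") 2^nmd else rep(1, length(nmd))
    expect_equal(unname(log2(ratio)), unname(log2(expected)), tolerance = 0.15)
  }
})

test_that("polysome simulation reflects the TE component in the loading ratio", {
  gen <- generate_reporter_library(library_spec(n_uorfs = 40, seed = 17))
  pairs <- make_pairs(gen$library)
  pc <- simulate_polysome_counts(gen$library, gen$truth, depth = 6e6, seed = 31)
  expect_equal(sum(pc), 6e6)
  pooled <- pool_fractions(pc)
  te <- with(gen$truth, true_effect_log2 * (1 - true_nmd_fraction))[
    match(pairs$wt_id, gen$truth$construct_id)]
  eff <- vapply(seq_len(nrow(pairs)), function(i)
    loading_effect(pooled[pairs$wt_id[i], , 1], pooled[pairs$aag_id[i], , 1]),
    numeric(1))
  strong <- abs(te) > 0.5
  expect_true(all(sign(eff[strong]) == sign(te[strong])))
  expect_equal(eff, te, tolerance = 0.5)
})
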