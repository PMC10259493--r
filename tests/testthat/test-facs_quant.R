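test_that("rpm normalization conserves the million scale", {
  expect_equal(normalize_rpm(c(1, 1, 2)), c(250000, 250000, 500000))
  expect_equal(normalize_rpm(5), 1e6)
  set.seed(1)
  x <- rpois(100, 40)
  expect_equal(sum(normalize_rpm(x)), 1e6)
  expect_error(normalize_rpm(c(0, 0)), "all-zero")
})

test_that("RNA level is the rpm ratio with missing DNA flagged", {
  expect_equal(rna_level(200, 100), 2)
  expect_equal(rna_level(0, 100), 0)
  expect_equal(rna_level(c(10, 10), c(10, 10)), c(1, 1))
  expect_true(is.na(rna_level(5, 0)))
})

test_that("bin calibration divides by the maximum and is idempotent", {
  expect_equal(calibrate_bins(c(0.2, 0.4, 0.8)), c(0.25, 0.5, 1))
  v <- c(0.25, 0.5, 1)
  expect_equal(calibrate_bins(v), v)
  expect_equal(calibrate_bins(c(2, 2, 2)), c(1, 1, 1))
  expect_error(calibrate_bins(c(-1, 0)), "non-positive")
})

test_that("downsampling hits cell-proportional totals without upsampling", {
  m <- matrix(c(60, 40, 180, 120), 2, 2)  # reads [100, 300]
  out <- downsample_to_cell_proportions(m, c(50, 50), seed = 2)
  expect_equal(colSums(out), c(100, 100))
  expect_true(all(out <= m))
  # already-matched proportions are a fixed point (up to rounding)
  m2 <- matrix(c(50, 50, 150, 150), 2, 2)
  out2 <- downsample_to_cell_proportions(m2, c(100, 300), seed = 3)
  expect_true(all(abs(colSums(out2) / c(100, 300) -
                        sum(colSums(out2)) / 400) <= 1))
  expect_true(all(out2 <= m2))
})

test_that("downsampling preserves within-bin construct proportions in expectation", {
  m <- matrix(c(10, 30, 60, 200, 200, 0), 3, 2)
  acc <- matrix(0, 3, 2)
  n_seed <- 1000
  for (s in seq_len(n_seed)) {
    acc <- acc + downsample_to_cell_proportions(m, c(30, 70), seed = s)
  }
  acc <- acc / n_seed
  for (b in 1:2) {
    expect_equal(acc[, b] / sum(acc[, b]), m[, b] / sum(m[, b]),
                 tolerance = 0.02)
  }
})

test_that("weighted expression is the read-weighted bin mean and is bounded", {
  expect_equal(weighted_expression(c(0, 100, 0), c(0.1, 0.4, 1)), 0.4)
  expect_equal(weighted_expression(c(50, 50), c(0.2, 0.4)), 0.3)
  expect_equal(weighted_expression(c(10, 20, 70), c(0.1, 0.5, 1.0)), 0.81)
  expect_true(is.na(weighted_expression(c(0, 0), c(0.2, 0.4))))
  set.seed(8)
  for (i in 1:20) {
    n <- sample(0:50, 5); n[1] <- n[1] + 1
    y <- sort(runif(5))
    w <- weighted_expression(n, y)
    expect_gte(w, min(y)); expect_lte(w, max(y))
    expect_equal(w, sum(n * y) / sum(n))     # direct-summation oracle
  }
})

test_that("noise filter drops high-SD or weakly supported constructs", {
  yfp <- rbind(a = c(0.5, 0.5, 0.5), b = c(0.2, 0.2, 0.4), c = c(0.3, 0.31, 0.32))
  reads <- matrix(100, 3, 3, dimnames = list(rownames(yfp), NULL))
  keep <- filter_noisy(yfp, reads)
  expect_true(keep["a"]); expect_false(keep["b"]); expect_true(keep["c"])
  reads["c", 2] <- 49
  expect_false(filter_noisy(yfp, reads)["c"])
})

test_that("identical WT/AAG bin profiles give a null effect call", {
  yfp <- rbind(u1_WT = c(0.5, 0.5), u1_AAG = c(0.5, 0.5))
  bc <- matrix(c(40, 40, 60, 60), 2, 2,
               dimnames = list(c("u1_WT", "u1_AAG"), NULL))
  est <- list(yfp = yfp)
  pairs <- data.frame(uorf_id = "u1", wt_id = "u1_WT", aag_id = "u1_AAG")
  retained <- c(u1_WT = TRUE, u1_AAG = TRUE)
  eff <- compute_uorf_effects(est, list(bc, bc), list(c(0.3, 0.8), c(0.3, 0.8)),
                              pairs, retained)
  expect_equal(eff$effect_log2, 0)
  expect_false(eff$significant)
  expect_equal(eff$direction, "ns")
})

test_that("extreme bin separation is called a significant repressor", {
  yfp <- rbind(u1_WT = c(0.1, 0.1), u1_AAG = c(1, 1))
  bc <- rbind(u1_WT = c(500, 0), u1_AAG = c(0, 500))
  est <- list(yfp = yfp)
  pairs <- data.frame(uorf_id = "u1", wt_id = "u1_WT", aag_id = "u1_AAG")
  eff <- compute_uorf_effects(est, list(bc, bc), list(c(0.1, 1), c(0.1, 1)),
                              pairs, c(u1_WT = TRUE, u1_AAG = TRUE))
  expect_true(eff$significant)
  expect_equal(eff$direction, "repressor")
  expect_lt(eff$effect_log2, -3)
})

test_that("planted 2.8-fold repressors are recovered near -1.49 within a diverse library", {
  # effects centred on -log2(2.8) with realistic spread, so the gates face a
  # continuous expression distribution as in a real library
  spec <- library_spec(n_uorfs = 120, planted_weights = c(kozak_score = 0),
                       noise_sd = 0.35, intercept = -log2(2.8), seed = 77)
  gen <- generate_reporter_library(spec)
  pairs <- make_pairs(gen$library)
  reps <- simulate_replicates(gen, n_rep = 3, depth = 1e6, seed0 = 400)
  res <- facs_quant(reps, pairs, seed = 6)
  truth <- gen$truth$true_effect_log2[match(pairs$wt_id, gen$truth$construct_id)]
  near <- abs(truth + log2(2.8)) < 0.2        # the ~2.8-fold repressors
  expect_gt(sum(near), 20)
  est <- res$effects$effect_log2[near]
  expect_lt(abs(median(est, na.rm = TRUE) + log2(2.8)), 0.15)
  expect_lt(median(abs(est - truth[near]), na.rm = TRUE), 0.1)
})

test_that("high-depth noiseless simulation recovers expression within 0.02 on a fine gate grid", {
  gen <- generate_reporter_library(library_spec(n_uorfs = 50, seed = 19))
  rng <- range(gen$truth$true_expression)
  edges <- seq(rng[1] - 1e-6, rng[2] + 1e-6, length.out = 41)[2:40]
  f <- simulate_facs_counts(gen$library, gen$truth, n_bins = 40,
                            bin_edges = edges, sort_noise_sd = 0,
                            depth = 1e6, seed = 23)
  byfp <- calibrate_bins(f$bin_means)
  down <- downsample_to_cell_proportions(f$bin_counts[, -1], f$cells_sorted,
                                         seed = 4)
  yfp <- apply(down, 1, weighted_expression, bin_yfp = byfp)
  truth_scaled <- gen$truth$true_expression / max(f$bin_means)
  expect_lt(max(abs(yfp - truth_scaled), na.rm = TRUE), 0.02)
})
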