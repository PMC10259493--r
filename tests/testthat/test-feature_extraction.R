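test_that("Kozak lookup is exact, spelling-normalized, and guarded", {
  tab <- data.frame(context = c("AAAA", "CCCC"), start_codon = c("ATG", "TTG"),
                    plus1 = c("G", "A"), score = c(0.9, 0.2))
  expect_equal(kozak_score("AAAAATGG", 4, tab), 0.9)
  # U/T spelling is normalized both ways
  tab_u <- transform(tab, context = gsub("T", "U", context),
                     start_codon = gsub("T", "U", start_codon))
  expect_equal(kozak_score("ccccuugaCC", 4, tab_u), 0.2)
  expect_warning(ks <- kozak_score("GGGGATGG", 4, tab), "not in table")
  expect_true(is.na(ks))
  expect_warning(ks2 <- kozak_score("AAATGG", 3, tab), "too close")
  expect_true(is.na(ks2))
})

test_that("positional distances use 0-based half-open conventions", {
  d <- positional_distances(50, 0, 9)
  expect_equal(unname(d["dist_cap_start"]), 0)
  d2 <- positional_distances(40, 10, 30)
  expect_equal(unname(d2["dist_stop_cds"]), 10)
  # oORF: stop 12 nt into the CDS
  d3 <- positional_distances(40, 10, 52, cds_start = 40)
  expect_equal(unname(d3["dist_stop_cds"]), -12)
  expect_error(positional_distances(40, -1, 10), "outside")
})

test_that("%AU window covers the 9 nt after the stop and truncates", {
  s <- paste0(strrep("G", 10), "TAA", "AATTAATTA", "GG")
  expect_equal(pct_au_downstream(s, 13), 100)
  s2 <- paste0(strrep("A", 10), "TAA", "GCGCGCGCG")
  expect_equal(pct_au_downstream(s2, 13), 0)
  s3 <- paste0(strrep("G", 10), "TAA", "ATGCATGCA")
  expect_equal(pct_au_downstream(s3, 13), 100 * 5 / 9, tolerance = 1e-10)
  # truncation and empty window
  expect_equal(pct_au_downstream("GGGTAAAT", 6), 100)
  expect_true(is.na(pct_au_downstream("GGGTAA", 6)))
})

test_that("CAI is the geometric mean of codon weights", {
  w <- c(AAA = 1, GCT = 1, CCA = 0.5, GGT = 0.25)
  expect_equal(cai(c("AAA", "GCT"), w), 1)
  expect_equal(cai(c("CCA", "CCA"), w), 0.5)
  expect_equal(cai(c("AAA", "GGT"), w), 0.5)
  expect_equal(cai("AAACCA", w), sqrt(0.5))
  expect_true(is.na(cai("", w)))
  expect_error(cai("TTT", w), "missing from weight table")
  # identical codons: CAI equals that codon's weight exactly
  cw <- synthetic_codon_weights(3)
  for (cd in c("GCT", "CGA", "TTT")) {
    expect_equal(cai(strrep(cd, 7), cw), unname(cw[cd]), tolerance = 1e-12)
  }
})

test_that("isoelectric point matches closed-form and numeric references", {
  expect_equal(isoelectric_point("A"), (8.6 + 3.6) / 2, tolerance = 2e-3)
  expect_equal(isoelectric_point("K"), 9.7, tolerance = 0.1)
  expect_equal(isoelectric_point("D"), 3.75, tolerance = 0.1)
  # monotonicity: K never lowers pI, D never raises it
  set.seed(12)
  aas <- c("A", "G", "S", "K", "D", "E", "R", "H", "Y", "L")
  for (i in 1:10) {
    pep <- paste(sample(aas, 6, replace = TRUE), collapse = "")
    expect_gte(isoelectric_point(paste0(pep, "K")) + 1e-9,
               isoelectric_point(pep))
    expect_lte(isoelectric_point(paste0(pep, "D")) - 1e-9,
               isoelectric_point(pep))
  }
})

test_that("proline/glycine frequency is a simple proportion", {
  expect_equal(pro_gly_frequency("PPG"), 1)
  expect_equal(pro_gly_frequency("AAAA"), 0)
  expect_equal(pro_gly_frequency("PAGA"), 0.5)
})

test_that("conservation means fall back to the dataset average", {
  track <- c(`10` = 0.9, `11` = 0.9, `12` = 0.9, `20` = 0, `21` = 0.5, `22` = 1)
  expect_equal(phastcons_mean(track, 10:12, 0.4), 0.9)
  expect_equal(phastcons_mean(track, 20:22, 0.4), 0.5)
  expect_equal(phastcons_mean(track, 100:102, 0.4), 0.4)
  expect_equal(phastcons_mean(NULL, 1:3, 0.4), 0.4)
})

test_that("toy-engine unfolding energies follow the window rule", {
  eng <- toy_fold_engine()
  expect_equal(ddg_unfolding(strrep("A", 30), 10, eng)$ddg_median, 0)
  # hairpin of 5 pairs fully inside the window
  hp <- paste0("GGGGG", "AAA", "CCCCC")
  d <- ddg_unfolding(hp, 6, eng, window = c(0, 13))
  expect_equal(d$ddg_median, 5)
  # hairpin entirely outside the window costs nothing to keep folded
  far <- paste0(strrep("A", 40), "GGGGG", "TTT", "CCCCC")
  d2 <- ddg_unfolding(far, 5, eng, window = c(0, 15))
  expect_equal(d2$ddg_median, 0)
  expect_true(all(d2$ddg_values >= 0))
})

test_that("toy engine structures match brute-force maximal-pairing enumeration", {
  eng <- toy_fold_engine()
  set.seed(20)
  seqs <- c("GGGAAACCC", "GCAUGGCAAUCG", "AUGGCAAUAGCAUU",
            replicate(4, paste(sample(c("A", "C", "G", "U"), 14, replace = TRUE),
                               collapse = "")))
  for (s in seqs) {
    oracle <- oracle_max_pairings(s)
    got <- sort(unique(vapply(eng$sample_structures(s, 10000), canonical_pairs,
                              character(1))))
    expect_equal(got, oracle, info = s)
    # ddg is 0 iff no maximal pairing touches the window
    start <- floor(nchar(s) / 2)
    d <- ddg_unfolding(s, start, eng, n = 10000)
    expect_true(all(d$ddg_values >= 0))
  }
})

test_that("the assembled feature matrix has 15 stable columns and drops incomplete rows", {
  gen <- generate_reporter_library(library_spec(n_uorfs = 12,
                                                leader_length_range = c(40, 60),
                                                seed = 44))
  ann <- gen$annotations
  ann$wt_seq <- gen$library$leader_seq[match(paste0(ann$uorf_id, "_WT"),
                                             gen$library$construct_id)]
  cons <- data.frame(uorf_id = ann$uorf_id,
                     phastcons_start = gen$features$phastcons_start,
                     phastcons_stop = gen$features$phastcons_stop)
  fm <- assemble_feature_matrix(ann, synthetic_kozak_table(),
                                synthetic_codon_weights(),
                                conservation = cons,
                                engine = toy_fold_engine(), n_structures = 25)
  expect_equal(colnames(fm$X), uorf_feature_names())
  expect_equal(nrow(fm$X) + length(fm$dropped), nrow(ann))
  expect_true(all(stats::complete.cases(fm$X)))
  # a uORF with an unknown Kozak context is dropped and reported
  tiny_tab <- synthetic_kozak_table()[1, ]
  expect_message(
    fm2 <- suppressWarnings(
      assemble_feature_matrix(ann[1:3, ], tiny_tab, synthetic_codon_weights(),
                              conservation = cons, engine = toy_fold_engine(),
                              n_structures = 10)),
    "dropping")
  expect_true(length(fm2$dropped) >= 1)
})
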