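# Shared small simulation for the caller tests
sim <- generate_expression(tiny_spec(seed = 21))
cfg <- de_config()
signals <- summarize_signal(sim$matrix, "median")

test_that("signal summarizer computes median / trimmed mean per gene and sample", {
  sheet <- sheet_4x3(conditions = "G9", reps = 1)
  vals <- matrix(c(1, 2, 3, 4, 100), 5, 1, dimnames = list(NULL, sheet$sample_id))
  mat <- expr_matrix(vals, rep("g1", 5), sheet, probe_index = 1:5)
  expect_equal(unname(summarize_signal(mat, "median")$values[1, 1]), 3)
  expect_equal(unname(summarize_signal(mat, "trimmed_mean")$values[1, 1]),
               mean(c(1, 2, 3, 4, 100), trim = 0.1))
  # single-probe gene passes through as its own value
  one <- expr_matrix(matrix(7, 1, 1, dimnames = list(NULL, sheet$sample_id)),
                     "g1", sheet, probe_index = 1L, min_probes = 1)
  expect_equal(unname(summarize_signal(one, "median")$values[1, 1]), 7)
  # gene-level input is the identity
  expect_identical(summarize_signal(signals, "median"), signals)
})

test_that("zero-noise probe summaries recover the planted baseline exactly", {
  spec <- synthetic_spec(n_genes = 10, probes_per_gene = 11, noise_sd_log2 = 0,
                         probe_sd_log2 = 0, gene_sd_log2 = 0,
                         planted_blocks = list(), absent_fraction = 0,
                         categories = list(), symbol_assignments = NULL,
                         baseline_log2_mean = 8, seed = 2)
  s <- summarize_signal(generate_expression(spec)$matrix, "median")
  expect_equal(unname(s$values), matrix(256, 10, 12), tolerance = 1e-12)
})

test_that("detection calls separate expressed from background genes", {
  sheet <- sheet_4x3(conditions = "G9", reps = 1)
  bg <- 32
  at_bg <- expr_matrix(matrix(bg, 11, 1, dimnames = list(NULL, sheet$sample_id)),
                       rep("g1", 11), sheet, probe_index = 1:11)
  det <- detection_call(at_bg, bg)
  expect_equal(det$status, "Absent")
  expect_equal(det$detection_p, 1)

  high <- expr_matrix(matrix(bg * 16, 11, 1, dimnames = list(NULL, sheet$sample_id)),
                      rep("g1", 11), sheet, probe_index = 1:11)
  det2 <- detection_call(high, bg)
  expect_equal(det2$status, "Present")
  expect_equal(det2$detection_p, 2^-11, tolerance = 1e-15)  # minimal attainable

  # fewer than 3 probes: conservative Absent with a warning
  short <- expr_matrix(matrix(bg * 16, 2, 1, dimnames = list(NULL, sheet$sample_id)),
                       rep("g1", 2), sheet, probe_index = 1:2, min_probes = 2)
  expect_warning(det3 <- detection_call(short, bg), "fewer than 3")
  expect_equal(det3$status, c("Absent"))
})

test_that("planted absent genes are overwhelmingly called Absent", {
  spec <- tiny_spec(seed = 31, noise = 0.25, n_genes = 150)
  s <- generate_expression(spec)
  det <- detection_call(s$matrix, spec$background_level)
  absent_ids <- s$truth$gene_id[s$truth$absent]
  frac_absent <- mean(det$status[det$feature_id %in% absent_ids] == "Absent")
  expect_gte(frac_absent, 0.95)
  expressed_ids <- s$truth$gene_id[!s$truth$absent]
  expect_gte(mean(det$status[det$feature_id %in% expressed_ids] == "Present"), 0.99)
})

test_that("3 vs 3 replicates yield exactly nine pairwise calls per gene", {
  calls <- pairwise_change_calls(sim$matrix, "G9", "G22", cfg)
  expect_equal(as.vector(table(calls$feature_id)),
               rep(9L, length(unique(sim$matrix$feature_ids))))
  expect_error(pairwise_change_calls(sim$matrix, "G9", "XX", cfg), "unknown condition")
})

test_that("comparing a replicate with itself yields NoChange with p = 1", {
  mat <- sim$matrix
  # duplicate G9_r1 as the sole replicate of a fake reference condition
  sheet <- rbind(mat$samples,
                 data.frame(sample_id = "REF_r1", condition = "REF", replicate = 1))
  vals <- cbind(mat$values, REF_r1 = mat$values[, "G9_r1"])
  m2 <- expr_matrix(vals, mat$feature_ids, sheet, probe_index = mat$probe_index)
  calls <- pairwise_change_calls(m2, "G9", "REF", cfg)
  self <- calls[calls$sample_exp == "G9_r1", ]
  expect_true(all(self$direction == "NoChange"))
  expect_true(all(self$change_p == 1))
})

test_that("a planted four-fold gene under zero noise gives 9/9 Increase", {
  spec <- synthetic_spec(n_genes = 20, probes_per_gene = 11, noise_sd_log2 = 0,
                         planted_blocks = list(list(name = "G9_block",
                                                    conditions = "G9",
                                                    n_genes = 5,
                                                    effect_log2 = 2.0)),
                         absent_fraction = 0, categories = list(),
                         symbol_assignments = NULL, seed = 4)
  s <- generate_expression(spec)
  calls <- pairwise_change_calls(s$matrix, "G9", "S9", cfg)
  planted <- s$truth$gene_id[!is.na(s$truth$selective_condition)]
  for (g in planted) {
    expect_equal(sum(calls$direction[calls$feature_id == g] == "Increase"), 9)
  }
  other <- setdiff(unique(s$truth$gene_id), planted)
  expect_true(all(calls$direction[calls$feature_id %in% other] == "NoChange"))
})

test_that("concordance selection applies the 7-of-9 and two-fold rules", {
  expect_equal(required_concordant_count(9, 0.77), 7L)
  expect_equal(required_concordant_count(9, 0.60), 6L)
  expect_equal(required_concordant_count(10, 0.77), 8L)

  fake_calls <- function(n_inc, n_dec, n_no, fc, gene = "g1") {
    dirs <- rep(c("Increase", "Decrease", "NoChange"), c(n_inc, n_dec, n_no))
    calls <- data.frame(feature_id = gene,
                        sample_exp = paste0("A_r", seq_along(dirs)),
                        sample_ref = "B_r1",
                        direction = dirs,
                        change_p = ifelse(dirs == "NoChange", 0.8, 0.01),
                        stringsAsFactors = FALSE)
    attr(calls, "cond_exp") <- "A"; attr(calls, "cond_ref") <- "B"
    sheet <- data.frame(sample_id = c("A_r1", "B_r1"),
                        condition = c("A", "B"), replicate = 1)
    sig <- expr_matrix(matrix(c(fc * 100, 100), 1, 2,
                              dimnames = list(NULL, c("A_r1", "B_r1"))),
                       gene, sheet)
    concordance_select(calls, sig, cfg)
  }
  # 6 Increase / 3 NoChange at FC 3.1: below the 7-of-9 cutoff
  r <- fake_calls(6, 0, 3, 3.1)
  expect_false(r$selected)
  expect_equal(r$concordance, 6 / 9)
  # 8 Increase / 1 NoChange at FC 1.8: fails the two-fold filter
  r <- fake_calls(8, 0, 1, 1.8)
  expect_false(r$selected)
  # 7 of 9 at FC 2.5: selected Up
  r <- fake_calls(7, 0, 2, 2.5)
  expect_true(r$selected)
  expect_equal(r$direction, "Up")
  # counts always partition the pairs
  expect_equal(r$n_increase + r$n_decrease + r$n_nochange, r$n_pairs)
})

test_that("swapping conditions mirrors calls and inverts fold changes", {
  fwd <- concordance_select(pairwise_change_calls(sim$matrix, "G9", "G22", cfg),
                            signals, cfg)
  rev <- concordance_select(pairwise_change_calls(sim$matrix, "G22", "G9", cfg),
                            signals, cfg)
  expect_equal(fwd$n_increase, rev$n_decrease)
  expect_equal(fwd$n_decrease, rev$n_increase)
  # fold changes invert where the denominator floor never engages
  sam <- signals$samples
  m_g9 <- rowMeans(signals$values[, sam$sample_id[sam$condition == "G9"]])
  m_g22 <- rowMeans(signals$values[, sam$sample_id[sam$condition == "G22"]])
  ok <- m_g9 > 1 & m_g22 > 1
  expect_equal(fwd$fold_change[ok], 1 / rev$fold_change[ok], tolerance = 1e-9)
  up_fwd <- fwd$feature_id[fwd$selected & fwd$direction == "Up"]
  down_rev <- rev$feature_id[rev$selected & rev$direction == "Down"]
  expect_setequal(up_fwd, down_rev)
})

test_that("raising thresholds never enlarges the selected set", {
  calls <- pairwise_change_calls(sim$matrix, "G9", "G22", cfg)
  sel <- function(fc_thr, cutoff) {
    c2 <- de_config(fc_threshold = fc_thr, concordance_cutoff = cutoff)
    r <- concordance_select(calls, signals, c2)
    r$feature_id[r$selected]
  }
  base <- sel(2.0, 0.77)
  expect_true(all(sel(3.0, 0.77) %in% base))
  expect_true(all(sel(2.0, 0.89) %in% base))
  expect_true(all(sel(4.0, 1.0) %in% sel(2.0, 0.77)))
  expect_true(all(base %in% sel(1.5, 0.60)))
})

test_that("marker panel reports calls, detection counts and missing markers", {
  records <- concordance_select(pairwise_change_calls(sim$matrix, "G9", "G22", cfg),
                                signals, cfg)
  det <- detection_call(sim$matrix, tiny_spec()$background_level, cfg)
  up_gene <- records$feature_id[records$selected & records$direction == "Up"][1]
  absent_gene <- sim$truth$gene_id[sim$truth$absent][1]
  markers <- gene_set_collection(list(
    panel = c(up_gene, absent_gene, "not_on_array_1", "not_on_array_2")))
  mp <- marker_panel(records, det, markers, samples = sim$matrix$samples)
  expect_setequal(mp$not_represented, c("not_on_array_1", "not_on_array_2"))
  expect_equal(mp$report$call[mp$report$feature_id == up_gene], "Up")
  # an all-background gene is Absent in every replicate of every condition
  pres_cols <- grep("^present_", names(mp$report), value = TRUE)
  expect_equal(sum(unlist(mp$report[mp$report$feature_id == absent_gene, pres_cols])), 0)
})
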