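test_that("expression matrix round-trips through TSV at full precision", {
  sheet <- sheet_4x3()
  set.seed(1)
  vals <- matrix(rexp(4 * 12, rate = 1 / 200), 4, 12,
                 dimnames = list(NULL, sheet$sample_id))
  rownames(vals) <- NULL
  paths <- write_fixture_matrix(vals, sheet, feature_ids = paste0("g", 1:4))
  mat <- read_expression_matrix(paths[1], paths[2])
  expect_s3_class(mat, "expr_matrix")
  expect_equal(length(unique(mat$feature_ids)), 4)
  expect_equal(ncol(mat$values), 12)
  expect_identical(mat$feature_ids, paste0("g", 1:4))
  expect_equal(unname(mat$values), unname(vals), tolerance = 0)
  expect_false(is_probe_level(mat))
})

test_that("probe-level round-trip preserves probe index and row order", {
  sheet <- sheet_4x3(conditions = c("G9", "S9"), reps = 2)
  set.seed(2)
  vals <- matrix(runif(33 * 4, 10, 500), 33, 4,
                 dimnames = list(NULL, sheet$sample_id))
  fid <- rep(paste0("g", 1:3), each = 11)
  pidx <- rep(1:11, 3)
  paths <- write_fixture_matrix(vals, sheet, probe_index = pidx, feature_ids = fid)
  mat <- read_expression_matrix(paths[1], paths[2])
  expect_true(is_probe_level(mat))
  expect_identical(mat$probe_index, as.integer(pidx))
  expect_identical(mat$feature_ids, fid)
  expect_equal(sum(mat$feature_ids == "g2"), 11)
  # byte-identical determinism of the writer
  p2 <- tempfile(); p3 <- tempfile()
  write_expression_matrix(mat, p2, p3)
  expect_identical(readLines(p2), readLines(paths[1]))
})

test_that("reader rejects invariant violations", {
  sheet <- sheet_4x3(conditions = c("G9", "S9"), reps = 2)
  vals <- matrix(1:16, 4, 4, dimnames = list(NULL, sheet$sample_id))
  paths <- write_fixture_matrix(vals, sheet, feature_ids = paste0("g", 1:4))

  # header omits a sheet sample -> error names it
  tab <- read.delim(paths[1], check.names = FALSE)
  bad <- tempfile()
  write.table(tab[, setdiff(names(tab), "S9_r2")], bad, sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(read_expression_matrix(bad, paths[2]), "S9_r2")

  # negative intensity -> validation error with location
  tab2 <- tab; tab2[2, "G9_r1"] <- -5
  bad2 <- tempfile()
  write.table(tab2, bad2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_expression_matrix(bad2, paths[2]), "row 2.*G9_r1")

  # duplicated sample_id in sheet
  sheet2 <- sheet; sheet2$sample_id[2] <- sheet2$sample_id[1]
  expect_error(stageset:::validate_sample_sheet(sheet2), "duplicated sample_id")

  # duplicated (condition, replicate)
  sheet3 <- sheet; sheet3$replicate[2] <- 1
  expect_error(stageset:::validate_sample_sheet(sheet3), "condition, replicate")

  # probe-level feature with too few probes
  expect_error(
    expr_matrix(vals, rep(c("a", "b"), c(2, 2)), sheet,
                probe_index = c(1, 2, 1, 2), min_probes = 3),
    "fewer than 3 probes")
})

test_that("gene list and GMT readers parse, deduplicate and fail loudly", {
  lst <- tempfile()
  writeLines(sprintf("id%03d", 1:255), lst)
  gs <- read_gene_sets(lst, "list", name = "ssc")
  expect_length(gs$sets$ssc, 255)

  # duplicate collapsed with a warning
  writeLines(c(sprintf("id%03d", 1:9), "id001"), lst)
  expect_warning(gs2 <- read_gene_sets(lst, "list", name = "dup"), "duplicated")
  expect_length(gs2$sets$dup, 9)

  gmt <- tempfile()
  writeLines(c(paste(c("catA", "desc", paste0("a", 1:10)), collapse = "\t"),
               paste(c("catB", "desc", paste0("b", 1:20)), collapse = "\t")), gmt)
  gc <- read_gene_sets(gmt, "gmt")
  expect_equal(lengths(gc$sets), c(catA = 10L, catB = 20L))

  writeLines(c("ok\tdesc\tx1", "broken_line"), gmt)
  expect_error(read_gene_sets(gmt, "gmt"), "line 2")

  writeLines(character(0), lst)
  expect_error(read_gene_sets(lst, "list"), "empty")

  # GMT round-trip through the writer
  out <- tempfile()
  write_gmt(gc, out)
  expect_equal(read_gene_sets(out, "gmt")$sets, gc$sets)
})

test_that("pair table reader enforces non-empty unique rows", {
  p <- tempfile()
  writeLines(c("ligand\treceptor", "vegfc\tkdr", "edn1\tednrb"), p)
  tab <- read_pair_table(p, c("ligand", "receptor"))
  expect_equal(nrow(tab), 2)
  writeLines(c("ligand\treceptor", "vegfc\tkdr", "vegfc\tkdr"), p)
  expect_error(read_pair_table(p), "duplicate")
  writeLines(c("ligand\treceptor", "vegfc\t"), p)
  expect_error(read_pair_table(p), "empty")
})

test_that("write_results is deterministic with a complete manifest", {
  tabs <- list(
    hits = data.frame(feature_id = c("b", "a"), x = c(2, 1)),
    empty = data.frame(feature_id = character(0), x = numeric(0)),
    plain = data.frame(v = 1:3))
  d1 <- file.path(tempdir(), "res1"); d2 <- file.path(tempdir(), "res2")
  m1 <- write_results(tabs, d1)
  m2 <- write_results(tabs, d2)
  expect_equal(m1$rows[m1$file == "empty.tsv"], 0)
  expect_equal(nrow(m1), 3)
  for (f in m1$file) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  # rows sorted by feature_id
  hits <- read.delim(file.path(d1, "hits.tsv"))
  expect_equal(hits$feature_id, c("a", "b"))
  expect_equal(nrow(read.delim(file.path(d1, "empty.tsv"))), 0)
})

test_that("gene set collections validate names and universe membership", {
  expect_error(gene_set_collection(list(c("a"))), "names")
  expect_error(gene_set_collection(list(s1 = c("a", "z")), universe = c("a", "b")),
               "outside the universe")
  gc <- gene_set_collection(list(s1 = c("a", "a", "b")), universe = c("a", "b"))
  expect_equal(gc$sets$s1, c("a", "b"))
})
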