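test_that("hypergeometric tails match hand-enumerated values", {
  # N=10 genes, 5 in the category, cluster of 4, all 4 in the category:
  # P(X >= 4) = C(5,4)C(5,0)/C(10,4) = 5/210
  expect_equal(hypergeom_tail(10, 5, 4, 4, "upper"), 5 / 210, tolerance = 1e-12)
  # lower tail at k=0 is the point mass C(N-m, n)/C(N, n)
  expect_equal(hypergeom_tail(20, 6, 5, 0, "lower"),
               choose(14, 5) / choose(20, 5), tolerance = 1e-12)
  # upper tail at k=0 is certain
  expect_equal(hypergeom_tail(50, 10, 7, 0, "upper"), 1.0)
  expect_error(hypergeom_tail(10, 12, 4, 2, "upper"), "invalid")
  expect_error(hypergeom_tail(10, 5, 4, 5, "upper"), "invalid")
})

test_that("tails agree with full enumeration for N <= 60", {
  set.seed(707)
  for (rep in 1:40) {
    N <- sample(5:60, 1)
    m <- sample(0:N, 1)
    n <- sample(0:N, 1)
    k <- sample(0:min(m, n), 1)
    expect_equal(hypergeom_tail(N, m, n, k, "upper"),
                 oracle_hyper(N, m, n, k, "upper"), tolerance = 1e-10,
                 info = sprintf("N=%d m=%d n=%d k=%d", N, m, n, k))
    expect_equal(hypergeom_tail(N, m, n, k, "lower"),
                 oracle_hyper(N, m, n, k, "lower"), tolerance = 1e-10)
  }
})

test_that("inclusive tails satisfy p_upper + p_lower = 1 + P(X = k)", {
  for (case in list(c(30, 10, 8, 3), c(60, 20, 15, 7), c(12, 4, 6, 2))) {
    N <- case[1]; m <- case[2]; n <- case[3]; k <- case[4]
    expect_equal(hypergeom_tail(N, m, n, k, "upper") +
                   hypergeom_tail(N, m, n, k, "lower"),
                 1 + dhyper(k, m, N - m, n), tolerance = 1e-12)
  }
})

test_that("enrich reports m*n/N expectations and correct flags", {
  universe <- sprintf("u%03d", 1:100)
  categories <- gene_set_collection(list(
    at_expectation = universe[1:20],
    hot = universe[1:10],
    cold = universe[90:100]), universe = universe)
  # a cluster overlapping 'at_expectation' in exactly its random expectation
  cluster_exp <- c(universe[1:2], universe[41:48])
  at_exp <- enrich(cluster_exp, categories, universe = universe,
                   cluster_name = "test")
  at_exp <- at_exp[at_exp$category_name == "at_expectation", ]
  expect_equal(at_exp$expected, 20 * 10 / 100)
  expect_equal(at_exp$k, 2)  # k equals expectation -> no flag
  expect_equal(at_exp$flag, "none")
  # a cluster sitting entirely inside 'hot'
  cluster <- universe[1:10]
  res <- enrich(cluster, categories, universe = universe,
                cfg = enrich_config(), cluster_name = "test")
  hot <- res[res$category_name == "hot", ]
  expect_equal(hot$k, 10)
  expect_equal(hot$flag, "enriched")
  expect_lt(hot$p_enrich, 1e-10)
  # a disjoint category with large m*n/N is flagged depleted
  big_universe <- sprintf("u%03d", 1:120)
  cats2 <- gene_set_collection(list(big = big_universe[1:60]))
  res2 <- enrich(big_universe[61:120], cats2, universe = big_universe)
  expect_equal(res2$flag, "depleted")
  expect_lt(res2$p_deplete, 0.001)
  expect_error(enrich(cluster, categories, universe = character(0)), "empty universe")
})

test_that("cluster/category roles are symmetric in k, expectation and tails", {
  universe <- sprintf("u%03d", 1:80)
  set.seed(808)
  a <- sample(universe, 25)
  b <- sample(universe, 15)
  ra <- enrich(a, gene_set_collection(list(s = b)), universe = universe)
  rb <- enrich(b, gene_set_collection(list(s = a)), universe = universe)
  expect_equal(ra$k, rb$k)
  expect_equal(ra$expected, rb$expected)
  expect_equal(ra$p_enrich, rb$p_enrich, tolerance = 1e-12)
  expect_equal(ra$p_deplete, rb$p_deplete, tolerance = 1e-12)
})

test_that("overlap counts over a category partition sum to the cluster size", {
  universe <- sprintf("u%03d", 1:90)
  parts <- split(universe, rep(1:3, each = 30))
  names(parts) <- paste0("part", 1:3)
  cats <- gene_set_collection(parts)
  set.seed(909)
  cluster <- sample(universe, 40)
  res <- enrich(cluster, cats, universe = universe)
  expect_equal(sum(res$k), 40)
})

test_that("planted categories flag enriched against their selective set", {
  res <- run_pipeline(pipeline_config(synthetic = tiny_spec(seed = 21),
                                      crosstalk_between = character(0)))
  enr <- res$enrichment
  for (cc in c("G9", "S9", "G22", "S22")) {
    row <- enr[enr$cluster_name == paste0(cc, "_sel") &
                 enr$category_name == paste0("GO_", cc, "_program"), ]
    expect_equal(row$flag, "enriched")
    expect_lt(row$p_enrich, 0.001)
    expect_gte(row$k, 4)
  }
  null_rows <- enr[grepl("^GO_null", enr$category_name), ]
  expect_true(all(null_rows$flag != "enriched"))
})

test_that("list_overlap translates orthologs and handles empty lists", {
  universe <- sprintf("rat%02d", 1:50)
  clusters <- gene_set_collection(list(G9_sel = universe[1:10]))
  # identity-like map: human IDs to rat IDs one-to-one
  map <- data.frame(id_a = sprintf("hum%02d", 1:50),
                    id_b = universe, stringsAsFactors = FALSE)
  ext_human <- gene_set_collection(list(ssc = sprintf("hum%02d", 1:8)))
  ext_rat <- gene_set_collection(list(ssc = universe[1:8]))
  with_map <- list_overlap(clusters, ext_human, universe, ortholog_map = map)
  pre_translated <- list_overlap(clusters, ext_rat, universe)
  expect_equal(with_map$k, pre_translated$k)
  expect_equal(with_map$p_enrich, pre_translated$p_enrich, tolerance = 1e-12)
  expect_equal(with_map$n_unmapped, 0L)

  # fully contained external list on a small universe: enumerable tail
  res <- list_overlap(clusters, ext_rat, universe)
  expect_equal(res$k, 8)
  expect_equal(res$p_enrich, oracle_hyper(50, 8, 10, 8, "upper"), tolerance = 1e-10)
  expect_equal(res$expected, 8 * 10 / 50)

  # list that maps to nothing: error-free row with k = 0 and expected 0
  ext_orphan <- gene_set_collection(list(orphan = c("humXX", "humYY")))
  res2 <- list_overlap(clusters, ext_orphan, universe, ortholog_map = map)
  expect_equal(res2$k, 0)
  expect_equal(res2$expected, 0)
  expect_equal(res2$n_unmapped, 2L)
  # many-to-many: one gene counts once however many partners map to it
  map_m2m <- rbind(map, data.frame(id_a = "hum01b", id_b = universe[1]))
  ext_dup <- gene_set_collection(list(dup = c("hum01", "hum01b")))
  res3 <- list_overlap(clusters, ext_dup, universe, ortholog_map = map_m2m)
  expect_equal(res3$m, 1)
  expect_equal(res3$k, 1)
})
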