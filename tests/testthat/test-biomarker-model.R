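# Fusion, AUC, ranking, the feature-count sweep and task evaluation.
# Unit tests run with small forests; the full 5000-tree study conditions
# are exercised by the acceptance suite.

fused_fixture <- function(seed = 13, groups = c(Healthy = 20L, GD1 = 10L,
                                                GD2 = 20L)) {
  b <- generate_cohort(small_config(seed = seed, groups = groups))
  list(bundle = b,
       fused = fuse_layers(b$tables[c("species", "mag", "gene")], b$snps))
}

test_that("fusion concatenates CLR layers and binarizes SNPs", {
  fx <- fused_fixture()
  b <- fx$bundle; fused <- fx$fused
  expect_equal(ncol(fused), 25 + 30 + 40 + 30)
  lm <- attr(fused, "layer_map")
  expect_equal(as.integer(table(lm)[c("species", "mag", "gene", "snp")]),
               c(25L, 30L, 40L, 30L))
  snp_cols <- fused[, lm == "snp"]
  expect_true(all(snp_cols %in% c(0, 1)))
  expect_equal(unname(snp_cols), unname(snp_presence(b$snps)))
  # abundance blocks are CLR: zero row sums within each layer block
  for (layer in c("species", "mag", "gene")) {
    expect_true(all(abs(rowSums(fused[, lm == layer])) < 1e-9))
  }
  # binarization boundary: frequency 0 -> 0, any positive -> 1
  s <- snp_matrix(matrix(c(0, 0.001), 2, 1,
                         dimnames = list(c("a", "b"), "sp|l1")), "sp")
  expect_equal(unname(snp_presence(s)[, 1]), c(0L, 1L))
})

test_that("fusion uses the sample intersection and rejects empty overlap", {
  fx <- fused_fixture()
  t1 <- fx$bundle$tables$species
  t2 <- fx$bundle$tables$mag[1:10, ]
  expect_message(f <- fuse_layers(list(species = t1, mag = t2)), "shared")
  expect_equal(nrow(f), 10)
  t3 <- fx$bundle$tables$mag
  rownames(t3) <- paste0("X", rownames(t3))
  expect_error(fuse_layers(list(species = t1, mag = t3)), "intersection")
})

test_that("AUC matches concordance counting, including ties", {
  expect_equal(auc(c(0.9, 0.8, 0.3, 0.2), c(1, 0, 1, 0)), 0.75)
  expect_equal(auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(auc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  set.seed(17)
  for (i in 1:500) {
    n <- sample(4:20, 1)
    scores <- sample(round(rnorm(n), 1))  # ties likely
    pos <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(pos) || all(pos)) next
    expect_lt(abs(auc(scores, pos) - oracle_auc(scores, pos)), 1e-12)
  }
})

test_that("feature ranking is deterministic and recovers strong planted signal", {
  fx <- fused_fixture(seed = 23, groups = c(Healthy = 25L, GD1 = 10L,
                                            GD2 = 25L))
  grp <- group_vector(fx$fused, fx$bundle$metadata)
  r1 <- rank_features(fx$fused, grp, n_trees = 500, seed = 3)
  r2 <- rank_features(fx$fused, grp, n_trees = 500, seed = 3)
  expect_identical(r1, r2)
  planted <- fx$bundle$truth$planted_markers  # 4 per layer, 16 total
  planted_ids <- paste0(planted$layer, ":", planted$feature_id)
  top16 <- r1$fused_id[1:16]
  expect_gte(length(intersect(planted_ids, top16)), 10)
  expect_error(rank_features(fx$fused, rep("A", nrow(fx$fused))), "2 classes")
})

test_that("the sweep respects its grid contract", {
  fx <- fused_fixture(seed = 29)
  grp <- group_vector(fx$fused, fx$bundle$metadata)
  keep <- grp %in% c("Healthy", "GD2")
  f2 <- structure(fx$fused[keep, , drop = FALSE],
                  layer_map = attr(fx$fused, "layer_map"))
  rep1 <- sweep_feature_counts(f2, grp[keep], grid = c(2L),
                               n_trees = 200, seed = 5)
  expect_equal(nrow(rep1$sweep), 1L)
  expect_equal(rep1$chosen_n, 2L)
  expect_warning(
    rep2 <- sweep_feature_counts(f2, grp[keep], grid = c(4L, 1e6L),
                                 n_trees = 200, seed = 5),
    "dropping")
  expect_equal(rep2$sweep$n, 4L)
  expect_true(rep2$chosen_n %in% rep2$sweep$n)
  expect_equal(nrow(rep2$markers), rep2$chosen_n)
  expect_error(sweep_feature_counts(f2, grp[keep], grid = c(2L),
                                    n_trees = 200, n_folds = 50L),
               "smallest class")
})

test_that("task evaluation reports three reproducible AUCs", {
  fx <- fused_fixture(seed = 37, groups = c(Healthy = 20L, GD1 = 12L,
                                            GD2 = 20L))
  grp <- group_vector(fx$fused, fx$bundle$metadata)
  markers <- rank_features(fx$fused, grp, n_trees = 300, seed = 2)[1:12, ]
  e1 <- evaluate_tasks(fx$fused, grp, markers, n_trees = 300, seed = 8)
  e2 <- evaluate_tasks(fx$fused, grp, markers, n_trees = 300, seed = 8)
  expect_identical(e1, e2)
  expect_equal(e1$task, c("healthy_vs_gd2", "healthy_vs_gd1", "three_class"))
  expect_true(all(e1$auc >= 0 & e1$auc <= 1))
  expect_error(evaluate_tasks(fx$fused, grp, c("no_such:feature"),
                              n_trees = 100), "not in fused")
})

test_that("single-vs-combined comparison reports 4 + 1 models", {
  fx <- fused_fixture(seed = 41)
  cmp <- compare_single_vs_combined(fx$bundle, grid = c(2L, 8L),
                                    n_trees = 200, seed = 3)
  expect_equal(nrow(cmp$models), 5L)
  expect_setequal(cmp$models$model,
                  c("species", "mag", "gene", "snp", "combined"))
  expect_true(is.finite(cmp$gap))
})
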