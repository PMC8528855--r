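# Generator contracts: determinism, design defaults, compositional
# closure, planted-effect realization, null calibration, gene-hit fixtures.

test_that("default configuration reproduces the study design", {
  cfg <- cohort_config(seed = 1)
  expect_equal(unname(cfg$group_sizes), c(62L, 36L, 64L))
  expect_equal(sum(cfg$group_sizes), 162L)
  expect_equal(nrow(cfg$planted_markers), 32L)
  b <- generate_cohort(cfg)
  expect_equal(nrow(b$metadata), 162L)
  expect_equal(as.integer(table(b$metadata$group)[c("Healthy", "GD1", "GD2")]),
               c(62L, 36L, 64L))
})

test_that("identical config and seed give bit-identical bundles; seeds differ", {
  cfg <- small_config(seed = 5)
  b1 <- generate_cohort(cfg)
  b2 <- generate_cohort(cfg)
  expect_identical(serialize(b1, NULL), serialize(b2, NULL))
  b3 <- generate_cohort(small_config(seed = 6))
  expect_false(identical(b1$tables$species, b3$tables$species))
})

test_that("all tables share the same sample set and compositional layers close to 1", {
  b <- generate_cohort(small_config())
  ids <- b$metadata$sample_id
  for (layer in names(b$tables)) {
    expect_identical(rownames(b$tables[[layer]]), ids)
  }
  expect_identical(rownames(b$snps), ids)
  for (layer in c("species", "mag", "gene", "metabolite")) {
    expect_true(all(abs(rowSums(b$tables[[layer]]) - 1) < 1e-9),
                label = paste(layer, "rows sum to 1"))
  }
  expect_true(all(b$snps >= 0 & b$snps <= 1))
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(group_sizes = c(Healthy = 10L)), ">= 2 groups")
  expect_error(cohort_config(n_species = 0), "n_species")
  expect_error(cohort_config(group_sizes = c(A = 3L, B = -1L)), "B")
  bad <- default_planted_effects(4)
  bad$feature_id[1] <- "sp_999"
  bad2 <- small_config(planted = bad)
  bad2$planted_markers$feature_id[bad2$planted_markers$layer == "species"] <-
    sprintf("sp_%03d", 96:99)  # outside a 25-species layer
  # planted ids are relabelled into range by generate_cohort for the
  # default frames; an over-full layer must error
  over <- default_planted_effects(30)
  expect_error(generate_cohort(small_config(planted = over)),
               "more planted")
})

test_that("a null cohort carries no planted structure", {
  b <- generate_cohort(small_config(planted = null_planted(),
                                    seed = 21))
  tf <- monotonic_trend_filter(b$snps, b$metadata)
  expect_lte(nrow(tf), ceiling(0.02 * ncol(b$snps)) + 1)
  expect_equal(nrow(b$truth$planted_markers), 0L)
})

test_that("planted multiplicative folds are realized in group-mean ratios", {
  pm <- default_planted_effects(6, fold = 4)
  pm <- pm[pm$layer == "species", , drop = FALSE]
  cfg <- cohort_config(group_sizes = c(Healthy = 400L, GD1 = 2L, GD2 = 400L),
                       n_species = 100L, n_mags = 5L, n_genes = 5L,
                       n_metabolites = 5L,
                       n_snps_per_species = c(Bacteroides_vulgatus = 5L),
                       planted_markers = pm, seed = 101)
  b <- generate_cohort(cfg)
  grp <- b$metadata$group
  sp <- b$tables$species
  for (i in seq_len(nrow(b$truth$planted_markers))) {
    id <- b$truth$planted_markers$feature_id[i]
    f <- b$truth$planted_markers$effect_GD2[i]
    ratio <- mean(sp[grp == "GD2", id]) / mean(sp[grp == "Healthy", id])
    expect_lt(abs(ratio / f - 1), 0.25, label = sprintf("feature %s fold", id))
  }
})

test_that("rank-sum p-values are uniform under the group null", {
  cfg <- cohort_config(group_sizes = c(Healthy = 62L, GD2 = 64L),
                       n_species = 2000L, n_mags = 5L, n_genes = 5L,
                       n_metabolites = 5L,
                       n_snps_per_species = c(Bacteroides_vulgatus = 5L),
                       planted_markers = null_planted(), seed = 303)
  b <- generate_cohort(cfg)
  res <- differential_features(b$tables$species, b$metadata, "Healthy", "GD2")
  ks <- suppressWarnings(stats::ks.test(res$p, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("noise-free gene hits recover the truth map exactly", {
  truth <- setNames(c("genome_001", "genome_002", "unassigned", "genome_001"),
                    sprintf("mag_%03d", 1:4))
  hits <- generate_gene_hits(4, 10, 5, truth_assignment = truth,
                             true_fraction = 1, decoy_rate = 0,
                             subthreshold_rate = 0, seed = 2)
  expect_true(all(hits$pident == 100))
  expect_true(all(hits$coverage == 100))
  res <- assign_mags(hits)
  expect_identical(setNames(res$assigned_taxon, res$mag_id)[names(truth)],
                   truth)
})

test_that("a true fraction of exactly 0.8 leaves the MAG unassigned", {
  truth <- setNames("genome_001", "mag_001")
  hits <- generate_gene_hits(1, 10, 3, truth_assignment = truth,
                             true_fraction = 0.8, decoy_rate = 0,
                             subthreshold_rate = 0, seed = 3)
  res <- assign_mags(hits)
  expect_equal(res$assigned_taxon, "unassigned")
  expect_equal(res$supporting_fraction, 0.8)
})

test_that("rate arguments outside [0,1] are rejected", {
  expect_error(generate_gene_hits(2, 5, 3, true_fraction = 1.2), "rates")
})
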