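# Compositional transforms, distances, ordination, Mantel, PERMANOVA,
# Spearman network.

toy_table <- function(rows, ids = sprintf("S%d", seq_len(nrow(rows)))) {
  dimnames(rows) <- list(ids, sprintf("f%d", seq_len(ncol(rows))))
  rows
}

test_that("CLR has the closed-form values and zero row sums", {
  x <- toy_table(rbind(c(1, 3, 9), c(1, 1, 1)))
  clr <- clr_transform(x)
  expect_equal(clr[1, ], c(f1 = -log(3), f2 = 0, f3 = log(3)), tolerance = 1e-4)
  expect_equal(unname(clr[2, ]), c(0, 0, 0))
  set.seed(2)
  r <- toy_table(matrix(rexp(60), 6, 10))
  expect_true(all(abs(rowSums(clr_transform(r))) < 1e-9))
  # zeros handled by multiplicative replacement, still zero-sum and finite
  r[2, 3] <- 0
  clr0 <- clr_transform(r)
  expect_true(all(is.finite(clr0)))
  expect_true(all(abs(rowSums(clr0)) < 1e-9))
  expect_error(clr_transform(toy_table(rbind(c(0, 0, 0)))), "all-zero")
  expect_error(clr_transform(r, pseudocount_mode = "none"), "zeros")
})

test_that("Aitchison distance is scale-invariant with the closed-form toy value", {
  x <- toy_table(rbind(c(1, 3, 9), c(9, 3, 1), c(2, 6, 18)))
  d <- aitchison_distance(x)
  expect_equal(unname(d["S1", "S3"]), 0, tolerance = 1e-12)  # d(x, c*x) = 0
  expect_equal(unname(d["S1", "S2"]),
               sqrt((2 * log(3))^2 * 2), tolerance = 1e-3)   # 3.107
  expect_equal(unname(diag(d)), rep(0, 3))
  expect_equal(d, t(d))
})

test_that("Bray-Curtis matches hand computation and edge conventions", {
  x <- toy_table(rbind(c(1, 2, 3), c(3, 2, 1)))
  expect_equal(unname(bray_curtis(x)["S1", "S2"]), 1 / 3, tolerance = 1e-12)
  same <- toy_table(rbind(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(unname(bray_curtis(same)["S1", "S2"]), 0)
  disj <- toy_table(rbind(c(1, 1, 0, 0), c(0, 0, 2, 2)))
  expect_equal(unname(bray_curtis(disj)["S1", "S2"]), 1)
  zz <- toy_table(rbind(c(0, 0), c(0, 0), c(1, 1)))
  expect_warning(d <- bray_curtis(zz), "all-zero")
  expect_equal(unname(d["S1", "S2"]), 0)
})

test_that("distances satisfy triangle inequality on random compositions", {
  set.seed(5)
  x <- toy_table(matrix(rexp(8 * 12), 8, 12))
  for (d in list(aitchison_distance(x), bray_curtis(x))) {
    for (i in 1:8) for (j in 1:8) for (k in 1:8) {
      expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-12)
    }
  }
})

test_that("PCoA reproduces Euclidean-embeddable distances", {
  pts <- c(0, 1, 3)  # three points on a line
  d <- as.matrix(dist(pts))
  dimnames(d) <- list(sprintf("S%d", 1:3), sprintf("S%d", 1:3))
  ord <- pcoa(d)
  expect_equal(sum(ord$eigenvalues > 1e-8), 1)  # a line needs one axis
  rec <- as.matrix(dist(ord$coordinates))
  expect_equal(unname(rec), unname(d), tolerance = 1e-8)
  expect_true(all(ord$proportion_explained >= 0 &
                    ord$proportion_explained <= 1))
  expect_lte(sum(ord$proportion_explained), 1 + 1e-12)
  # duplicated sample -> coincident coordinates
  d2 <- as.matrix(dist(c(0, 0, 2, 5)))
  dimnames(d2) <- list(sprintf("S%d", 1:4), sprintf("S%d", 1:4))
  ord2 <- pcoa(d2)
  expect_lt(max(abs(ord2$coordinates["S1", ] - ord2$coordinates["S2", ])),
            1e-6)
  expect_error(pcoa(d, n_axes = 3), "n_axes")
})

test_that("Mantel r is exact for identical matrices and p matches enumeration", {
  set.seed(8)
  x <- toy_table(matrix(rexp(5 * 6), 5, 6))
  d1 <- aitchison_distance(x)
  expect_equal(mantel_test(d1, d1, n_perm = 99, seed = 1)$r, 1)
  y <- toy_table(matrix(rexp(5 * 6), 5, 6))
  d2 <- aitchison_distance(y)
  res <- mantel_test(d1, d2, n_perm = 999, seed = 4)
  p_exact <- oracle_mantel_p(d1, d2)
  mc_err <- sqrt(p_exact * (1 - p_exact) / 999)
  expect_lt(abs(res$p - p_exact), max(2 * mc_err, 2 / 999))
  expect_true(res$p > 0)  # (1+B)/(1+N) never exactly 0
  # cross-check the statistic against vegan's implementation
  ref <- vegan::mantel(as.dist(d1), as.dist(d2), permutations = 99)
  expect_equal(res$r, unname(ref$statistic), tolerance = 1e-12)
})

test_that("Mantel p is approximately uniform under independence", {
  set.seed(12)
  ps <- replicate(150, {
    d1 <- as.matrix(dist(rnorm(10)))
    d2 <- as.matrix(dist(rnorm(10)))
    mantel_test(d1, d2, n_perm = 199,
                seed = sample.int(1e6, 1))$p
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_lt(unname(ks$statistic), 0.12)
})

test_that("PERMANOVA R2 equals the direct SS decomposition on a 4-sample toy", {
  d <- matrix(c(0, 1, 8, 9,
                1, 0, 9, 8,
                8, 9, 0, 1,
                9, 8, 1, 0), 4, 4,
              dimnames = list(sprintf("S%d", 1:4), sprintf("S%d", 1:4)))
  labels <- c("A", "A", "B", "B")
  res <- permanova(d, labels, n_perm = 999, seed = 2)
  expect_equal(res$r2, oracle_permanova_r2(d, labels), tolerance = 1e-12)
  expect_gt(res$r2, 0.9)
  expect_true(res$p > 0)
  single <- permanova(d, rep("A", 4))
  expect_equal(single$r2, 0)
  expect_equal(single$p, 1)
})

test_that("PERMANOVA p is approximately uniform under random labels", {
  set.seed(31)
  ps <- replicate(150, {
    d <- as.matrix(dist(matrix(rnorm(12 * 3), 12, 3)))
    permanova(d, sample(rep(c("A", "B", "C"), 4)), n_perm = 199,
              seed = sample.int(1e6, 1))$p
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_lt(unname(ks$statistic), 0.12)
})

test_that("Spearman rho equals Pearson on midranks and known toy values", {
  set.seed(3)
  for (i in 1:100) {
    a <- round(rnorm(20), 1); b <- round(rnorm(20), 1)
    expect_equal(cor(a, b, method = "spearman"),
                 cor(rank(a), rank(b)), tolerance = 1e-12)
  }
  x <- matrix(c(1, 2, 3, 4, 2, 1, 4, 3, 4, 3, 2, 1), 4, 3,
              dimnames = list(sprintf("S%d", 1:4), c("a", "b", "c")))
  edges <- spearman_network(list(x), rho_min = 0, q_max = 1)
  e_ab <- edges[edges$node_a == "a" & edges$node_b == "b", ]
  expect_equal(e_ab$rho, 0.6)  # 1 - 6*4/(4*15) by the rank formula
  e_ac <- edges[edges$node_a == "a" & edges$node_b == "c", ]
  expect_equal(e_ac$rho, -1)
  expect_equal(e_ac$sign, "negative")
})

test_that("network thresholds and constant-feature handling work", {
  set.seed(9)
  n <- 40
  base <- rnorm(n)
  m <- cbind(up1 = base + rnorm(n, 0, 0.1), up2 = base + rnorm(n, 0, 0.1),
             anti = -base + rnorm(n, 0, 0.1), noise = rnorm(n),
             flat = rep(1, n))
  rownames(m) <- sprintf("S%02d", 1:n)
  expect_warning(edges <- spearman_network(list(m)), "constant")
  expect_true(all(abs(edges$rho) >= 0.3 & edges$q < 0.05))
  expect_false(any(edges$node_a == "flat" | edges$node_b == "flat"))
  e_anti <- edges[edges$node_a == "up1" & edges$node_b == "anti", ]
  expect_equal(e_anti$sign, "negative")
})
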