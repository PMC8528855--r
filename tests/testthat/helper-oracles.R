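# Independent oracles (brute force / enumeration) and small fixtures.
# These deliberately avoid the package's own code paths.

# Two-tailed rank-sum p by full enumeration of all label arrangements.
oracle_ranksum_p <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  idx <- utils::combn(length(pooled), n1)
  u_all <- apply(idx, 2, function(ii) sum(r[ii]) - n1 * (n1 + 1) / 2)
  p_low <- mean(u_all <= u_obs)
  p_high <- mean(u_all >= u_obs)
  min(1, 2 * min(p_low, p_high))
}

# AUC by explicit concordant-pair counting (ties count half).
oracle_auc <- function(scores, pos) {
  sp <- scores[pos]; sn <- scores[!pos]
  total <- 0
  for (a in sp) for (b in sn) total <- total + (a > b) + 0.5 * (a == b)
  total / (length(sp) * length(sn))
}

# MAG consensus by direct count-and-threshold on per-gene assignments.
oracle_mag_call <- function(assigned_genomes, n_genes) {
  hits <- assigned_genomes[assigned_genomes != "unassigned"]
  if (length(hits) == 0 || n_genes == 0) return("unassigned")
  tab <- sort(table(hits), decreasing = TRUE)
  if (as.numeric(tab[1]) / n_genes > 0.8) names(tab)[1] else "unassigned"
}

# Exact Mantel p over all permutations (n small).
oracle_mantel_p <- function(d1, d2) {
  n <- nrow(d1)
  v1 <- d1[upper.tri(d1)]
  r_obs <- cor(v1, d2[upper.tri(d2)])
  perms <- gtools_permutations(n)
  r_all <- apply(perms, 1, function(p) {
    dp <- d2[p, p]
    cor(v1, dp[upper.tri(dp)])
  })
  mean(r_all >= r_obs)
}

gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- gtools_permutations(n - 1)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    out <- rbind(out, cbind(i, sub + (sub >= i)))
  }
  out
}

# PERMANOVA R2 from the direct sum-of-squares decomposition.
oracle_permanova_r2 <- function(d, labels) {
  n <- nrow(d)
  ss_total <- sum(d[upper.tri(d)]^2) / n
  ss_within <- 0
  for (g in unique(labels)) {
    idx <- which(labels == g)
    dg <- d[idx, idx, drop = FALSE]
    ss_within <- ss_within + sum(dg[upper.tri(dg)]^2) / length(idx)
  }
  (ss_total - ss_within) / ss_total
}

# Small, fast cohort configuration for unit tests.
small_config <- function(seed = 11, planted = default_planted_effects(4),
                         groups = c(Healthy = 20L, GD1 = 15L, GD2 = 20L),
                         ...) {
  cohort_config(group_sizes = groups, n_species = 25L, n_mags = 30L,
                n_genes = 40L, n_metabolites = 12L,
                n_snps_per_species = c(Bacteroides_vulgatus = 20L,
                                       Eubacterium_rectale = 10L),
                planted_markers = planted,
                sequencing_depth_proxy = 2e4, seed = seed, ...)
}

null_planted <- function() default_planted_effects(1)[0, ]

# Close rows of a matrix to relative abundances.
close_rows <- function(m) m / rowSums(m)
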