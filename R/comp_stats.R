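# Compositional transforms, distances, ordination, matrix-correlation and
# variance-partitioning tests, and the Spearman co-occurrence network.

#' Centered log-ratio (CLR) transform
#'
#' Per sample: close the row to 1, replace zeros according to
#' `pseudocount_mode`, and return `log(x_i / g(x))` where `g` is the
#' geometric mean. Every output row sums to zero.
#'
#' Zero handling: `"multiplicative"` (default) sets zeros to a small
#' pseudocount delta and rescales the non-zero parts so the row still sums
#' to 1 (multiplicative replacement); `"additive"` adds delta everywhere;
#' `"none"` errors on any zero. Delta defaults to half the smallest
#' non-zero relative abundance in the table, which keeps the replacement
#' scale-aware.
#'
#' @param table a [feature_table()] or non-negative matrix.
#' @param pseudocount_mode `"multiplicative"`, `"additive"` or `"none"`.
#' @param delta pseudocount; `NULL` for the default above.
#' @return matrix of CLR values (same dimnames; `layer` attribute kept
#'   when input is a feature table).
#' @examples
#' clr_transform(matrix(c(1, 3, 9), 1, dimnames = list("s1", c("a", "b", "c"))))
#' @export
clr_transform <- function(table, pseudocount_mode = "multiplicative",
                          delta = NULL) {
  pseudocount_mode <- match.arg(pseudocount_mode,
                                c("multiplicative", "additive", "none"))
  x <- unclass(table)
  if (any(x < 0)) stopf("CLR requires non-negative abundances")
  rs <- rowSums(x)
  if (any(rs == 0)) {
    stopf("sample with all-zero row: %s", rownames(x)[which(rs == 0)[1]])
  }
  x <- x / rs  # close to relative abundances
  if (any(x == 0)) {
    if (pseudocount_mode == "none") {
      stopf("zeros present and pseudocount_mode = 'none'")
    }
    if (is.null(delta)) delta <- 0.5 * min(x[x > 0])
    if (pseudocount_mode == "multiplicative") {
      zero <- x == 0
      nz <- rowSums(zero)
      x <- x * pmax(1 - nz * delta, delta)  # shrink non-zeros, then fill zeros
      x[zero] <- delta
    } else {
      x <- x + delta
    }
    x <- x / rowSums(x)
  }
  lx <- log(x)
  out <- lx - rowMeans(lx)
  if (inherits(table, "feature_table")) attr(out, "layer") <- table_layer(table)
  out
}

#' Aitchison distance
#'
#' Euclidean distance between CLR-transformed samples; scale-invariant
#' (multiplying a sample by a positive constant leaves it unchanged).
#'
#' @inheritParams clr_transform
#' @return a symmetric `dist`-backed matrix with zero diagonal and sample
#'   IDs as dimnames.
#' @export
aitchison_distance <- function(table, pseudocount_mode = "multiplicative",
                               delta = NULL) {
  d <- as.matrix(stats::dist(clr_transform(table, pseudocount_mode, delta)))
  diag(d) <- 0
  d
}

#' Bray-Curtis dissimilarity
#'
#' `sum |x - y| / sum (x + y)` for every sample pair. A pair of all-zero
#' samples is defined to have distance 0 (with a warning).
#'
#' @param table non-negative samples x features matrix.
#' @return symmetric matrix with zero diagonal.
#' @export
bray_curtis <- function(table) {
  x <- unclass(table)
  if (any(x < 0)) stopf("Bray-Curtis requires non-negative abundances")
  # vegdist warns on empty rows; the all-zero convention is handled here
  d <- as.matrix(suppressWarnings(vegan::vegdist(x, method = "bray")))
  if (anyNA(d)) {
    warnf("all-zero sample pair(s); distance defined as 0")
    d[is.na(d)] <- 0
  }
  diag(d) <- 0
  d
}

check_distance <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) stopf("distance matrix must be square")
  if (max(abs(d - t(d))) > 1e-12) stopf("distance matrix must be symmetric")
  if (any(diag(d) != 0)) stopf("distance matrix diagonal must be zero")
  d
}

#' Principal coordinates analysis (PCoA)
#'
#' Metric multidimensional scaling: eigendecomposition of the
#' Gower-centered squared-distance matrix. Negative eigenvalues (possible
#' for non-Euclidean dissimilarities) are reported as-is and excluded from
#' the proportion-explained denominator; no Lingoes/Cailliez correction is
#' applied.
#'
#' @param d distance matrix (square symmetric, zero diagonal).
#' @param n_axes number of coordinate axes to return (default: all
#'   positive-eigenvalue axes, at most n-1).
#' @return list: `coordinates` (samples x axes), `eigenvalues` (all, in
#'   decreasing order), `proportion_explained` (per returned axis, relative
#'   to the positive-eigenvalue total).
#' @export
pcoa <- function(d, n_axes = NULL) {
  d <- check_distance(d)
  n <- nrow(d)
  if (!is.null(n_axes) && n_axes > n - 1) {
    stopf("n_axes must be <= n_samples - 1")
  }
  res <- suppressWarnings(stats::cmdscale(stats::as.dist(d), k = n - 1,
                                          eig = TRUE))
  eig <- sort(res$eig, decreasing = TRUE)
  pos_total <- sum(eig[eig > 0])
  k_pos <- ncol(res$points)
  k <- if (is.null(n_axes)) k_pos else min(n_axes, k_pos)
  coords <- res$points[, seq_len(k), drop = FALSE]
  colnames(coords) <- sprintf("PCo%d", seq_len(k))
  rownames(coords) <- rownames(d)
  list(coordinates = coords, eigenvalues = eig,
       proportion_explained = if (pos_total > 0)
         pmax(eig[seq_len(k)], 0) / pos_total else rep(0, k))
}

upper_vec <- function(d) d[upper.tri(d)]

#' Mantel test between two distance matrices
#'
#' Classical Mantel statistic: Pearson correlation of the off-diagonal
#' upper-triangle entries, with significance from joint row/column
#' permutations of the second matrix. The p-value uses the
#' `(1 + B) / (1 + N)` estimator and is therefore never exactly zero.
#'
#' @param d1,d2 distance matrices over the same samples (matching
#'   dimnames required when present).
#' @param n_perm number of permutations (>= 99).
#' @param seed integer seed for the permutations.
#' @return list: `r`, `p`, `n_perm`.
#' @export
mantel_test <- function(d1, d2, n_perm = 999, seed = 1L) {
  d1 <- check_distance(d1); d2 <- check_distance(d2)
  if (nrow(d1) != nrow(d2)) stopf("distance matrices must match in size")
  if (!is.null(rownames(d1)) && !is.null(rownames(d2))) {
    if (!all(rownames(d1) == rownames(d2))) {
      d2 <- d2[rownames(d1), rownames(d1)]  # errors if IDs mismatch
    }
  }
  if (n_perm < 99) stopf("'n_perm' must be >= 99")
  v1 <- upper_vec(d1)
  r_obs <- stats::cor(v1, upper_vec(d2))
  n <- nrow(d1)
  hits <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(n)
      stats::cor(v1, upper_vec(d2[idx, idx])) >= r_obs
    }, TRUE))
  })
  list(r = r_obs, p = (1 + hits) / (1 + n_perm), n_perm = as.integer(n_perm))
}

#' One-way PERMANOVA (Adonis)
#'
#' Partitions distance-matrix variance by a single grouping factor via
#' `vegan::adonis2`; R-squared is the between-group fraction of the total
#' sum of squared distances, the pseudo-F uses (k-1, n-k) degrees of
#' freedom, and the p-value comes from label permutations with the
#' `(1 + B) / (1 + N)` estimator. A single group returns R2 = 0, p = 1.
#'
#' @param d distance matrix.
#' @param labels group label per sample (in row order of `d`).
#' @param n_perm permutations (>= 99).
#' @param seed integer seed.
#' @return list: `r2` (in \[0, 1\]), `pseudo_f`, `p`, `df`.
#' @export
permanova <- function(d, labels, n_perm = 999, seed = 1L) {
  d <- check_distance(d)
  labels <- as.character(labels)
  if (length(labels) != nrow(d)) stopf("one label per sample required")
  if (length(unique(labels)) < 2L) {
    return(list(r2 = 0, pseudo_f = NA_real_, p = 1, df = c(0L, nrow(d) - 1L)))
  }
  if (n_perm < 99) stopf("'n_perm' must be >= 99")
  df <- data.frame(group = factor(labels))
  fit <- with_seed(seed, {
    # permute emits a console note when it enumerates all permutations
    suppressMessages(vegan::adonis2(stats::as.dist(d) ~ group, data = df,
                                    permutations = n_perm))
  })
  list(r2 = fit$R2[1], pseudo_f = fit$F[1], p = fit$`Pr(>F)`[1],
       df = c(fit$Df[1], fit$Df[2]))
}

#' Spearman correlation network
#'
#' All pairwise Spearman rank correlations (midrank ties) among a selected
#' set of features drawn from one or more tables (e.g. MAG markers,
#' metabolites and clinical indexes), with BH correction across all tested
#' pairs. Edges are kept when `|rho| >= rho_min` and `q < q_max`. Constant
#' features are skipped with a warning (rho undefined).
#'
#' @param tables list of [feature_table()]s / matrices sharing samples.
#' @param feature_subset character vector of feature IDs to include;
#'   `NULL` for all.
#' @param rho_min minimum absolute correlation (default 0.3).
#' @param q_max maximum BH q-value (default 0.05).
#' @return data.frame of edges: `node_a`, `node_b`, `rho`, `p`, `q`,
#'   `sign`.
#' @export
spearman_network <- function(tables, feature_subset = NULL, rho_min = 0.3,
                             q_max = 0.05) {
  if (!is.list(tables)) tables <- list(tables)
  shared <- Reduce(intersect, lapply(tables, rownames))
  if (length(shared) < 3L) stopf("need >= 3 shared samples across tables")
  mats <- lapply(tables, function(t) unclass(t)[shared, , drop = FALSE])
  m <- do.call(cbind, mats)
  if (!is.null(feature_subset)) {
    missing <- setdiff(feature_subset, colnames(m))
    if (length(missing)) stopf("unknown feature in subset: %s", missing[1])
    m <- m[, feature_subset, drop = FALSE]
  }
  if (ncol(m) < 2L) stopf("need >= 2 features for a network")
  const <- apply(m, 2, function(v) stats::var(v) == 0)
  if (any(const)) {
    warnf("skipping constant feature(s): %s",
          paste(colnames(m)[const], collapse = ", "))
    m <- m[, !const, drop = FALSE]
  }
  k <- ncol(m)
  pairs <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
  rho <- numeric(nrow(pairs)); pval <- numeric(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    a <- m[, pairs[i, 1]]; b <- m[, pairs[i, 2]]
    ct <- suppressWarnings(stats::cor.test(a, b, method = "spearman",
                                           exact = FALSE))
    rho[i] <- unname(ct$estimate); pval[i] <- ct$p.value
  }
  q <- stats::p.adjust(pval, method = "BH")
  out <- data.frame(node_a = colnames(m)[pairs[, 1]],
                    node_b = colnames(m)[pairs[, 2]],
                    rho = rho, p = pval, q = q,
                    sign = ifelse(rho >= 0, "positive", "negative"),
                    stringsAsFactors = FALSE)
  out <- out[abs(out$rho) >= rho_min & out$q < q_max, , drop = FALSE]
  rownames(out) <- NULL
  out
}
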