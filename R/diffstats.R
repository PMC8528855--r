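# Two-tailed rank-sum differential testing across layers and the
# monotonic-trend SNP marker filter: a locus is a marker iff both the
# healthy-vs-severe and mild-vs-severe comparisons reach p < alpha AND its
# three group mean frequencies are strictly ordered in one direction.

#' Two-tailed Wilcoxon/Mann-Whitney rank-sum test
#'
#' Midranks are used for ties. The p-value is exact (from the null
#' rank-sum distribution) when the pooled sample size is at most 12 and
#' there are no ties; otherwise the normal approximation with tie
#' correction and continuity correction is used. A comparison with zero
#' tie-corrected variance (all values identical) is defined to have
#' p = 1: the data carry no evidence of a difference.
#'
#' @param x,y numeric vectors (each length >= 1).
#' @return list with `statistic` (Mann-Whitney U for `x`), `p` (two-tailed),
#'   `mean_x`, `mean_y`, `direction` (`"up"` if `mean_y > mean_x`,
#'   `"down"` if lower, `"none"` if equal).
#' @examples
#' rank_sum_test(c(1, 2, 3), c(4, 5, 6))$p  # 0.1, exact
#' @export
rank_sum_test <- function(x, y) {
  if (length(x) < 1L || length(y) < 1L) stopf("both samples must be non-empty")
  if (anyNA(x) || anyNA(y)) stopf("missing values are not supported")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0
  if (!ties && n1 + n2 <= 12) {
    p_low <- stats::pwilcox(u, n1, n2)
    p_high <- stats::pwilcox(u - 1, n1, n2, lower.tail = FALSE)
    p <- min(1, 2 * min(p_low, p_high))
  } else {
    tie_tab <- table(r)
    nn <- n1 + n2
    sigma2 <- n1 * n2 / 12 *
      ((nn + 1) - sum(tie_tab^3 - tie_tab) / (nn * (nn - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- u - n1 * n2 / 2
      z <- z - sign(z) * 0.5  # continuity correction
      p <- min(1, 2 * stats::pnorm(-abs(z) / sqrt(sigma2)))
    }
  }
  mx <- mean(x); my <- mean(y)
  list(statistic = u, p = p, mean_x = mx, mean_y = my,
       direction = if (my > mx) "up" else if (my < mx) "down" else "none")
}

#' Per-feature differential testing between two groups
#'
#' Applies the two-tailed rank-sum test to every feature of a table,
#' comparing two named groups. Selection downstream uses raw p-values (as
#' in rank-sum screens of this design); Benjamini-Hochberg q-values are
#' reported alongside for transparency.
#'
#' @param table a [feature_table()] (or matrix), samples x features.
#' @param meta metadata with `sample_id` and `group`.
#' @param group_a,group_b group labels to compare (direction is reported
#'   for `group_b` relative to `group_a`).
#' @param alpha significance threshold used for the `significant` flag.
#' @return data.frame sorted by ascending p: `feature_id`, `statistic`,
#'   `p`, `q`, `mean_a`, `mean_b`, `direction`, `significant`.
#' @export
differential_features <- function(table, meta, group_a, group_b, alpha = 0.05) {
  grp <- group_vector(table, meta)
  for (g in c(group_a, group_b)) {
    if (sum(grp == g) < 2L) stopf("group '%s' needs >= 2 samples", g)
  }
  a <- unclass(table)[grp == group_a, , drop = FALSE]
  b <- unclass(table)[grp == group_b, , drop = FALSE]
  res <- lapply(seq_len(ncol(table)), function(j) {
    t <- rank_sum_test(a[, j], b[, j])
    data.frame(feature_id = colnames(table)[j], statistic = t$statistic,
               p = t$p, mean_a = t$mean_x, mean_b = t$mean_y,
               direction = t$direction, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$p < alpha
  out <- out[order(out$p, out$feature_id),
             c("feature_id", "statistic", "p", "q", "mean_a", "mean_b",
               "direction", "significant")]
  rownames(out) <- NULL
  out
}

#' Monotonic-trend SNP marker filter
#'
#' Selects loci whose mutational frequency changes consistently with
#' disease severity: a locus is returned iff (i) the healthy-vs-severe and
#' mild-vs-severe two-tailed rank-sum p-values are both strictly below
#' `alpha`, and (ii) its three group mean frequencies are strictly ordered
#' (healthy > mild > severe, or healthy < mild < severe). The
#' healthy-vs-mild p-value is computed and reported but is not part of the
#' selection rule. BH q-values over all tested loci are reported for
#' transparency; selection uses raw p.
#'
#' @param snps an [snp_matrix()].
#' @param meta metadata with `sample_id` and `group`.
#' @param alpha strict significance threshold (default 0.05).
#' @param groups length-3 character vector naming the healthy, mild and
#'   severe groups, in that order.
#' @param all_loci if `TRUE`, return every locus with a `selected` flag
#'   instead of markers only.
#' @return data.frame of markers: `snp_id`, `species`, `mean_H`,
#'   `mean_GD1`, `mean_GD2`, `p_h_gd1`, `p_h_gd2`, `p_gd1_gd2`, `q_h_gd2`,
#'   `q_gd1_gd2`, `ordering` (`"increasing"` / `"decreasing"`).
#' @export
monotonic_trend_filter <- function(snps, meta, alpha = 0.05,
                                   groups = c("Healthy", "GD1", "GD2"),
                                   all_loci = FALSE) {
  if (length(groups) != 3L) stopf("'groups' must name exactly three groups")
  grp <- group_vector(snps, meta)
  present <- intersect(groups, unique(grp))
  if (length(present) < 3L) {
    stopf("all three groups must be present (missing: %s)",
          paste(setdiff(groups, present), collapse = ", "))
  }
  h <- unclass(snps)[grp == groups[1], , drop = FALSE]
  g1 <- unclass(snps)[grp == groups[2], , drop = FALSE]
  g2 <- unclass(snps)[grp == groups[3], , drop = FALSE]
  sp <- snp_species(snps)
  rows <- lapply(seq_len(ncol(snps)), function(j) {
    t_h2 <- rank_sum_test(h[, j], g2[, j])
    t_12 <- rank_sum_test(g1[, j], g2[, j])
    t_h1 <- rank_sum_test(h[, j], g1[, j])
    m <- c(mean(h[, j]), mean(g1[, j]), mean(g2[, j]))
    inc <- m[1] < m[2] && m[2] < m[3]
    dec <- m[1] > m[2] && m[2] > m[3]
    data.frame(snp_id = colnames(snps)[j], species = unname(sp[j]),
               mean_H = m[1], mean_GD1 = m[2], mean_GD2 = m[3],
               p_h_gd1 = t_h1$p, p_h_gd2 = t_h2$p, p_gd1_gd2 = t_12$p,
               ordering = if (inc) "increasing" else if (dec) "decreasing"
                 else "none",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_h_gd2 <- stats::p.adjust(out$p_h_gd2, method = "BH")
  out$q_gd1_gd2 <- stats::p.adjust(out$p_gd1_gd2, method = "BH")
  out$selected <- out$p_h_gd2 < alpha & out$p_gd1_gd2 < alpha &
    out$ordering != "none"
  out <- out[, c("snp_id", "species", "mean_H", "mean_GD1", "mean_GD2",
                 "p_h_gd1", "p_h_gd2", "p_gd1_gd2", "q_h_gd2", "q_gd1_gd2",
                 "ordering", "selected")]
  rownames(out) <- NULL
  if (all_loci) out else out[out$selected, setdiff(names(out), "selected")]
}
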