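# Cross-cohort specificity of a marker set: per-cohort summaries of the
# total CLR-transformed marker abundance and pairwise cohort-vs-cohort
# discrimination by that score. CLR is computed per cohort (no
# cross-cohort normalisation), mirroring a per-cohort re-annotation
# workflow.

#' Build a cohort panel on a shared marker namespace
#'
#' Ensures every cohort table contains every marker column, zero-filling
#' markers absent from a cohort (the CLR pseudocount keeps the transformed
#' values finite).
#'
#' @param cohorts named list; each element a list with `table` (matrix /
#'   [feature_table()]) and `meta` (metadata data.frame) or just a table.
#' @param marker_ids character vector of marker feature IDs.
#' @return a `cohort_panel`: named list of `list(table, meta)` where every
#'   table contains all `marker_ids`.
#' @export
build_cohort_panel <- function(cohorts, marker_ids) {
  if (length(marker_ids) == 0) stopf("'marker_ids' must be non-empty")
  if (is.null(names(cohorts))) stopf("cohorts must be named")
  out <- lapply(names(cohorts), function(nm) {
    el <- cohorts[[nm]]
    if (!is.list(el) || is.null(el$table)) el <- list(table = el, meta = NULL)
    tab <- unclass(el$table)
    missing <- setdiff(marker_ids, colnames(tab))
    if (length(missing)) {
      fill <- matrix(0, nrow(tab), length(missing),
                     dimnames = list(rownames(tab), missing))
      tab <- cbind(tab, fill)
    }
    list(table = tab, meta = el$meta)
  })
  structure(stats::setNames(out, names(cohorts)),
            marker_ids = marker_ids, class = "cohort_panel")
}

#' Total CLR-transformed abundance of a marker set
#'
#' CLR-transforms the full table (so the marker columns are interpreted
#' against the whole composition) and sums the marker columns per sample.
#'
#' @param table non-negative abundance matrix containing every marker
#'   column.
#' @param marker_ids marker feature IDs.
#' @param pseudocount_mode,delta passed to [clr_transform()].
#' @return named numeric vector, one score per sample.
#' @export
marker_total_clr <- function(table, marker_ids,
                             pseudocount_mode = "multiplicative",
                             delta = NULL) {
  if (length(marker_ids) == 0) stopf("'marker_ids' must be non-empty")
  missing <- setdiff(marker_ids, colnames(table))
  if (length(missing)) stopf("marker absent from table: %s", missing[1])
  clr <- clr_transform(table, pseudocount_mode, delta)
  rowSums(clr[, marker_ids, drop = FALSE])
}

#' Cross-cohort marker specificity screen
#'
#' For each cohort, summarises the distribution of the total CLR marker
#' score (median and IQR, per cohort and per marker); for every cohort
#' pair, reports the AUC of the score as a discriminator (rows = positive
#' cohort), so `auc[a, b] + auc[b, a] = 1` exactly.
#'
#' @param panel a `cohort_panel` from [build_cohort_panel()].
#' @param marker_ids marker IDs; defaults to the panel's own.
#' @param min_samples cohorts with fewer samples are excluded with a
#'   warning (default 5).
#' @return list: `summary` (per-cohort data.frame), `marker_summary`
#'   (per cohort x marker), `auc` (cohort x cohort matrix, diagonal 0.5),
#'   `scores` (named list of per-sample scores).
#' @export
specificity_screen <- function(panel, marker_ids = NULL, min_samples = 5L) {
  if (is.null(marker_ids)) marker_ids <- attr(panel, "marker_ids")
  sizes <- vapply(panel, function(el) nrow(el$table), 1L)
  small <- sizes < min_samples
  if (any(small)) {
    warnf("excluding cohort(s) with < %d samples: %s", min_samples,
          paste(names(panel)[small], collapse = ", "))
    panel <- panel[!small]
  }
  if (length(panel) < 2L) stopf("need >= 2 cohorts after exclusions")
  scores <- lapply(panel, function(el) marker_total_clr(el$table, marker_ids))
  summary_df <- do.call(rbind, lapply(names(panel), function(nm) {
    s <- scores[[nm]]
    q <- stats::quantile(s, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(cohort = nm, n = length(s), median = q[2], iqr = q[3] - q[1],
               q1 = q[1], q3 = q[3], stringsAsFactors = FALSE)
  }))
  rownames(summary_df) <- NULL
  marker_summary <- do.call(rbind, lapply(names(panel), function(nm) {
    clr <- clr_transform(panel[[nm]]$table)
    do.call(rbind, lapply(marker_ids, function(mk) {
      v <- clr[, mk]
      q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
      data.frame(cohort = nm, marker = mk, median = q[2], iqr = q[3] - q[1],
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(marker_summary) <- NULL
  k <- length(panel)
  aucm <- matrix(0.5, k, k, dimnames = list(names(panel), names(panel)))
  for (a in seq_len(k)) {
    for (b in seq_len(k)) {
      if (a == b) next
      sa <- scores[[a]]; sb <- scores[[b]]
      aucm[a, b] <- auc(c(sa, sb),
                        c(rep(TRUE, length(sa)), rep(FALSE, length(sb))),
                        positive = "TRUE")
    }
  }
  list(summary = summary_df, marker_summary = marker_summary, auc = aucm,
       scores = scores)
}
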