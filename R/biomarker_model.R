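# Four-layer feature fusion, random-forest importance ranking, the
# feature-count sweep with fivefold cross-validation and a 50-50 holdout,
# and rank-based ROC/AUC evaluation.
#
# Feature selection is re-done inside every cross-validation training fold
# (and inside the training half of the 50-50 split): ranking features on
# the full data set before cross-validating leaks the test folds into the
# selection and inflates the null AUC. The full-data ranking is still what
# the reported marker set is drawn from.

#' Fuse feature layers into one classifier table
#'
#' Abundance layers are CLR-transformed per layer and concatenated; SNP
#' columns are binarized to presence/absence (frequency > 0). Columns are
#' prefixed `"<layer>:"` and each carries its provenance in the
#' `layer_map` attribute. Samples are the intersection across layers, in
#' the order of the first table.
#'
#' @param tables named list of [feature_table()]s (abundance layers).
#' @param snps optional [snp_matrix()].
#' @param snp_mode `"presence"` (default) or `"frequency"`.
#' @param pseudocount_mode passed to [clr_transform()].
#' @return fused numeric matrix with a `layer_map` attribute.
#' @export
fuse_layers <- function(tables, snps = NULL, snp_mode = "presence",
                        pseudocount_mode = "multiplicative") {
  snp_mode <- match.arg(snp_mode, c("presence", "frequency"))
  if (length(tables) == 0 && is.null(snps)) stopf("no layers to fuse")
  sample_sets <- c(lapply(tables, rownames),
                   if (!is.null(snps)) list(rownames(snps)))
  shared <- Reduce(intersect, sample_sets)
  if (length(shared) == 0) stopf("empty sample intersection across layers")
  if (length(shared) < max(lengths(sample_sets))) {
    message(sprintf("fusing over %d shared samples (layers have up to %d)",
                    length(shared), max(lengths(sample_sets))))
  }
  parts <- list(); layer_map <- character()
  for (layer in names(tables)) {
    m <- clr_transform(tables[[layer]], pseudocount_mode)[shared, , drop = FALSE]
    colnames(m) <- paste0(layer, ":", colnames(m))
    parts[[layer]] <- m
    layer_map <- c(layer_map, stats::setNames(rep(layer, ncol(m)), colnames(m)))
  }
  if (!is.null(snps)) {
    s <- if (snp_mode == "presence") snp_presence(snps) else unclass(snps)
    s <- s[shared, , drop = FALSE]
    colnames(s) <- paste0("snp:", colnames(s))
    parts$snp <- s
    layer_map <- c(layer_map, stats::setNames(rep("snp", ncol(s)), colnames(s)))
  }
  fused <- do.call(cbind, parts)
  if (anyDuplicated(colnames(fused))) {
    stopf("duplicate (layer, feature) pair: %s",
          colnames(fused)[duplicated(colnames(fused))][1])
  }
  structure(fused, layer_map = layer_map)
}

order_groups <- function(labels) {
  u <- unique(as.character(labels))
  std <- intersect(c("Healthy", "GD1", "GD2"), u)
  if (length(std) == length(u)) std else sort(u)
}

rf_fit <- function(x, y, n_trees, seed, importance = "none",
                   probability = FALSE) {
  ranger::ranger(x = as.data.frame(x), y = y, num.trees = n_trees,
                 importance = importance, probability = probability,
                 seed = seed, num.threads = 1)
}

rf_prob <- function(fit, x) {
  stats::predict(fit, data = as.data.frame(x), num.threads = 1)$predictions
}

#' Rank fused features by random-forest importance
#'
#' Fits a random forest (impurity/Gini importance by default, permutation
#' importance optional) and returns features in decreasing importance.
#' Deterministic given `seed` (single-threaded).
#'
#' @param fused matrix from [fuse_layers()].
#' @param labels class label per sample.
#' @param n_trees number of trees (default 5000).
#' @param seed integer seed.
#' @param importance `"impurity"` or `"permutation"`.
#' @return marker-set data.frame: `fused_id`, `feature_id`, `layer`,
#'   `importance`, `rank`, `direction` (sign of the mean change from the
#'   first to the last group in severity order).
#' @export
rank_features <- function(fused, labels, n_trees = 5000, seed = 1L,
                          importance = "impurity") {
  importance <- match.arg(importance, c("impurity", "permutation"))
  y <- factor(as.character(labels))
  if (nlevels(y) < 2L) stopf("need >= 2 classes to rank features")
  check_count(n_trees, "n_trees")
  fit <- rf_fit(fused, y, n_trees, seed, importance = importance)
  imp <- fit$variable.importance
  ord <- order(-imp, names(imp))
  # layer provenance is encoded in the "<layer>:<feature>" column names,
  # so subsets of a fused table remain self-describing
  go <- order_groups(labels)
  first <- as.character(labels) == go[1]
  last <- as.character(labels) == go[length(go)]
  delta <- colMeans(fused[last, , drop = FALSE]) -
    colMeans(fused[first, , drop = FALSE])
  out <- data.frame(
    fused_id = names(imp)[ord],
    feature_id = sub("^[^:]*:", "", names(imp)[ord]),
    layer = sub(":.*$", "", names(imp)[ord]),
    importance = unname(imp[ord]),
    rank = seq_along(imp),
    direction = ifelse(delta[ord] > 0, "up",
                       ifelse(delta[ord] < 0, "down", "none")),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Rank-based AUC
#'
#' Area under the ROC curve computed as the Mann-Whitney concordance
#' probability with midrank tie handling. Equal scores contribute half a
#' concordant pair; all-tied scores give 0.5.
#'
#' @param scores numeric classifier scores (higher = more positive).
#' @param labels binary labels.
#' @param positive the positive label; defaults to `TRUE`, `1`, or the
#'   last sorted level.
#' @return AUC in \[0, 1\].
#' @examples
#' auc(c(0.9, 0.8, 0.3, 0.2), c(1, 0, 1, 0))  # 0.75
#' @export
auc <- function(scores, labels, positive = NULL) {
  labels <- as.character(labels)
  u <- sort(unique(labels))
  if (length(u) != 2L) stopf("AUC needs exactly two classes present")
  if (is.null(positive)) {
    positive <- if ("TRUE" %in% u) "TRUE" else if ("1" %in% u) "1" else u[2]
  }
  pos <- labels == as.character(positive)
  n1 <- sum(pos); n0 <- sum(!pos)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Macro one-vs-rest AUC from a class-probability matrix.
macro_ovr_auc <- function(prob, labels) {
  labels <- as.character(labels)
  classes <- colnames(prob)
  mean(vapply(classes, function(cl) {
    auc(prob[, cl], labels == cl, positive = "TRUE")
  }, 1))
}

# Stratified k-fold assignment, deterministic given seed.
stratified_folds <- function(labels, k, seed) {
  labels <- as.character(labels)
  if (min(table(labels)) < k) stopf("n_folds exceeds the smallest class size")
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

# Stratified split: TRUE = training half.
stratified_split <- function(labels, frac, seed) {
  labels <- as.character(labels)
  train <- logical(length(labels))
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      train[idx[seq_len(max(1L, round(frac * length(idx))))]] <- TRUE
    }
  })
  train
}

auc_from_prob <- function(prob, labels) {
  if (length(unique(labels)) == 2L) {
    go <- order_groups(labels)
    auc(prob[, go[length(go)]], labels == go[length(go)], positive = "TRUE")
  } else {
    macro_ovr_auc(prob, labels)
  }
}

#' Feature-count sweep
#'
#' For each feature count `n` in the grid, evaluates a random forest
#' restricted to the top-`n` features under (a) stratified fivefold
#' cross-validation — features re-ranked within each training fold, AUC
#' pooled over out-of-fold predictions — and (b) a stratified 50-50
#' train/test split. The chosen `n` maximises the pooled CV AUC, ties
#' broken to the smallest `n`. For two-class labels the AUC is binary; for
#' more classes it is macro one-vs-rest.
#'
#' @param fused matrix from [fuse_layers()].
#' @param labels class label per sample.
#' @param grid candidate feature counts (entries beyond the number of
#'   features are dropped with a warning).
#' @param n_trees,n_folds,seed random-forest and CV settings.
#' @param ranked optional precomputed full-data ranking (from
#'   [rank_features()]); computed internally when `NULL`. Used only for
#'   the reported marker set, never inside the cross-validation.
#' @return a `model_report` list: `sweep` (per-n data.frame with pooled CV
#'   AUC, per-fold mean and sd, holdout AUC), `chosen_n`, `markers` (top
#'   chosen-n rows of the full-data ranking), `cv_auc`, `holdout_auc`,
#'   `n_trees`, `n_folds`, `seed`, `classes`.
#' @export
sweep_feature_counts <- function(fused, labels,
                                 grid = c(2L, 4L, 8L, 16L, 32L, 64L, 128L, 256L),
                                 n_trees = 5000, n_folds = 5L, seed = 1L,
                                 ranked = NULL) {
  y <- factor(as.character(labels))
  if (nlevels(y) < 2L) stopf("need >= 2 classes")
  grid <- sort(unique(as.integer(grid)))
  if (any(grid > ncol(fused))) {
    warnf("dropping grid entries beyond %d features: %s", ncol(fused),
          paste(grid[grid > ncol(fused)], collapse = ", "))
    grid <- grid[grid <= ncol(fused)]
  }
  if (length(grid) == 0) stopf("empty sweep grid after dropping oversized entries")
  seeds <- derive_seeds(seed, n_folds + 3L)
  fold <- stratified_folds(y, n_folds, seeds[n_folds + 1L])

  oof <- array(NA_real_, dim = c(length(y), nlevels(y), length(grid)),
               dimnames = list(rownames(fused), levels(y), NULL))
  fold_auc <- matrix(NA_real_, n_folds, length(grid))
  for (f in seq_len(n_folds)) {
    tr <- fold != f
    rk <- rank_features(structure(fused[tr, , drop = FALSE],
                                  layer_map = attr(fused, "layer_map")),
                        y[tr], n_trees = n_trees, seed = seeds[f])
    for (gi in seq_along(grid)) {
      cols <- rk$fused_id[seq_len(grid[gi])]
      fit <- rf_fit(fused[tr, cols, drop = FALSE], y[tr], n_trees,
                    seeds[f], probability = TRUE)
      prob <- rf_prob(fit, fused[!tr, cols, drop = FALSE])
      oof[!tr, , gi] <- prob[, levels(y)]
      fold_auc[f, gi] <- auc_from_prob(
        prob[, levels(y), drop = FALSE], as.character(y[!tr]))
    }
  }
  cv_auc <- vapply(seq_along(grid), function(gi) {
    auc_from_prob(oof[, , gi, drop = TRUE], as.character(y))
  }, 1)

  # 50-50 stratified holdout, ranking on the training half only
  tr <- stratified_split(y, 0.5, seeds[n_folds + 2L])
  rk_half <- rank_features(structure(fused[tr, , drop = FALSE],
                                     layer_map = attr(fused, "layer_map")),
                           y[tr], n_trees = n_trees, seed = seeds[n_folds + 3L])
  holdout <- vapply(seq_along(grid), function(gi) {
    cols <- rk_half$fused_id[seq_len(grid[gi])]
    fit <- rf_fit(fused[tr, cols, drop = FALSE], y[tr], n_trees,
                  seeds[n_folds + 3L], probability = TRUE)
    prob <- rf_prob(fit, fused[!tr, cols, drop = FALSE])
    auc_from_prob(prob[, levels(y), drop = FALSE], as.character(y[!tr]))
  }, 1)

  chosen <- grid[which.max(cv_auc)]  # which.max takes the first (smallest) tie
  if (is.null(ranked)) {
    ranked <- rank_features(fused, y, n_trees = n_trees, seed = seed)
  }
  structure(list(
    sweep = data.frame(n = grid, cv_auc = cv_auc,
                       cv_auc_mean = colMeans(fold_auc),
                       cv_auc_sd = apply(fold_auc, 2, stats::sd),
                       holdout_auc = holdout),
    chosen_n = chosen,
    markers = ranked[seq_len(chosen), ],
    cv_auc = cv_auc[match(chosen, grid)],
    holdout_auc = holdout[match(chosen, grid)],
    n_trees = n_trees, n_folds = n_folds, seed = as.integer(seed),
    classes = levels(y)), class = "model_report")
}

#' @export
print.model_report <- function(x, ...) {
  cat(sprintf("<model_report> classes: %s; chosen n = %d (CV AUC %.3f, holdout %.3f)\n",
              paste(x$classes, collapse = "/"), x$chosen_n, x$cv_auc,
              x$holdout_auc))
  print(x$sweep, row.names = FALSE)
  invisible(x)
}

#' Evaluate a fixed marker set on the three classification tasks
#'
#' Healthy vs severe (GD2), healthy vs mild (GD1) — binary AUC — and the
#' three-class task (macro one-vs-rest AUC), each with a stratified 50-50
#' train/test split using only the marker columns.
#'
#' @param fused matrix from [fuse_layers()].
#' @param labels three-group labels.
#' @param markers marker set from [rank_features()] /
#'   [sweep_feature_counts()], or a character vector of fused column IDs.
#' @param n_trees,seed random-forest settings.
#' @param groups healthy / mild / severe group names.
#' @return data.frame: `task`, `auc`, `n_train`, `n_test`.
#' @export
evaluate_tasks <- function(fused, labels, markers, n_trees = 5000, seed = 1L,
                           groups = c("Healthy", "GD1", "GD2")) {
  cols <- if (is.data.frame(markers)) markers$fused_id else as.character(markers)
  missing <- setdiff(cols, colnames(fused))
  if (length(missing)) stopf("marker not in fused table: %s", missing[1])
  labels <- as.character(labels)
  if (!all(groups %in% labels)) {
    stopf("missing group: %s", setdiff(groups, labels)[1])
  }
  tasks <- list(healthy_vs_gd2 = c(groups[1], groups[3]),
                healthy_vs_gd1 = c(groups[1], groups[2]),
                three_class = groups)
  seeds <- derive_seeds(seed, length(tasks))
  out <- do.call(rbind, lapply(seq_along(tasks), function(i) {
    keep <- labels %in% tasks[[i]]
    y <- factor(labels[keep], levels = tasks[[i]])
    x <- fused[keep, cols, drop = FALSE]
    tr <- stratified_split(y, 0.5, seeds[i])
    fit <- rf_fit(x[tr, , drop = FALSE], droplevels(y[tr]), n_trees,
                  seeds[i], probability = TRUE)
    prob <- rf_prob(fit, x[!tr, , drop = FALSE])
    data.frame(task = names(tasks)[i],
               auc = auc_from_prob(prob, as.character(y[!tr])),
               n_train = sum(tr), n_test = sum(!tr),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Compare single-layer models with the combined model
#'
#' Runs the full feature-count sweep on each layer alone (species, MAG,
#' gene as CLR tables; SNPs as presence/absence) and on the fused
#' four-layer table, on the same samples and labels, and reports the best
#' AUC per model together with the combined-minus-best-single gap.
#'
#' @param bundle a `synthetic_bundle` (or any list with `tables`, `snps`,
#'   `metadata`).
#' @param labels labels per sample of the fused table; default: the binary
#'   healthy-vs-severe task from the bundle metadata.
#' @param grid,n_trees,n_folds,seed sweep settings.
#' @return list: `models` (data.frame with one row per model: 4 single + 1
#'   combined), `gap` (combined best CV AUC minus best single-layer best
#'   CV AUC), `reports` (named list of `model_report`s).
#' @export
compare_single_vs_combined <- function(bundle, labels = NULL,
                                       grid = c(2L, 4L, 8L, 16L, 32L, 64L,
                                                128L, 256L),
                                       n_trees = 5000, n_folds = 5L,
                                       seed = 1L) {
  layer_names <- intersect(c("species", "mag", "gene"), names(bundle$tables))
  fused_all <- fuse_layers(bundle$tables[layer_names], bundle$snps)
  if (is.null(labels)) {
    grp <- group_vector(fused_all, bundle$metadata)
    keep <- grp %in% c("Healthy", "GD2")
    fused_all <- structure(fused_all[keep, , drop = FALSE],
                           layer_map = attr(fused_all, "layer_map"))
    labels <- grp[keep]
  }
  samples <- rownames(fused_all)
  single_inputs <- c(
    stats::setNames(lapply(layer_names, function(l) {
      fuse_layers(bundle$tables[l])
    }), layer_names),
    list(snp = fuse_layers(list(), snps = bundle$snps)))
  reports <- list()
  for (nm in names(single_inputs)) {
    f <- single_inputs[[nm]]
    f <- structure(f[samples, , drop = FALSE], layer_map = attr(f, "layer_map"))
    reports[[nm]] <- suppressWarnings(
      sweep_feature_counts(f, labels, grid = grid, n_trees = n_trees,
                           n_folds = n_folds, seed = seed))
  }
  reports$combined <- sweep_feature_counts(fused_all, labels, grid = grid,
                                           n_trees = n_trees,
                                           n_folds = n_folds, seed = seed)
  models <- do.call(rbind, lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    data.frame(model = nm, chosen_n = r$chosen_n,
               best_cv_auc = max(r$sweep$cv_auc),
               holdout_auc = r$holdout_auc, stringsAsFactors = FALSE)
  }))
  rownames(models) <- NULL
  best_single <- max(models$best_cv_auc[models$model != "combined"])
  list(models = models,
       gap = models$best_cv_auc[models$model == "combined"] - best_single,
       reports = reports)
}
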