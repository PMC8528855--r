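# Readers/writers for all on-disk formats: TSV feature tables and
# metadata, BLAST-tabular (outfmt 6 subset) gene hits, SNP matrices with
# the species encoded in the locus ID ("<species>|<locus>"), YAML pipeline
# configuration, JSON reports. All numeric output uses %.12g, which is
# idempotent under write -> parse -> write (exact round-trip bytes).

#' Read a feature table from TSV
#'
#' Expects a header row of feature IDs and a first column of sample IDs.
#' Values are returned unchanged: normalisation is an explicit downstream
#' operation, never implicit.
#'
#' @param path TSV file path.
#' @param layer the layer tag to attach (see [feature_table()]).
#' @return a [feature_table()].
#' @export
read_feature_table <- function(path, layer) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stopf("%s: need a sample-ID column plus >= 1 feature", path)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    stopf("%s: duplicate sample ID '%s' (row %d)", path,
          ids[duplicated(ids)][1], which(duplicated(ids))[1] + 1L)
  }
  feat_ids <- colnames(df)[-1]  # before subsetting: `[.data.frame` dedupes
  if (anyDuplicated(feat_ids)) {
    stopf("%s: duplicate feature ID '%s'", path,
          feat_ids[duplicated(feat_ids)][1])
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(df[-1], is.numeric, TRUE))[1]
    stopf("%s: non-numeric cell in column '%s' (column %d)", path,
          colnames(df)[bad + 1L], bad + 1L)
  }
  dimnames(m) <- list(ids, feat_ids)
  feature_table(m, layer)
}

#' Write a feature table (or any sample-by-feature matrix) to TSV
#'
#' @param x matrix with sample and feature IDs.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(x, path) {
  write_matrix_tsv(unclass(x), path)
}

write_matrix_tsv <- function(m, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(c("sample_id", colnames(m)), collapse = "\t"), con)
  for (i in seq_len(nrow(m))) {
    writeLines(paste(c(rownames(m)[i], fmt_num(m[i, ])), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a SNP frequency matrix from TSV
#'
#' Locus column names follow the `"<species>|<locus>"` convention, so the
#' file is self-contained.
#'
#' @param path TSV file path.
#' @return an [snp_matrix()].
#' @export
read_snp_matrix <- function(path) {
  ft <- read_feature_table(path, "clinical")  # numeric parse + ID checks
  m <- unclass(ft)
  attr(m, "layer") <- NULL
  class(m) <- "matrix"
  sp <- sub("\\|.*$", "", colnames(m))
  if (any(sp == colnames(m))) {
    stopf("%s: locus IDs must follow '<species>|<locus>' (offending: %s)",
          path, colnames(m)[sp == colnames(m)][1])
  }
  snp_matrix(m, sp)
}

#' @rdname read_snp_matrix
#' @param snps an [snp_matrix()] to serialise.
#' @export
write_snp_matrix <- function(snps, path) {
  write_matrix_tsv(unclass(snps), path)
}

#' Read / write per-sample metadata
#'
#' Metadata TSV must contain `sample_id` and `group` columns; any further
#' columns (demographics, clinical summaries) are kept as-is.
#'
#' @param path TSV file path.
#' @return data.frame.
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  check_metadata(df)
}

#' @rdname read_metadata
#' @param meta metadata data.frame.
#' @export
write_metadata <- function(meta, path) {
  check_metadata(meta)
  out <- meta
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]])) out[[j]] <- fmt_num(out[[j]])
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(out), collapse = "\t"), con)
  for (i in seq_len(nrow(out))) {
    writeLines(paste(vapply(out, function(col) as.character(col[i]), ""),
                     collapse = "\t"), con)
  }
  invisible(path)
}

# Turn a raw outfmt-6-style data.frame (qseqid sseqid pident length qlen)
# into the internal gene_hit_table, parsing "<mag>|<gene>" query IDs.
parse_gene_hits <- function(df) {
  need <- c("qseqid", "sseqid", "pident", "length", "qlen")
  if (nrow(df) > 0) names(df)[seq_along(need)] <- need
  if (nrow(df) == 0) {
    out <- data.frame(mag = character(), gene = character(),
                      genome = character(), pident = numeric(),
                      length = integer(), qlen = integer(),
                      coverage = numeric(), stringsAsFactors = FALSE)
    class(out) <- c("gene_hit_table", class(out))
    return(out)
  }
  if (any(df$pident < 0 | df$pident > 100)) {
    stopf("pident outside [0, 100] at hit row %d",
          which(df$pident < 0 | df$pident > 100)[1])
  }
  if (any(df$qlen <= 0)) stopf("non-positive qlen at hit row %d",
                               which(df$qlen <= 0)[1])
  over <- df$length > df$qlen
  if (any(over)) {
    warnf("%d hit(s) with alignment length > gene length; coverage capped at 100%%",
          sum(over))
  }
  mag <- sub("\\|.*$", "", df$qseqid)
  gene <- sub("^[^|]*\\|", "", df$qseqid)
  if (any(mag == df$qseqid)) {
    stopf("qseqid must follow '<mag>|<gene>' (offending: %s)",
          df$qseqid[mag == df$qseqid][1])
  }
  out <- data.frame(mag = mag, gene = gene, genome = as.character(df$sseqid),
                    pident = as.numeric(df$pident),
                    length = as.integer(df$length), qlen = as.integer(df$qlen),
                    coverage = pmin(df$length / df$qlen * 100, 100),
                    stringsAsFactors = FALSE)
  class(out) <- c("gene_hit_table", class(out))
  out
}

#' Read BLAST-tabular gene hits
#'
#' Parses a headerless tab-separated file with at least the five columns
#' `qseqid sseqid pident length qlen`, where `qseqid` encodes the MAG
#' membership as `"<mag>|<gene>"`. Query coverage is computed as
#' `length / qlen * 100`; alignments longer than the gene raise a warning
#' and are kept with coverage capped at 100.
#'
#' @param path file path.
#' @return a `gene_hit_table` data.frame (columns `mag`, `gene`, `genome`,
#'   `pident`, `length`, `qlen`, `coverage`).
#' @export
read_gene_hits <- function(path) {
  if (file.size(path) == 0) return(parse_gene_hits(data.frame()))
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 5L) stopf("%s: expected >= 5 tab-separated columns", path)
  df <- df[, 1:5]
  names(df) <- c("qseqid", "sseqid", "pident", "length", "qlen")
  for (col in c("pident", "length", "qlen")) {
    if (!is.numeric(df[[col]])) stopf("%s: non-numeric '%s' column", path, col)
  }
  parse_gene_hits(df)
}

#' @rdname read_gene_hits
#' @param hits a `gene_hit_table`.
#' @export
write_gene_hits <- function(hits, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (nrow(hits) > 0) {
    for (i in seq_len(nrow(hits))) {
      writeLines(paste(c(sprintf("%s|%s", hits$mag[i], hits$gene[i]),
                         hits$genome[i], fmt_num(hits$pident[i]),
                         hits$length[i], hits$qlen[i]), collapse = "\t"), con)
    }
  }
  invisible(path)
}

#' Write / read a synthetic bundle as a directory of plain-text files
#'
#' One TSV per abundance layer plus `clinical.tsv`, `snp_freq.tsv`,
#' `metadata.tsv`, `gene_hits.tsv` (BLAST tabular) and `truth.json`.
#'
#' @param bundle a `synthetic_bundle` from [generate_cohort()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (layer in names(bundle$tables)) {
    write_feature_table(bundle$tables[[layer]],
                        file.path(dir, paste0(layer, ".tsv")))
  }
  write_snp_matrix(bundle$snps, file.path(dir, "snp_freq.tsv"))
  write_metadata(bundle$metadata, file.path(dir, "metadata.tsv"))
  write_gene_hits(bundle$gene_hits, file.path(dir, "gene_hits.tsv"))
  truth <- bundle$truth
  # named vectors serialize to JSON objects only as lists
  truth$mag_assignment <- as.list(truth$mag_assignment)
  truth$genes_per_mag <- attr(bundle$gene_hits, "genes_per_mag")
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(dir) {
  layers <- intersect(LAYERS, sub("\\.tsv$", "", list.files(dir, "\\.tsv$")))
  tables <- stats::setNames(lapply(layers, function(l) {
    read_feature_table(file.path(dir, paste0(l, ".tsv")), l)
  }), layers)
  snps <- read_snp_matrix(file.path(dir, "snp_freq.tsv"))
  meta <- read_metadata(file.path(dir, "metadata.tsv"))
  hits <- read_gene_hits(file.path(dir, "gene_hits.tsv"))
  truth <- NULL
  tj <- file.path(dir, "truth.json")
  if (file.exists(tj)) {
    truth <- jsonlite::read_json(tj, simplifyVector = TRUE)
    if (!is.null(truth$genes_per_mag)) {
      attr(hits, "genes_per_mag") <- truth$genes_per_mag
      attr(hits, "mags") <- names(truth$mag_assignment)
      attr(hits, "truth") <- unlist(truth$mag_assignment)
    }
  }
  structure(list(tables = tables, snps = snps, metadata = meta,
                 gene_hits = hits, truth = truth, config = NULL),
            class = "synthetic_bundle")
}

#' Pipeline configuration defaults
#'
#' Flat list of every tunable the command-line pipeline reads:
#' significance thresholds, permutation counts, random-forest settings,
#' the feature-count sweep grid and network thresholds.
#'
#' @return named list of defaults.
#' @export
pipeline_defaults <- function() {
  list(alpha = 0.05, n_perm = 999L,
       n_trees = 5000L, n_folds = 5L,
       sweep_grid = c(2L, 4L, 8L, 16L, 32L, 64L, 128L, 256L),
       rho_min = 0.3, q_max = 0.05,
       pseudocount_mode = "multiplicative",
       seed = 1L)
}

#' Read a YAML pipeline configuration
#'
#' Unknown keys are rejected; missing keys fall back to
#' [pipeline_defaults()]. Invariants enforced: thresholds in (0, 1),
#' permutation counts >= 99, sweep grid strictly increasing positive
#' integers.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return validated configuration list.
#' @export
read_pipeline_config <- function(path = NULL) {
  cfg <- pipeline_defaults()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    unknown <- setdiff(names(user), c(names(cfg), "group_sizes", "n_species",
                                      "n_mags", "n_genes", "n_metabolites",
                                      "n_clinical", "n_snps_per_species",
                                      "sigma_log", "snp_concentration",
                                      "sequencing_depth_proxy",
                                      "metabolite_noise_sd", "clinical_shift",
                                      "null_cohort"))
    if (length(unknown)) stopf("unknown config key: %s", unknown[1])
    cfg <- utils::modifyList(cfg, user)
  }
  for (k in c("alpha", "q_max")) {
    if (cfg[[k]] <= 0 || cfg[[k]] >= 1) stopf("'%s' must lie in (0, 1)", k)
  }
  if (cfg$n_perm < 99) stopf("'n_perm' must be >= 99")
  g <- cfg$sweep_grid
  if (any(g <= 0) || any(g != round(g)) || any(diff(g) <= 0)) {
    stopf("'sweep_grid' must be strictly increasing positive integers")
  }
  cfg
}

# Provenance record: enough to reproduce a run, with no wall-clock field
# so identical runs serialize to identical bytes.
write_provenance <- function(out_dir, subcommand, cfg, seed) {
  rec <- list(subcommand = subcommand,
              config_hash = fnv1a32(paste(deparse(cfg), collapse = "")),
              seed = seed,
              package_version = as.character(utils::packageVersion("gdmicro")),
              r_version = R.version.string)
  jsonlite::write_json(rec, file.path(out_dir, paste0(subcommand, ".prov.json")),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(rec)
}
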