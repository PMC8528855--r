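# Lightweight S3 containers. A feature table is a plain numeric matrix
# (samples x features) tagged with its layer; a SNP matrix additionally
# carries the species of origin of each locus. Plain matrices keep the
# whole pipeline compatible with base R and vegan.

LAYERS <- c("species", "mag", "gene", "metabolite", "clinical")
COMPOSITIONAL_LAYERS <- c("species", "mag", "gene", "metabolite")

#' Construct a feature table
#'
#' A samples-by-features numeric matrix tagged with the data layer it
#' belongs to. Compositional layers (`species`, `mag`, `gene`,
#' `metabolite`) must be non-negative; no normalisation is applied here.
#'
#' @param x numeric matrix with sample IDs as row names and feature IDs as
#'   column names.
#' @param layer one of `"species"`, `"mag"`, `"gene"`, `"metabolite"`,
#'   `"clinical"`.
#' @return a `feature_table`: the matrix with a `layer` attribute.
#' @examples
#' m <- matrix(runif(6), 3, 2, dimnames = list(paste0("S", 1:3), c("f1", "f2")))
#' feature_table(m, "species")
#' @export
feature_table <- function(x, layer) {
  layer <- match.arg(layer, LAYERS)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stopf("feature table needs sample IDs (rownames) and feature IDs (colnames)")
  }
  if (anyDuplicated(rownames(x))) {
    stopf("duplicate sample ID: %s", rownames(x)[duplicated(rownames(x))][1])
  }
  if (anyDuplicated(colnames(x))) {
    stopf("duplicate feature ID: %s", colnames(x)[duplicated(colnames(x))][1])
  }
  if (layer %in% COMPOSITIONAL_LAYERS) {
    if (anyNA(x)) stopf("missing values are not allowed in the '%s' layer", layer)
    if (any(x < 0)) stopf("negative abundance in compositional layer '%s'", layer)
  }
  structure(x, layer = layer, class = c("feature_table", class(x)))
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> layer=%s: %d samples x %d features\n",
              attr(x, "layer"), nrow(x), ncol(x)))
  print(utils::head(unclass(x)[, seq_len(min(5L, ncol(x))), drop = FALSE], 4L))
  invisible(x)
}

table_layer <- function(x) attr(x, "layer")

#' Construct a SNP frequency matrix
#'
#' Samples-by-loci matrix of per-locus mutational frequencies in \[0, 1\]
#' (fraction of reads supporting the variant allele within a sample), with
#' a species-of-origin annotation per locus.
#'
#' @param x numeric matrix, values in \[0, 1\], sample IDs as row names,
#'   locus IDs as column names.
#' @param species character vector, one species name per locus (recycled if
#'   length 1).
#' @return an `snp_matrix` object.
#' @export
snp_matrix <- function(x, species) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stopf("SNP matrix needs sample IDs (rownames) and locus IDs (colnames)")
  }
  if (anyNA(x) || any(x < 0) || any(x > 1)) {
    stopf("SNP frequencies must lie in [0, 1] with no missing values")
  }
  if (length(species) == 1L) species <- rep(species, ncol(x))
  if (length(species) != ncol(x)) {
    stopf("'species' must annotate every locus (%d loci, %d annotations)",
          ncol(x), length(species))
  }
  structure(x, species = stats::setNames(as.character(species), colnames(x)),
            class = c("snp_matrix", class(x)))
}

#' @export
print.snp_matrix <- function(x, ...) {
  cat(sprintf("<snp_matrix> %d samples x %d loci from %d species\n",
              nrow(x), ncol(x), length(unique(attr(x, "species")))))
  invisible(x)
}

#' Presence/absence view of a SNP matrix
#'
#' A locus is present in a sample when its mutational frequency is
#' strictly positive.
#'
#' @param snps an [snp_matrix()].
#' @return integer 0/1 matrix of the same shape.
#' @export
snp_presence <- function(snps) {
  p <- (unclass(snps) > 0) * 1L
  dimnames(p) <- dimnames(snps)
  p
}

snp_species <- function(snps) attr(snps, "species")

# Validate a metadata data.frame: sample_id + group columns required.
check_metadata <- function(meta) {
  if (!is.data.frame(meta)) stopf("metadata must be a data.frame")
  if (!all(c("sample_id", "group") %in% names(meta))) {
    stopf("metadata needs 'sample_id' and 'group' columns")
  }
  if (anyDuplicated(meta$sample_id)) {
    stopf("duplicate sample ID in metadata: %s",
          meta$sample_id[duplicated(meta$sample_id)][1])
  }
  meta
}

# Align a table's samples with metadata; returns group factor in table order.
group_vector <- function(x, meta) {
  check_metadata(meta)
  idx <- match(rownames(x), meta$sample_id)
  if (anyNA(idx)) {
    stopf("samples missing from metadata: %s",
          paste(utils::head(rownames(x)[is.na(idx)], 3), collapse = ", "))
  }
  as.character(meta$group[idx])
}
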