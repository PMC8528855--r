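# Gene-consensus taxonomic assignment of MAGs. A gene is assigned to the
# genome of its best qualifying BLAST hit (identity >= 95%, query coverage
# >= 90%; ranked by identity, then coverage, then genome ID). A MAG is
# assigned to a genome iff strictly more than 80% of ALL its genes
# (including genes with no qualifying hit) agree on that genome.

IDENTITY_MIN <- 95
COVERAGE_MIN <- 90
CONSENSUS_MIN <- 0.8  # strict: fraction must exceed this

#' Assign genes to genomes from alignment hits
#'
#' Qualifying hits have percent identity >= 95 and query coverage >= 90
#' (both inclusive). Each gene goes to the genome of its best qualifying
#' hit, ranked by identity, then coverage, then lexicographic genome ID
#' (a total order, so the result is invariant to hit-row order). Genes
#' without a qualifying hit are `"unassigned"`.
#'
#' @param hits a `gene_hit_table` from [read_gene_hits()] or
#'   [generate_gene_hits()].
#' @return data.frame: `mag`, `gene`, `assigned_genome`, `best_identity`,
#'   `best_coverage` (NA when unassigned).
#' @export
assign_genes <- function(hits) {
  if (nrow(hits) == 0) {
    return(data.frame(mag = character(), gene = character(),
                      assigned_genome = character(), best_identity = numeric(),
                      best_coverage = numeric(), stringsAsFactors = FALSE))
  }
  qual <- hits[hits$pident >= IDENTITY_MIN & hits$coverage >= COVERAGE_MIN, ,
               drop = FALSE]
  key_all <- paste(hits$mag, hits$gene, sep = "\r")
  keys <- unique(key_all)
  if (nrow(qual) > 0) {
    key_q <- paste(qual$mag, qual$gene, sep = "\r")
    ord <- order(key_q, -qual$pident, -qual$coverage, qual$genome)
    qual <- qual[ord, , drop = FALSE]
    best <- qual[!duplicated(key_q[ord]), , drop = FALSE]
    bi <- match(keys, paste(best$mag, best$gene, sep = "\r"))
  } else {
    best <- qual
    bi <- rep(NA_integer_, length(keys))
  }
  first <- match(keys, key_all)
  data.frame(
    mag = hits$mag[first], gene = hits$gene[first],
    assigned_genome = ifelse(is.na(bi), "unassigned", best$genome[bi]),
    best_identity = ifelse(is.na(bi), NA_real_, best$pident[bi]),
    best_coverage = ifelse(is.na(bi), NA_real_, best$coverage[bi]),
    stringsAsFactors = FALSE)
}

#' Consensus assignment of one MAG
#'
#' The supporting fraction is the number of genes assigned to the modal
#' genome divided by the total number of genes in the MAG, including genes
#' with no qualifying hit. The MAG is assigned iff the fraction strictly
#' exceeds 0.8 (a fraction of exactly 0.8 is unassigned).
#'
#' @param gene_assignments data.frame as returned by [assign_genes()],
#'   restricted to one MAG.
#' @param n_genes total number of genes in the MAG; defaults to the number
#'   of rows (genes absent from the BLAST output must be counted by
#'   passing the true total).
#' @return one-row data.frame: `mag_id`, `assigned_taxon`,
#'   `supporting_fraction`, `n_genes`, `n_assigned`.
#' @export
assign_mag <- function(gene_assignments, n_genes = nrow(gene_assignments)) {
  mag_id <- if (nrow(gene_assignments) > 0) gene_assignments$mag[1] else NA_character_
  if (n_genes == 0) {
    warnf("MAG '%s' has zero genes; unassigned", mag_id)
    return(data.frame(mag_id = mag_id, assigned_taxon = "unassigned",
                      supporting_fraction = 0, n_genes = 0L, n_assigned = 0L,
                      stringsAsFactors = FALSE))
  }
  ass <- gene_assignments$assigned_genome
  ass <- ass[ass != "unassigned"]
  if (length(ass) == 0) {
    return(data.frame(mag_id = mag_id, assigned_taxon = "unassigned",
                      supporting_fraction = 0, n_genes = as.integer(n_genes),
                      n_assigned = 0L, stringsAsFactors = FALSE))
  }
  tab <- sort(table(ass), decreasing = TRUE)
  modal <- names(tab)[1]
  frac <- as.numeric(tab[1]) / n_genes
  data.frame(
    mag_id = mag_id,
    assigned_taxon = if (frac > CONSENSUS_MIN) modal else "unassigned",
    supporting_fraction = frac, n_genes = as.integer(n_genes),
    n_assigned = length(ass), stringsAsFactors = FALSE)
}

#' Consensus assignment of every MAG in a hit table
#'
#' Runs [assign_genes()] then [assign_mag()] per MAG. The per-MAG gene
#' totals default to the `genes_per_mag` attribute carried by synthetic
#' hit tables (so hit-less genes count in the denominator); pass
#' `n_genes_per_mag` explicitly for real data where the gene complement is
#' known from gene calling.
#'
#' @param hits a `gene_hit_table`.
#' @param n_genes_per_mag named integer vector of gene totals per MAG, or
#'   `NULL` to use observed genes (plus the table's own annotation, if
#'   present).
#' @return data.frame with one row per MAG (see [assign_mag()]).
#' @export
assign_mags <- function(hits, n_genes_per_mag = NULL) {
  ga <- assign_genes(hits)
  mags <- unique(ga$mag)
  if (is.null(n_genes_per_mag)) {
    gpm <- attr(hits, "genes_per_mag")
    all_mags <- attr(hits, "mags")
    if (!is.null(gpm) && !is.null(all_mags)) {
      n_genes_per_mag <- stats::setNames(rep(as.integer(gpm), length(all_mags)),
                                         all_mags)
      mags <- all_mags
    } else {
      n_genes_per_mag <- stats::setNames(
        as.integer(table(ga$mag)[mags]), mags)
    }
  } else {
    mags <- union(names(n_genes_per_mag), mags)
  }
  out <- do.call(rbind, lapply(mags, function(m) {
    rows <- ga[ga$mag == m, , drop = FALSE]
    res <- assign_mag(rows, n_genes = n_genes_per_mag[[m]] %||% nrow(rows))
    res$mag_id <- m
    res
  }))
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a)) b else a
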