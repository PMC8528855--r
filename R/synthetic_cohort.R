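# Synthetic multi-layer cohort generator.
#
# Emulates the downstream products of a three-group shotgun-metagenomic
# study of Graves' disease (healthy controls, mild GD1, severe GD2):
# relative-abundance tables for species / MAG / gene / predicted-metabolite
# layers, a per-species SNP frequency matrix, clinical indexes, and a
# BLAST-tabular gene-hit table for MAG taxonomy — all with planted,
# recoverable ground truth.

GROUPS <- c("Healthy", "GD1", "GD2")

CLINICAL_PANEL <- data.frame(
  index = c("ALT", "AST", "direct_bilirubin", "FT3", "FT4", "TSH",
            "TPOAb", "TRAb", "TGAb", "IL17A", "IL23"),
  # +1: rises with disease severity; -1: falls (TSH is suppressed in
  # hyperthyroidism). Immune indexes shift only in severe disease.
  sign = c(1, 1, 1, 1, 1, -1, 1, 1, 1, 1, 1),
  gd1_affected = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE,
                   FALSE, FALSE),
  stringsAsFactors = FALSE
)

#' Default planted marker effects
#'
#' Ground-truth effects used by the default cohort configuration: eight
#' features per fused layer (species, MAG, gene, SNP), half increasing and
#' half decreasing monotonically across Healthy -> GD1 -> GD2. Abundance
#' effects are multiplicative folds per group (severe-group fold 4, mild
#' intermediate at 2); SNP effects are target mean mutational frequencies
#' per group (0.2 / 0.45 / 0.7 or the reverse).
#'
#' @param n_per_layer planted features per layer (default 8, i.e. 32 total).
#' @param fold severe-group fold change for abundance layers (default 4).
#' @param snp_means length-3 target mean frequencies for increasing SNP
#'   effects (default `c(0.2, 0.45, 0.7)`).
#' @return data.frame with columns `feature_id`, `layer`, `effect_Healthy`,
#'   `effect_GD1`, `effect_GD2`, `monotone`.
#' @export
default_planted_effects <- function(n_per_layer = 8L, fold = 4,
                                    snp_means = c(0.2, 0.45, 0.7)) {
  n_per_layer <- check_count(n_per_layer, "n_per_layer")
  mid <- sqrt(fold)  # mild group sits at the geometric midpoint
  out <- list()
  for (layer in c("species", "mag", "gene")) {
    ids <- sprintf("%s_%03d", sub("species", "sp", layer), seq_len(n_per_layer))
    up <- seq_len(n_per_layer) <= ceiling(n_per_layer / 2)
    out[[layer]] <- data.frame(
      feature_id = ids, layer = layer,
      effect_Healthy = 1,
      effect_GD1 = ifelse(up, mid, 1 / mid),
      effect_GD2 = ifelse(up, fold, 1 / fold),
      monotone = TRUE, stringsAsFactors = FALSE)
  }
  up <- seq_len(n_per_layer) <= ceiling(n_per_layer / 2)
  out$snp <- data.frame(
    feature_id = sprintf("planted_snp_%03d", seq_len(n_per_layer)),
    layer = "snp",
    effect_Healthy = ifelse(up, snp_means[1], snp_means[3]),
    effect_GD1 = snp_means[2],
    effect_GD2 = ifelse(up, snp_means[3], snp_means[1]),
    monotone = TRUE, stringsAsFactors = FALSE)
  do.call(rbind, out)
}

#' Cohort generator configuration
#'
#' Defaults mirror the study design the package targets: 162 subjects
#' split 62 healthy / 36 mild (GD1) / 64 severe (GD2), four abundance
#' layers plus eleven clinical indexes, per-species SNP loci, and 32
#' planted marker effects spread over the four fused layers.
#'
#' @param group_sizes named integer vector of samples per group (>= 2
#'   groups; names become group labels).
#' @param n_species,n_mags,n_genes,n_metabolites,n_clinical feature counts
#'   per layer.
#' @param n_snps_per_species named integer vector: SNP loci simulated per
#'   species.
#' @param planted_markers data.frame of planted effects (see
#'   [default_planted_effects()]); use a 0-row data.frame for a null cohort.
#' @param sigma_log standard deviation of the log-normal latent abundances.
#' @param snp_concentration Beta concentration parameter for SNP
#'   frequencies (higher = less within-group spread).
#' @param sequencing_depth_proxy multinomial resampling depth applied to
#'   each abundance layer; controls sampling noise and zero rates.
#' @param metabolite_noise_sd log-normal noise applied to the predicted
#'   metabolite layer.
#' @param clinical_shift per-severity-step shift of affected clinical
#'   indexes, in standard-deviation units.
#' @param seed integer; fully determines the generated bundle.
#' @return a `cohort_config` list.
#' @examples
#' cfg <- cohort_config(seed = 1)
#' sum(cfg$group_sizes)  # 162
#' @export
cohort_config <- function(group_sizes = c(Healthy = 62L, GD1 = 36L, GD2 = 64L),
                          n_species = 60L, n_mags = 80L, n_genes = 150L,
                          n_metabolites = 40L, n_clinical = 11L,
                          n_snps_per_species = c(
                            Bacteroides_vulgatus = 50L,
                            Faecalibacterium_prausnitzii = 50L,
                            Eubacterium_rectale = 50L),
                          planted_markers = default_planted_effects(),
                          sigma_log = 1.0, snp_concentration = 20,
                          sequencing_depth_proxy = 1e5,
                          metabolite_noise_sd = 0.25,
                          clinical_shift = 1.0, seed = 1L) {
  if (length(group_sizes) < 2L || is.null(names(group_sizes))) {
    stopf("'group_sizes' must be a named vector with >= 2 groups")
  }
  for (g in names(group_sizes)) check_count(group_sizes[[g]], g)
  for (nm in c("n_species", "n_mags", "n_genes", "n_metabolites", "n_clinical")) {
    check_count(get(nm), nm)
  }
  if (length(n_snps_per_species) < 1L || is.null(names(n_snps_per_species))) {
    stopf("'n_snps_per_species' must be a named vector")
  }
  for (sp in names(n_snps_per_species)) check_count(n_snps_per_species[[sp]], sp)
  if (sequencing_depth_proxy <= 0) stopf("'sequencing_depth_proxy' must be positive")
  if (sigma_log <= 0 || snp_concentration <= 0) {
    stopf("'sigma_log' and 'snp_concentration' must be positive")
  }
  structure(list(
    group_sizes = vapply(group_sizes, as.integer, 1L),
    n_species = as.integer(n_species), n_mags = as.integer(n_mags),
    n_genes = as.integer(n_genes), n_metabolites = as.integer(n_metabolites),
    n_clinical = as.integer(n_clinical),
    n_snps_per_species = vapply(n_snps_per_species, as.integer, 1L),
    planted_markers = planted_markers,
    sigma_log = sigma_log, snp_concentration = snp_concentration,
    sequencing_depth_proxy = sequencing_depth_proxy,
    metabolite_noise_sd = metabolite_noise_sd,
    clinical_shift = clinical_shift,
    seed = as.integer(seed)), class = "cohort_config")
}

layer_feature_ids <- function(config) {
  list(
    species = sprintf("sp_%03d", seq_len(config$n_species)),
    mag = sprintf("mag_%03d", seq_len(config$n_mags)),
    gene = sprintf("gene_%03d", seq_len(config$n_genes)),
    metabolite = sprintf("met_%03d", seq_len(config$n_metabolites)))
}

planted_for_layer <- function(config, layer) {
  pm <- config$planted_markers
  if (is.null(pm) || nrow(pm) == 0) return(pm[0, ])
  pm[pm$layer == layer, , drop = FALSE]
}

# Per-sample planted effect for row i of a planted-marker frame: effects
# are keyed by `effect_<group>` columns, so any group labelling works
# (cohort panels as well as Healthy/GD1/GD2). Groups without a stated
# effect get `default`.
planted_effect_by_group <- function(pm, i, groups, default) {
  out <- rep(default, length(groups))
  for (g in unique(groups)) {
    col <- paste0("effect_", g)
    if (col %in% names(pm) && !is.na(pm[[col]][i])) {
      out[groups == g] <- pm[[col]][i]
    }
  }
  out
}

# One abundance layer: log-normal latent + planted multiplicative group
# effects, multinomially resampled to `depth` reads, closed to 1.
gen_abundance_layer <- function(ids, groups, config, layer, seed) {
  with_seed(seed, {
    n <- length(groups)
    k <- length(ids)
    base <- rnorm(k, 0, 2)  # rank-abundance spread across features
    eff <- matrix(1, n, k)
    pm <- planted_for_layer(config, layer)
    if (nrow(pm) > 0) {
      bad <- setdiff(pm$feature_id, ids)
      if (length(bad)) {
        stopf("planted %s feature outside layer range: %s", layer, bad[1])
      }
      for (i in seq_len(nrow(pm))) {
        j <- match(pm$feature_id[i], ids)
        folds <- planted_effect_by_group(pm, i, groups, default = 1)
        if (any(folds <= 0)) stopf("abundance effects must be positive")
        eff[, j] <- folds
      }
    }
    latent <- exp(sweep(matrix(rnorm(n * k, 0, config$sigma_log), n, k),
                        2, base, "+") + log(eff))
    depth <- round(config$sequencing_depth_proxy)
    counts <- t(apply(latent, 1, function(p) {
      as.numeric(rmultinom(1, size = depth, prob = p / sum(p)))
    }))
    rel <- counts / rowSums(counts)
    dimnames(rel) <- list(names(groups), ids)
    rel
  })
}

# Predicted metabolite layer: fixed non-negative random linear map of the
# gene layer plus multiplicative log-normal noise, then closed to 1. This
# stands in for a trained metabolite-prediction model's output table and
# preserves the gene <-> metabolite coupling that Mantel tests probe.
gen_metabolite_layer <- function(gene_rel, config, seed) {
  with_seed(seed, {
    k <- ncol(gene_rel); m <- config$n_metabolites
    w <- matrix(abs(rnorm(k * m)) * rbinom(k * m, 1, 0.2), k, m)
    empty <- colSums(w) == 0
    if (any(empty)) w[sample.int(k, sum(empty)), which(empty)] <- 1
    raw <- gene_rel %*% w
    raw <- raw * exp(matrix(rnorm(length(raw), 0, config$metabolite_noise_sd),
                            nrow(raw), ncol(raw)))
    rel <- raw / rowSums(raw)
    dimnames(rel) <- list(rownames(gene_rel),
                          sprintf("met_%03d", seq_len(m)))
    rel
  })
}

# SNP layer: zero-inflated Beta. A locus with target group mean m is
# detected (frequency > 0) with probability sqrt(m); detected frequencies
# are Beta(kappa*sqrt(m), kappa*(1-sqrt(m))), so the marginal mean is
# exactly m while the presence/absence view still varies between groups.
gen_snp_layer <- function(groups, config, seed) {
  with_seed(seed, {
    n <- length(groups)
    per_sp <- config$n_snps_per_species
    species <- rep(names(per_sp), per_sp)
    locus_ids <- unlist(lapply(names(per_sp), function(sp) {
      sprintf("%s|snp_%04d", sp, seq_len(per_sp[[sp]]))
    }))
    k <- length(locus_ids)
    pm <- planted_for_layer(config, "snp")
    if (nrow(pm) > k) stopf("more planted SNP effects than simulated loci")
    # planted effects occupy the first loci (IDs relabelled to the truth
    # IDs); null loci share one baseline mean across all groups
    glev <- unique(groups)
    baseline <- runif(k, 0.1, 0.7)
    means <- matrix(baseline, nrow = length(glev), ncol = k, byrow = TRUE,
                    dimnames = list(glev, NULL))
    if (nrow(pm) > 0) {
      for (i in seq_len(nrow(pm))) {
        m_g <- planted_effect_by_group(pm, i, glev, default = baseline[i])
        if (any(m_g < 0 | m_g > 1)) stopf("SNP effects must lie in [0, 1]")
        means[, i] <- m_g
      }
      locus_ids[seq_len(nrow(pm))] <-
        sprintf("%s|%s", species[seq_len(nrow(pm))], pm$feature_id)
    }
    kappa <- config$snp_concentration
    freq <- matrix(0, n, k, dimnames = list(names(groups), locus_ids))
    for (g in glev) {
      rows <- which(groups == g)
      gm <- means[g, ]
      q <- sqrt(gm)
      for (j in seq_len(k)) {
        if (q[j] <= 0) next           # mean 0: locus absent in this group
        present <- rbinom(length(rows), 1, q[j])
        f <- if (q[j] >= 1) rep(1, length(rows)) else
          rbeta(length(rows), kappa * q[j], kappa * (1 - q[j]))
        freq[rows, j] <- present * pmin(pmax(f, 0), 1)
      }
    }
    snp_matrix(freq, species)
  })
}

gen_clinical_layer <- function(groups, config, seed) {
  with_seed(seed, {
    n <- length(groups)
    m <- config$n_clinical
    if (m == nrow(CLINICAL_PANEL)) {
      panel <- CLINICAL_PANEL
    } else {
      panel <- data.frame(index = sprintf("clin_%02d", seq_len(m)),
                          sign = rep(c(1, -1), length.out = m),
                          gd1_affected = rep(c(TRUE, FALSE), length.out = m))
    }
    step <- c(Healthy = 0, GD1 = 1, GD2 = 2)[groups]
    step[is.na(step)] <- 0
    x <- sapply(seq_len(m), function(j) {
      severity <- if (panel$gd1_affected[j]) step else (step == 2) * 2
      rnorm(n, mean = panel$sign[j] * config$clinical_shift * severity, sd = 1)
    })
    dimnames(x) <- list(names(groups), panel$index)
    x
  })
}

#' Generate a synthetic multi-layer cohort
#'
#' Draws every data layer of the study design described in
#' [cohort_config()]: species/MAG/gene abundances as closed log-normal
#' latents with planted multiplicative group effects, a predicted
#' metabolite layer as a noisy linear map of the gene layer, a SNP
#' frequency matrix with planted per-group mean frequencies, Gaussian
#' clinical indexes with monotone disease shifts, and a gene-hit table for
#' MAG taxonomy. The planted truth is returned verbatim for recovery
#' testing.
#'
#' @param config a [cohort_config()].
#' @return a `synthetic_bundle` list: `tables` (named list of
#'   [feature_table()]s), `snps` ([snp_matrix()]), `metadata` (data.frame),
#'   `gene_hits` (gene-hit table), `truth` (list with `planted_markers` and
#'   `mag_assignment`), `config`.
#' @examples
#' b <- generate_cohort(cohort_config(seed = 7))
#' nrow(b$metadata)  # 162
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) config <- do.call(cohort_config, config)
  gs <- config$group_sizes
  n <- sum(gs)
  ids <- sprintf("S%04d", seq_len(n))
  groups <- stats::setNames(rep(names(gs), gs), ids)
  seeds <- derive_seeds(config$seed, 8L)
  fids <- layer_feature_ids(config)

  # relabel planted abundance IDs into the layer namespaces
  pm <- config$planted_markers
  if (!is.null(pm) && nrow(pm) > 0) {
    for (layer in c("species", "mag", "gene")) {
      sel <- pm$layer == layer
      if (any(sel)) {
        k <- sum(sel)
        if (k > length(fids[[layer]])) {
          stopf("more planted %s effects than features in the layer", layer)
        }
        pm$feature_id[sel] <- fids[[layer]][seq_len(k)]
      }
    }
    config$planted_markers <- pm
  }

  tables <- list(
    species = feature_table(gen_abundance_layer(fids$species, groups, config,
                                                "species", seeds[1]), "species"),
    mag = feature_table(gen_abundance_layer(fids$mag, groups, config,
                                            "mag", seeds[2]), "mag"),
    gene = feature_table(gen_abundance_layer(fids$gene, groups, config,
                                             "gene", seeds[3]), "gene"))
  tables$metabolite <- feature_table(
    gen_metabolite_layer(unclass(tables$gene), config, seeds[4]), "metabolite")
  tables$clinical <- feature_table(
    gen_clinical_layer(groups, config, seeds[5]), "clinical")

  snps <- gen_snp_layer(groups, config, seeds[6])

  meta <- with_seed(seeds[7], {
    data.frame(
      sample_id = ids, group = unname(groups),
      gender = sample(c("F", "M"), n, replace = TRUE, prob = c(0.75, 0.25)),
      age = pmin(pmax(round(rnorm(n, 45, 12)), 18), 80),
      bmi = round(rnorm(n, 22.5, 3), 1),
      smoking = rbinom(n, 1, 0.2), alcohol = rbinom(n, 1, 0.15),
      stringsAsFactors = FALSE)
  })

  n_genomes <- 30L
  truth_map <- with_seed(seeds[8], {
    m <- config$n_mags
    assigned <- runif(m) < 0.7
    stats::setNames(ifelse(assigned,
                           sprintf("genome_%03d", sample.int(n_genomes, m,
                                                             replace = TRUE)),
                           "unassigned"),
                    fids$mag)
  })
  hits <- generate_gene_hits(n_mags = config$n_mags, genes_per_mag = 20L,
                             n_genomes = n_genomes,
                             truth_assignment = truth_map,
                             seed = seeds[8])

  structure(list(tables = tables, snps = snps, metadata = meta,
                 gene_hits = hits,
                 truth = list(planted_markers = config$planted_markers,
                              mag_assignment = truth_map),
                 config = config),
            class = "synthetic_bundle")
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat(sprintf("<synthetic_bundle> %d samples (%s); layers: %s; %d SNP loci\n",
              nrow(x$metadata),
              paste(sprintf("%s=%d", names(x$config$group_sizes),
                            x$config$group_sizes), collapse = "/"),
              paste(names(x$tables), collapse = ", "), ncol(x$snps)))
  invisible(x)
}

#' Generate a synthetic BLAST-tabular gene-hit table
#'
#' Builds per-(MAG, gene) alignment hits against candidate genomes for
#' testing the gene-consensus MAG assignment. For a MAG whose true genome
#' is known, a fixed fraction of its genes receive qualifying hits
#' (identity >= 95, coverage >= 90) to that genome; decoy qualifying hits
#' to other genomes and sub-threshold hits are injected at the stated
#' rates. MAGs mapped to `"unassigned"` receive only scattered decoy /
#' sub-threshold hits.
#'
#' @param n_mags,genes_per_mag,n_genomes problem dimensions.
#' @param truth_assignment named character vector mapping each MAG ID to a
#'   genome ID or `"unassigned"`; defaults to a deterministic round-robin
#'   over the genomes.
#' @param true_fraction fraction of a MAG's genes hitting its true genome
#'   (default 0.9; the consensus caller requires strictly more than 0.8).
#' @param decoy_rate,subthreshold_rate per-gene probabilities of an extra
#'   qualifying decoy hit / of a sub-threshold hit.
#' @param seed integer seed.
#' @return a `gene_hit_table` data.frame with columns `mag`, `gene`,
#'   `genome`, `pident`, `length`, `qlen`, `coverage`.
#' @export
generate_gene_hits <- function(n_mags, genes_per_mag, n_genomes,
                               truth_assignment = NULL,
                               true_fraction = 0.9, decoy_rate = 0.1,
                               subthreshold_rate = 0.1, seed = 1L) {
  n_mags <- check_count(n_mags, "n_mags")
  genes_per_mag <- check_count(genes_per_mag, "genes_per_mag")
  n_genomes <- check_count(n_genomes, "n_genomes")
  for (r in c(true_fraction, decoy_rate, subthreshold_rate)) {
    if (r < 0 || r > 1) stopf("rates must lie in [0, 1]")
  }
  mags <- sprintf("mag_%03d", seq_len(n_mags))
  genomes <- sprintf("genome_%03d", seq_len(n_genomes))
  if (is.null(truth_assignment)) {
    truth_assignment <- stats::setNames(genomes[(seq_len(n_mags) - 1L) %%
                                                  n_genomes + 1L], mags)
  }
  if (is.null(names(truth_assignment))) names(truth_assignment) <- mags
  noise_free <- decoy_rate == 0 && subthreshold_rate == 0 && true_fraction == 1

  with_seed(seed, {
    rows <- list()
    for (mag in names(truth_assignment)) {
      truth <- truth_assignment[[mag]]
      genes <- sprintf("g%04d", seq_len(genes_per_mag))
      n_true <- if (truth == "unassigned") 0L else round(true_fraction * genes_per_mag)
      for (i in seq_along(genes)) {
        q <- sprintf("%s|%s", mag, genes[i])
        qlen <- sample(300:1500, 1)
        if (i <= n_true) {
          ident <- if (noise_free) 100 else round(runif(1, 95, 100), 1)
          cov <- if (noise_free) 1 else runif(1, 0.9, 1)
          rows[[length(rows) + 1L]] <- data.frame(
            qseqid = q, sseqid = truth, pident = ident,
            length = ceiling(cov * qlen), qlen = qlen)
        }
        if (runif(1) < decoy_rate) {
          decoy <- sample(setdiff(genomes, truth), 1)
          rows[[length(rows) + 1L]] <- data.frame(
            qseqid = q, sseqid = decoy, pident = round(runif(1, 95, 100), 1),
            length = ceiling(runif(1, 0.9, 1) * qlen), qlen = qlen)
        }
        if (runif(1) < subthreshold_rate) {
          sub <- sample(genomes, 1)
          low_ident <- runif(1) < 0.5
          rows[[length(rows) + 1L]] <- data.frame(
            qseqid = q, sseqid = sub,
            pident = if (low_ident) round(runif(1, 70, 94.9), 1) else
              round(runif(1, 95, 100), 1),
            length = if (low_ident) round(runif(1, 0.9, 1) * qlen) else
              round(runif(1, 0.3, 0.89) * qlen),
            qlen = qlen)
        }
      }
      # genes with no hit at all simply do not appear in BLAST output;
      # the consensus denominator is restored from gene numbering upstream
    }
    raw <- if (length(rows)) do.call(rbind, rows) else
      data.frame(qseqid = character(), sseqid = character(),
                 pident = numeric(), length = integer(), qlen = integer())
    ght <- parse_gene_hits(raw)
    attr(ght, "truth") <- truth_assignment
    attr(ght, "genes_per_mag") <- genes_per_mag
    attr(ght, "mags") <- names(truth_assignment)
    ght
  })
}
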