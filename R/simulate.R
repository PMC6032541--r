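#' Simulation configuration
#'
#' Collects every knob of the synthetic multi-tissue expression/splicing
#' dataset. The generator plants known cis effects so downstream stages can
#' be validated against a recoverable ground truth:
#'
#' * genotypes with first-order autoregressive LD within each gene's cis
#'   window and Hardy-Weinberg genotypes within breed;
#' * gene-level counts with an additive dosage effect (`geQTL` genes), a
#'   local polygenic term whose per-SNP effects are correlated
#'   `cross_tissue_rg` across tissues, and negative-binomial noise;
#' * exon counts as gene reads split by exon usage, with `sQTL` genes
#'   shifting the target exon's usage by a logistic function of dosage so
#'   that the dosage-2 minus dosage-0 inclusion difference equals
#'   `usage_shift` exactly;
#' * intron junction counts whose cluster share moves opposite to the
#'   included exon.
#'
#' @param n_individuals individuals per cohort.
#' @param tissues named character vector mapping tissue name to cohort label;
#'   tissues in the same cohort share individuals, different cohorts are
#'   disjoint.
#' @param n_genes number of simulated genes (one cis window each).
#' @param exons_per_gene exons per gene (introns are the gaps between them).
#' @param n_snps_per_window SNPs per ±1 Mb cis window.
#' @param ld_decay adjacent-SNP haplotype correlation in `[0, 1)`; LD between
#'   SNPs i and j decays as `ld_decay^|i-j|`.
#' @param maf_range range the per-window allele frequency is drawn from.
#' @param gene_effects character vector recycled over genes, each of
#'   `"none"`, `"geQTL"`, `"sQTL"` or `"breed_sQTL"` (breed-driven usage
#'   shift, no causal SNP).
#' @param effect_size geQTL allelic effect in phenotype SD units.
#' @param usage_shift planted inclusion-ratio difference between dosage 2 and
#'   dosage 0 at the target exon of sQTL genes.
#' @param cross_tissue_rg genetic correlation of per-SNP local effects across
#'   tissues, in `[-1, 1]` (negative values only with exactly 2 tissues).
#' @param h2_local variance fraction of the latent log-expression explained
#'   by the local polygenic term.
#' @param breed_fraction proportion of individuals in the second breed.
#' @param breed_freq_delta allele-frequency offset of the second breed.
#' @param breed_splice_shift inclusion-ratio shift between breeds at the
#'   target exon of `breed_sQTL` genes.
#' @param depth expected gene-level count.
#' @param nb_dispersion negative-binomial dispersion (1/size).
#' @param window cis window half-width in bp.
#' @param seed integer seed; fully determines all generator output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 100,
                       tissues = c(blood = "A", milk = "A",
                                   muscle = "B", liver = "B"),
                       n_genes = 12,
                       exons_per_gene = 4,
                       n_snps_per_window = 40,
                       ld_decay = 0.7,
                       maf_range = c(0.1, 0.5),
                       gene_effects = c("geQTL", "sQTL", "none"),
                       effect_size = 1,
                       usage_shift = 0.3,
                       cross_tissue_rg = 0.8,
                       h2_local = 0.5,
                       breed_fraction = 0,
                       breed_freq_delta = 0,
                       breed_splice_shift = 0,
                       depth = 1000,
                       nb_dispersion = 0.1,
                       window = 1e6,
                       seed = 1) {
  stopifnot(n_individuals >= 2, n_genes >= 1, exons_per_gene >= 2,
            n_snps_per_window >= 1,
            ld_decay >= 0, ld_decay < 1,
            maf_range[1] >= 0.01, maf_range[2] <= 0.5,
            abs(cross_tissue_rg) <= 1,
            h2_local >= 0, h2_local < 1,
            breed_fraction >= 0, breed_fraction <= 1,
            usage_shift >= 0, usage_shift < 0.6)
  if (cross_tissue_rg < 0 && length(tissues) > 2) {
    abort("negative cross_tissue_rg requires exactly 2 tissues")
  }
  cfg <- list(n_individuals = n_individuals, tissues = tissues,
              n_genes = n_genes, exons_per_gene = exons_per_gene,
              n_snps_per_window = n_snps_per_window, ld_decay = ld_decay,
              maf_range = maf_range,
              gene_effects = rep_len(gene_effects, n_genes),
              effect_size = effect_size, usage_shift = usage_shift,
              cross_tissue_rg = cross_tissue_rg, h2_local = h2_local,
              breed_fraction = breed_fraction,
              breed_freq_delta = breed_freq_delta,
              breed_splice_shift = breed_splice_shift,
              depth = depth, nb_dispersion = nb_dispersion,
              window = window, seed = as.integer(seed))
  stopifnot(all(cfg$gene_effects %in%
                  c("none", "geQTL", "sQTL", "breed_sQTL")))
  class(cfg) <- "sim_config"
  cfg
}

# Gene windows are laid out on one chromosome, spaced so cis windows never
# overlap. Deterministic given the config (no RNG).
#' Simulated feature annotation
#'
#' @param config a [sim_config()].
#' @return A feature tibble (genes, exons, introns) as from
#'   [read_features()].
#' @export
sim_features <- function(config) {
  E <- config$exons_per_gene
  exon_len <- 300L
  intron_len <- 500L
  gene_len <- E * exon_len + (E - 1L) * intron_len
  spacing <- 2L * as.integer(config$window) + gene_len + 200000L
  out <- lapply(seq_len(config$n_genes), function(g) {
    gstart <- as.integer(config$window) + 100000L + (g - 1L) * spacing
    gid <- sprintf("gene%02d", g)
    ex_start <- gstart + (seq_len(E) - 1L) * (exon_len + intron_len)
    genes <- tibble(feature_id = gid, kind = "gene", chrom = "1",
                    start = gstart, end = gstart + gene_len - 1L,
                    strand = "+", gene_id = gid)
    exons <- tibble(feature_id = sprintf("%s_exon%d", gid, seq_len(E)),
                    kind = "exon", chrom = "1",
                    start = ex_start, end = ex_start + exon_len - 1L,
                    strand = "+", gene_id = gid)
    bind_rows(genes, exons)
  })
  build_feature_table(bind_rows(out), derive_introns = TRUE)
}

sim_samples <- function(config) {
  cohorts <- sort(unique(config$tissues))
  out <- lapply(cohorts, function(co) {
    id <- sprintf("%s%03d", co, seq_len(config$n_individuals))
    n_j <- round(config$breed_fraction * config$n_individuals)
    tibble(sample_id = id, cohort = co,
           breed = rep(c("J", "H"),
                       c(n_j, config$n_individuals - n_j)))
  })
  bind_rows(out)
}

#' Simulate genotypes with autoregressive LD
#'
#' Draws two haplotypes per individual per gene window. Within a window all
#' SNPs share an allele frequency (drawn once from `maf_range`); each
#' haplotype allele copies the previous SNP's allele with probability
#' `ld_decay` and is otherwise redrawn, so the adjacent-SNP haplotype
#' correlation is `ld_decay` and LD decays geometrically with SNP distance.
#' With `breed_freq_delta != 0` the second breed's frequency is offset,
#' creating allele-frequency differentiation between breeds.
#'
#' @param config a [sim_config()].
#' @return A [geno_matrix()] with a `samples_info` attribute (tibble of
#'   `sample_id`, `cohort`, `breed`).
#' @export
simulate_genotypes <- function(config) {
  set.seed(config$seed)
  feats <- sim_features(config)
  genes <- feats[feats$kind == "gene", , drop = FALSE]
  samples <- sim_samples(config)
  n <- nrow(samples)
  is_j <- rep(samples$breed == "J", each = 2)  # per haplotype
  r <- config$ld_decay
  m <- config$n_snps_per_window
  blocks <- vector("list", nrow(genes))
  for (g in seq_len(nrow(genes))) {
    p1 <- runif(1, config$maf_range[1], config$maf_range[2])
    p2 <- min(max(p1 + config$breed_freq_delta, 0.01), 0.99)
    p_hap <- ifelse(is_j, p2, p1)
    H <- matrix(0L, nrow = 2L * n, ncol = m)
    H[, 1] <- rbinom(2L * n, 1L, p_hap)
    if (m > 1) {
      for (j in 2:m) {
        copy <- rbinom(2L * n, 1L, r)
        H[, j] <- ifelse(copy == 1L, H[, j - 1], rbinom(2L * n, 1L, p_hap))
      }
    }
    dos <- H[seq(1, 2 * n, by = 2), , drop = FALSE] +
      H[seq(2, 2 * n, by = 2), , drop = FALSE]
    lo <- genes$start[g] - config$window
    hi <- genes$end[g] + config$window
    pos <- sort(sample(seq(max(lo, 1), hi), m))
    colnames(dos) <- sprintf("%s_snp%03d", genes$gene_id[g], seq_len(m))
    blocks[[g]] <- list(dos = dos,
                        snps = tibble(snp_id = colnames(dos), chrom = "1",
                                      pos = as.integer(pos),
                                      ref = "A", alt = "B"))
  }
  dosage <- do.call(cbind, lapply(blocks, `[[`, "dos"))
  rownames(dosage) <- samples$sample_id
  g <- geno_matrix(dosage, bind_rows(lapply(blocks, `[[`, "snps")))
  attr(g, "samples_info") <- samples
  g
}

# Causal SNP for a gene: the window SNP nearest the gene midpoint with
# MAF >= 0.1 (deterministic given the genotypes).
pick_causal <- function(genotypes, gene, window) {
  s <- genotypes$snps
  mid <- (gene$start + gene$end) / 2
  cand <- s[s$chrom == gene$chrom &
              s$pos >= gene$start - window & s$pos <= gene$end + window &
              s$maf >= 0.1, , drop = FALSE]
  if (!nrow(cand)) {
    cand <- s[s$chrom == gene$chrom &
                s$pos >= gene$start - window & s$pos <= gene$end + window, ,
              drop = FALSE]
  }
  cand$snp_id[which.min(abs(cand$pos - mid))]
}

#' Ground-truth table for a simulated dataset
#'
#' @param config a [sim_config()].
#' @param genotypes output of [simulate_genotypes()] for the same config.
#' @return Tibble: `gene_id`, `effect_type`, `causal_snp` (NA where no SNP
#'   effect is planted), `effect_size`, `target_exon`, `true_rg`.
#' @export
sim_truth <- function(config, genotypes) {
  feats <- sim_features(config)
  genes <- feats[feats$kind == "gene", , drop = FALSE]
  E <- config$exons_per_gene
  target <- ceiling(E / 2)
  purrr::map_dfr(seq_len(nrow(genes)), function(g) {
    eff <- config$gene_effects[g]
    tibble(gene_id = genes$gene_id[g],
           effect_type = eff,
           causal_snp = if (eff %in% c("geQTL", "sQTL")) {
             pick_causal(genotypes, genes[g, ], config$window)
           } else NA_character_,
           effect_size = switch(eff, geQTL = config$effect_size,
                                sQTL = config$usage_shift,
                                breed_sQTL = config$breed_splice_shift, 0),
           target_exon = if (eff %in% c("sQTL", "breed_sQTL")) {
             sprintf("%s_exon%d", genes$gene_id[g], target)
           } else NA_character_,
           true_rg = config$cross_tissue_rg)
  })
}

# logistic slope b with plogis(logit(p0) + 2 b) - plogis(logit(p0)) == shift
usage_slope <- function(p0, shift) {
  if (shift <= 0) return(0)
  uniroot(function(b) plogis(qlogis(p0) + 2 * b) - p0 - shift,
          c(0, 20))$root
}

#' Simulate per-tissue gene, exon and intron-junction counts
#'
#' Gene-level latent log2 expression is
#' `beta * dosage + a + e`, where `a = Z u` is the local polygenic value
#' (`Z` the standardised window dosages, per-SNP effects `u` correlated
#' `cross_tissue_rg` across tissues, `var(a) = h2_local`) and
#' `var(e) = 1 - h2_local`. Gene counts are negative binomial around
#' `depth * 2^eta`. Exon counts split each drawn gene count by exon usage;
#' the target exon of sQTL genes follows a logistic-in-dosage usage curve
#' calibrated so inclusion at dosage 2 minus dosage 0 equals `usage_shift`.
#' Intron junction counts share a per-gene cluster whose proportions move
#' opposite to the included exon.
#'
#' @param config a [sim_config()].
#' @param genotypes output of [simulate_genotypes()] for the same config.
#' @return Named list (one element per tissue) of lists with elements
#'   `gene`, `exon`, `intron` ([count_matrix()] objects). Attributes:
#'   `truth` (the [sim_truth()] table) and `samples_info`.
#' @export
simulate_counts <- function(config, genotypes) {
  set.seed(config$seed + 1L)
  feats <- sim_features(config)
  genes <- feats[feats$kind == "gene", , drop = FALSE]
  samples <- attr(genotypes, "samples_info")
  if (is.null(samples)) {
    samples <- tibble(sample_id = genotypes$samples, cohort = "A",
                      breed = "H")
  }
  truth <- sim_truth(config, genotypes)
  tissues <- config$tissues
  E <- config$exons_per_gene
  target <- ceiling(E / 2)
  size <- 1 / config$nb_dispersion
  h2 <- config$h2_local
  rg <- config$cross_tissue_rg

  out <- setNames(vector("list", length(tissues)), names(tissues))
  for (tn in names(tissues)) {
    ids <- samples$sample_id[samples$cohort == tissues[[tn]]]
    out[[tn]] <- list(
      gene = matrix(0, nrow(genes), length(ids),
                    dimnames = list(genes$feature_id, ids)),
      exon = NULL, intron = NULL, .exon_rows = list(), .intron_rows = list())
  }

  for (g in seq_len(nrow(genes))) {
    gid <- genes$gene_id[g]
    eff <- config$gene_effects[g]
    win <- feats[feats$kind == "exon" & feats$gene_id == gid, , drop = FALSE]
    snps_in <- genotypes$snps$snp_id[
      genotypes$snps$pos >= genes$start[g] - config$window &
        genotypes$snps$pos <= genes$end[g] + config$window]
    Z <- genotypes$dosage[, snps_in, drop = FALSE]
    sds <- apply(Z, 2, sd)
    Z <- scale(Z[, sds > 0, drop = FALSE])
    m <- ncol(Z)
    # per-SNP local effects, correlated rg across tissues
    nt <- length(tissues)
    U <- if (nt == 2) {
      L <- chol(matrix(c(1, rg, rg, 1), 2))
      matrix(rnorm(m * 2, sd = sqrt(h2 / m)), m, 2) %*% L
    } else {
      shared <- rnorm(m, sd = sqrt(h2 / m))
      sr <- sqrt(max(rg, 0))
      sapply(seq_len(nt), function(t)
        sr * shared + sqrt(1 - max(rg, 0)) * rnorm(m, sd = sqrt(h2 / m)))
    }
    colnames(U) <- names(tissues)
    a_all <- Z %*% U  # all genotyped individuals x tissues
    rownames(a_all) <- genotypes$samples

    causal <- truth$causal_snp[truth$gene_id == gid]
    dose_all <- if (!is.na(causal)) {
      genotypes$dosage[, causal]
    } else setNames(rep(0, length(genotypes$samples)), genotypes$samples)

    # exon usage weights
    pi0 <- rep((1 - 0.35) / (E - 1), E)
    pi0[target] <- 0.35
    slope <- if (eff == "sQTL") usage_slope(pi0[target], config$usage_shift)
             else 0

    for (tn in names(tissues)) {
      ids <- samples$sample_id[samples$cohort == tissues[[tn]]]
      breed_j <- samples$breed[match(ids, samples$sample_id)] == "J"
      d <- dose_all[ids]
      beta <- if (eff == "geQTL") config$effect_size else 0
      eta <- beta * (d - mean(d)) + a_all[ids, tn] +
        rnorm(length(ids), sd = sqrt(1 - h2))
      mu_g <- config$depth * 2^(eta - median(eta))
      gene_cnt <- rnbinom(length(ids), mu = mu_g, size = size)
      out[[tn]]$gene[gid, ] <- gene_cnt

      p_target <- plogis(qlogis(pi0[target]) + slope * d)
      if (eff == "breed_sQTL") {
        p_target <- pmin(pmax(
          pi0[target] + config$breed_splice_shift * breed_j, 0.02), 0.98)
      }
      other <- setdiff(seq_len(E), target)
      Pi <- matrix(0, E, length(ids))
      Pi[target, ] <- p_target
      for (k in other) {
        Pi[k, ] <- (1 - p_target) * pi0[k] / sum(pi0[other])
      }
      exon_cnt <- matrix(rnbinom(E * length(ids),
                                 mu = rep(gene_cnt, each = E) * Pi,
                                 size = 4 * size),
                         E, length(ids),
                         dimnames = list(sprintf("%s_exon%d", gid, seq_len(E)),
                                         ids))
      # intron cluster: junction adjacent to the target exon gains weight
      # as the exon is excluded
      nI <- E - 1
      w <- matrix(1, nI, length(ids))
      adj <- max(target - 1, 1)
      w[adj, ] <- 2 * (1 - p_target)
      Rho <- sweep(w, 2, colSums(w), "/")
      intr_cnt <- matrix(rnbinom(nI * length(ids),
                                 mu = rep(round(gene_cnt * 0.5), each = nI) * Rho,
                                 size = 4 * size),
                         nI, length(ids),
                         dimnames = list(sprintf("%s_intron%d", gid, seq_len(nI)),
                                         ids))
      out[[tn]]$.exon_rows[[gid]] <- exon_cnt
      out[[tn]]$.intron_rows[[gid]] <- intr_cnt
    }
  }

  for (tn in names(tissues)) {
    exon_m <- do.call(rbind, out[[tn]]$.exon_rows)
    intr_m <- do.call(rbind, out[[tn]]$.intron_rows)
    out[[tn]] <- list(gene = count_matrix(out[[tn]]$gene, feats),
                      exon = count_matrix(exon_m, feats),
                      intron = count_matrix(intr_m, feats))
  }
  attr(out, "truth") <- truth
  attr(out, "samples_info") <- samples
  out
}

#' Simulate two-cohort GWAS summary statistics
#'
#' Per trait and SNP, draws estimated effects around a planted true effect
#' with cohort-specific standard errors, emulating summary statistics from
#' sex-separated cohorts whose phenotypic error differs (e.g. bulls with
#' daughter-mean phenotypes vs individually phenotyped cows).
#'
#' @param config a [sim_config()] (supplies the seed).
#' @param genotypes a [geno_matrix()] naming the SNPs.
#' @param n_traits number of traits.
#' @param true_effects optional numeric matrix (SNPs x traits) of true
#'   effects; defaults to all zero (a null GWAS).
#' @param se_bull,se_cow per-cohort standard errors of the estimated effect.
#' @return Named list with elements `bull` and `cow`, each a tibble
#'   `snp_id, trait, B, se`.
#' @export
simulate_gwas_summaries <- function(config, genotypes, n_traits = 2,
                                    true_effects = NULL,
                                    se_bull = 1, se_cow = 2) {
  set.seed(config$seed + 2L)
  snps <- genotypes$snps$snp_id
  if (is.null(true_effects)) {
    true_effects <- matrix(0, length(snps), n_traits)
  }
  stopifnot(nrow(true_effects) == length(snps),
            ncol(true_effects) == n_traits)
  one <- function(se_c) {
    purrr::map_dfr(seq_len(n_traits), function(tr) {
      tibble(snp_id = snps, trait = sprintf("trait%d", tr),
             B = true_effects[, tr] + rnorm(length(snps), sd = se_c),
             se = se_c)
    })
  }
  list(bull = one(se_bull), cow = one(se_cow))
}

#' Simulate a bivariate phenotype pair structured by a local window
#'
#' Draws two traits `y_t = Z u_t + e_t` from the standardised dosages `Z` of
#' a SNP window, with per-SNP effects `u` correlated `rg` across traits and
#' `var(Z u) = h2`. This is the exact generating model of the local-GRM
#' bivariate REML, so the REML estimand equals `rg`.
#'
#' @param genotypes a [geno_matrix()].
#' @param snp_ids SNPs forming the local window (default: all).
#' @param h2 local heritability of each trait.
#' @param rg genetic correlation between the traits.
#' @param shared if TRUE both traits are observed on all individuals; if
#'   FALSE the sample set is split in half, one half per trait.
#' @param seed integer seed.
#' @return List with named numeric vectors `y1`, `y2` (names = sample ids).
#' @export
simulate_bivar_phenotypes <- function(genotypes, snp_ids = NULL, h2 = 0.5,
                                      rg = 0.8, shared = TRUE, seed = 1) {
  set.seed(seed)
  if (is.null(snp_ids)) snp_ids <- genotypes$snps$snp_id
  Z <- genotypes$dosage[, snp_ids, drop = FALSE]
  Z <- Z[, apply(Z, 2, sd) > 0, drop = FALSE]
  Z <- scale(Z)
  m <- ncol(Z)
  n <- nrow(Z)
  L <- chol(matrix(c(1, rg, rg, 1), 2) + diag(1e-10, 2))
  U <- matrix(rnorm(m * 2, sd = sqrt(h2 / m)), m, 2) %*% L
  A <- Z %*% U
  Y <- A + matrix(rnorm(n * 2, sd = sqrt(1 - h2)), n, 2)
  rownames(Y) <- rownames(Z)
  if (shared) {
    list(y1 = setNames(Y[, 1], rownames(Y)),
         y2 = setNames(Y[, 2], rownames(Y)))
  } else {
    half <- seq_len(floor(n / 2))
    list(y1 = setNames(Y[half, 1], rownames(Y)[half]),
         y2 = setNames(Y[-half, 2], rownames(Y)[-half]))
  }
}

#' Write a simulated dataset to disk
#'
#' Emits genotypes (TSV and VCF), the feature annotation (GFF3 and TSV),
#' per-tissue gene/exon/intron count TSVs, the truth table and the resolved
#' configuration (YAML).
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- simulate_genotypes(config)
  cts <- simulate_counts(config, g)
  feats <- sim_features(config)
  write_genotypes(g, file.path(dir, "genotypes.tsv"))
  write_genotypes_vcf(g, file.path(dir, "genotypes.vcf"))
  write_features(feats, file.path(dir, "features.tsv"))
  write_features_gff3(feats, file.path(dir, "features.gff3"))
  for (tn in names(cts)) {
    for (k in c("gene", "exon", "intron")) {
      write_counts(cts[[tn]][[k]], file.path(dir, sprintf("%s_%s.tsv", tn, k)))
    }
  }
  tr <- attr(cts, "truth")
  write.table(as.data.frame(tr), file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  yaml::write_yaml(unclass(config)[setdiff(names(config), "tissues")],
                   file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Write a feature table as GFF3
#'
#' @param features a feature tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_features_gff3 <- function(features, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  f <- as.data.frame(features)
  attr_col <- ifelse(f$kind == "gene",
                     paste0("ID=", f$feature_id),
                     paste0("ID=", f$feature_id, ";Parent=", f$gene_id))
  writeLines(paste(f$chrom, "sqtlkit", f$kind, f$start, f$end, ".",
                   f$strand, ".", attr_col, sep = "\t"), con)
  invisible(path)
}
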