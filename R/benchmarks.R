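# Reproducible simulation studies: each function generates data with known
# ground truth, runs the corresponding pipeline stage end-to-end, and
# returns the measured operating characteristics. The vignette discusses
# the study conditions; the acceptance script reports the numbers.

#' Simulation study: sQTL recovery and false discovery control
#'
#' Each replicate simulates one gene with a planted splicing QTL
#' (inclusion-ratio shift `usage_shift` at the target exon) plus
#' `n_null_genes` genes with no effect, builds inclusion and excision
#' phenotypes, runs both cis scans and applies the conjunction calling
#' rule. Recovery counts a replicate as a success when the causal SNP, or a
#' SNP in LD with it at r^2 > `ld_r2`, is called for the target gene. The
#' realised FDR pools calls over replicates and takes the fraction whose
#' gene carries no planted effect.
#'
#' @param n_reps number of replicates.
#' @param n individuals per replicate.
#' @param usage_shift planted inclusion difference (dosage 2 vs 0).
#' @param n_null_genes effect-free genes per replicate.
#' @param fdr per-scan conjunction threshold.
#' @param ld_r2 LD proxy threshold for crediting recovery.
#' @param seed integer seed.
#' @return List: `recovery_rate`, `realized_fdr`, `n_calls`,
#'   `n_false_calls`, `n_reps`.
#' @export
study_sqtl_recovery <- function(n_reps = 50, n = 200, usage_shift = 0.3,
                                n_null_genes = 4, fdr = 0.1, ld_r2 = 0.8,
                                seed = 1) {
  hits <- logical(n_reps)
  n_calls <- 0L
  n_false <- 0L
  for (i in seq_len(n_reps)) {
    cfg <- sim_config(n_individuals = n, n_genes = 1 + n_null_genes,
                      gene_effects = c("sQTL", rep("none", n_null_genes)),
                      usage_shift = usage_shift, tissues = c(a = "A"),
                      seed = seed + 7919L * i)
    g <- simulate_genotypes(cfg)
    cts <- simulate_counts(cfg, g)
    truth <- attr(cts, "truth")
    feats <- sim_features(cfg)
    ph_in <- suppressMessages(suppressWarnings(
      normalize_ratios(inclusion_ratio(cts$a$exon, cts$a$gene))))
    ph_ex <- suppressMessages(suppressWarnings(
      normalize_ratios(excision_ratio(cts$a$intron))))
    sc_in <- scan_cis(ph_in, g)
    sc_ex <- scan_cis(ph_ex, g)
    calls <- call_sqtls(sc_in, sc_ex, feats, fdr = fdr)
    n_calls <- n_calls + nrow(calls)
    sq_gene <- truth$gene_id[truth$effect_type == "sQTL"]
    n_false <- n_false + sum(calls$gene_id != sq_gene)
    causal <- truth$causal_snp[truth$effect_type == "sQTL"]
    cand <- calls$snp_id[calls$gene_id == sq_gene]
    if (length(cand)) {
      r2 <- cor(g$dosage[, causal], g$dosage[, cand, drop = FALSE])[1, ]^2
      hits[i] <- any(r2 > ld_r2)
    }
  }
  list(recovery_rate = mean(hits),
       realized_fdr = if (n_calls > 0) n_false / n_calls else 0,
       n_calls = n_calls, n_false_calls = n_false, n_reps = n_reps)
}

#' Simulation study: genetic-correlation recovery by local-GRM REML
#'
#' Each replicate draws a fresh cis window, builds the local GRM, simulates
#' a bivariate phenotype pair with local heritability `h2` and genetic
#' correlation `rg` on `n` shared individuals, and fits [bivariate_reml()].
#' The likelihood-ratio p value against `r = 0` is collected per replicate.
#'
#' @param n_reps number of replicates.
#' @param n shared individuals.
#' @param h2 local heritability of each trait.
#' @param rg true genetic correlation.
#' @param n_snps SNPs per window.
#' @param seed integer seed.
#' @return List: `mean_rg` (over converged, interior fits), `rg` estimates,
#'   `p_vs_0` vector, `coverage` of the +/-2 SE interval, `n_reps`.
#' @export
study_rg_recovery <- function(n_reps = 50, n = 300, h2 = 0.5, rg = 0.8,
                              n_snps = 60, seed = 1) {
  est <- p0 <- cover <- rep(NA_real_, n_reps)
  for (i in seq_len(n_reps)) {
    cfg <- sim_config(n_individuals = n, n_genes = 1,
                      n_snps_per_window = n_snps, tissues = c(a = "A"),
                      seed = seed + 104729L * i)
    g <- simulate_genotypes(cfg)
    grm <- build_lgrm(g, method = "gcta")
    yy <- simulate_bivar_phenotypes(g, h2 = h2, rg = rg,
                                    seed = seed + 104729L * i + 1L)
    fit <- bivariate_reml(yy$y1, yy$y2, grm)
    est[i] <- fit$r_lg
    if (!is.na(fit$r_lg) && !is.na(fit$se_r)) {
      cover[i] <- abs(fit$r_lg - rg) <= 2 * fit$se_r
    }
    p0[i] <- test_rg(fit, 0)$p
  }
  list(mean_rg = mean(est, na.rm = TRUE), rg = est, p_vs_0 = p0,
       coverage = mean(cover, na.rm = TRUE), n_reps = n_reps)
}

#' Simulation study: calibration of the meta-analysis statistics
#'
#' Draws independent null t values for `n_pairs` (SNP, feature) pairs in
#' `n_tissues` tissues, combines them with [meta_combine()], and measures
#' the rejection rate at `alpha`. Also draws correlated multi-trait null t
#' vectors and tests the [multitrait_chisq()] statistic against its
#' chi-square reference with a Kolmogorov-Smirnov test.
#'
#' @param n_pairs null pairs for the combined statistic.
#' @param n_tissues tissues combined.
#' @param alpha nominal level.
#' @param n_traits traits for the multi-trait null.
#' @param rho trait-correlation of the multi-trait null.
#' @param seed integer seed.
#' @return List: `meta_rejection_rate`, `binomial_ci` (95% interval around
#'   `alpha`), `multitrait_ks_p`.
#' @export
study_meta_calibration <- function(n_pairs = 10000, n_tissues = 3,
                                   alpha = 0.05, n_traits = 4, rho = 0.6,
                                   seed = 1) {
  set.seed(seed)
  tm <- matrix(rnorm(n_pairs * n_tissues), n_pairs, n_tissues)
  rate <- mean(meta_combine(tm)$p < alpha)
  V <- matrix(rho, n_traits, n_traits)
  diag(V) <- 1
  tmat <- matrix(rnorm(n_pairs * n_traits), n_pairs, n_traits) %*% chol(V)
  ks <- stats::ks.test(multitrait_chisq(tmat, V)$chi2, pchisq,
                       df = n_traits)
  list(meta_rejection_rate = rate,
       binomial_ci = alpha + c(-1, 1) * 1.96 *
         sqrt(alpha * (1 - alpha) / n_pairs),
       multitrait_ks_p = ks$p.value)
}

#' Simulation study: tissue mixed-model calibration
#'
#' Generates `n_features` null features (a real animal effect, no tissue
#' effect) on a repeated-measures design of `n_animals` animals in
#' `n_tissues` tissues and measures the tissue-test type-I error at
#' `alpha`. Also verifies the degenerate limit on a single-observation
#' design: with every animal observed once the mixed-model F must equal
#' the OLS two-way ANOVA F.
#'
#' @param n_features null features for the type-I error.
#' @param n_animals animals (each observed in every tissue).
#' @param n_tissues tissues.
#' @param animal_sd SD of the animal random effect.
#' @param alpha nominal level.
#' @param n_check features for the degenerate-limit comparison.
#' @param seed integer seed.
#' @return List: `type1_rate`, `binomial_ci`, `max_f_diff` (degenerate
#'   limit), `n_features`.
#' @export
study_tissue_type1 <- function(n_features = 1000, n_animals = 20,
                               n_tissues = 3, animal_sd = 1, alpha = 0.05,
                               n_check = 25, seed = 1) {
  set.seed(seed)
  tissues <- paste0("t", seq_len(n_tissues))
  design <- tibble(
    sample_id = sprintf("a%02d_%s", rep(seq_len(n_animals), n_tissues),
                        rep(tissues, each = n_animals)),
    animal = rep(sprintf("an%02d", seq_len(n_animals)), n_tissues),
    experiment = rep(rep_len(c("E1", "E2"), n_animals), n_tissues),
    tissue = rep(tissues, each = n_animals))
  feats <- tibble(feature_id = sprintf("f%04d", seq_len(n_features)),
                  kind = "exon", chrom = "1", start = 1, end = 10,
                  strand = "+",
                  gene_id = sprintf("g%04d", seq_len(n_features)),
                  tss = NA_integer_)
  an_idx <- as.integer(factor(design$animal))
  vals <- t(vapply(seq_len(n_features), function(i) {
    rnorm(n_animals, sd = animal_sd)[an_idx] + rnorm(nrow(design))
  }, numeric(nrow(design))))
  dimnames(vals) <- list(feats$feature_id, design$sample_id)
  ph <- pheno_matrix(vals, feats, "inclusion")
  res <- suppressWarnings(tissue_mixed_model(ph, design))
  type1 <- mean(res$p < alpha)

  # degenerate limit: unique animals, OLS equivalence
  design1 <- design
  design1$animal <- sprintf("u%03d", seq_len(nrow(design)))
  ph1 <- pheno_matrix(vals[seq_len(n_check), , drop = FALSE],
                      feats[seq_len(n_check), ], "inclusion")
  res1 <- suppressWarnings(tissue_mixed_model(ph1, design1))
  f_ols <- vapply(seq_len(n_check), function(i) {
    d <- design1
    d$y <- vals[i, ]
    anova(lm(y ~ experiment + tissue, data = d))["tissue", "F value"]
  }, numeric(1))
  list(type1_rate = type1,
       binomial_ci = alpha + c(-1, 1) * 1.96 *
         sqrt(alpha * (1 - alpha) / n_features),
       max_f_diff = max(abs(res1$statistic - f_ols)),
       n_features = n_features)
}

#' Simulation study: cis-scan agreement with the normal-equations oracle
#'
#' Random fixtures (varying sample size, SNP count, covariates and missing
#' phenotypes) are scanned with [scan_cis()] and every (SNP, feature)
#' estimate is compared against `lm()`.
#'
#' @param n_fixtures number of random fixtures.
#' @param seed integer seed.
#' @return List: `max_abs_beta_diff`, `max_abs_se_diff`, `max_abs_p_diff`,
#'   `n_comparisons`.
#' @export
study_scan_oracle <- function(n_fixtures = 20, seed = 1) {
  set.seed(seed)
  dmax <- c(beta = 0, se = 0, p = 0)
  n_cmp <- 0L
  for (rep in seq_len(n_fixtures)) {
    n <- sample(30:60, 1)
    m <- sample(4:10, 1)
    p_snp <- runif(m, 0.1, 0.5)
    dos <- matrix(rbinom(n * m, 2, rep(p_snp, each = n)), n, m,
                  dimnames = list(sprintf("s%03d", seq_len(n)), NULL))
    g <- geno_matrix(dos, tibble(snp_id = sprintf("snp%03d", seq_len(m)),
                                 chrom = "1",
                                 pos = seq(1500L, by = 300L,
                                           length.out = m),
                                 ref = "A", alt = "B"))
    feats <- tibble(feature_id = "f1", kind = "exon", chrom = "1",
                    start = 1000L, end = 1200L, strand = "+",
                    gene_id = "g1", tss = NA_integer_)
    y <- rnorm(n)
    y[sample(n, 3)] <- NA
    covar <- tibble(sample_id = g$samples,
                    breed = sample(c("H", "J"), n, replace = TRUE))
    ph <- pheno_matrix(matrix(y, 1, n,
                              dimnames = list("f1", g$samples)),
                       feats, "inclusion")
    res <- scan_cis(ph, g, covariates = covar)
    for (j in seq_len(nrow(res))) {
      fit <- summary(lm(y ~ x + breed,
                        data = data.frame(y = y,
                                          x = g$dosage[, res$snp_id[j]],
                                          breed = covar$breed)))$coefficients
      dmax <- pmax(dmax, c(abs(res$beta[j] - fit["x", "Estimate"]),
                           abs(res$se[j] - fit["x", "Std. Error"]),
                           abs(res$p[j] - fit["x", "Pr(>|t|)"])))
      n_cmp <- n_cmp + 1L
    }
  }
  list(max_abs_beta_diff = unname(dmax["beta"]),
       max_abs_se_diff = unname(dmax["se"]),
       max_abs_p_diff = unname(dmax["p"]),
       n_comparisons = n_cmp)
}
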