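test_that("generators are deterministic under a fixed seed", {
  cfg <- sim_config(n_individuals = 20, n_genes = 2, n_snps_per_window = 10,
                    tissues = c(a = "A", b = "A"), seed = 9)
  g1 <- simulate_genotypes(cfg)
  g2 <- simulate_genotypes(cfg)
  expect_identical(g1$dosage, g2$dosage)
  c1 <- simulate_counts(cfg, g1)
  c2 <- simulate_counts(cfg, g2)
  expect_identical(c1$a$gene$counts, c2$a$gene$counts)
  expect_identical(c1$b$intron$counts, c2$b$intron$counts)
  s1 <- simulate_gwas_summaries(cfg, g1, n_traits = 2)
  s2 <- simulate_gwas_summaries(cfg, g1, n_traits = 2)
  expect_identical(s1$bull, s2$bull)
  expect_identical(s1$cow, s2$cow)
})

test_that("LD structure follows the autoregressive target", {
  # independence limit
  cfg0 <- sim_config(n_individuals = 500, n_genes = 1,
                     n_snps_per_window = 20, ld_decay = 0,
                     tissues = c(a = "A"), seed = 101)
  g0 <- simulate_genotypes(cfg0)
  cc0 <- sapply(1:19, function(j) cor(g0$dosage[, j], g0$dosage[, j + 1]))
  expect_lt(max(abs(cc0)), 0.1)

  # strong LD: adjacent-SNP correlation near the planted ld_decay
  cfg9 <- sim_config(n_individuals = 1000, n_genes = 1,
                     n_snps_per_window = 20, ld_decay = 0.9,
                     tissues = c(a = "A"), seed = 102)
  g9 <- simulate_genotypes(cfg9)
  cc9 <- sapply(1:19, function(j) cor(g9$dosage[, j], g9$dosage[, j + 1]))
  expect_lt(abs(mean(cc9) - 0.9), 0.05)

  # realized MAF within the configured range (with sampling slack)
  expect_true(all(g9$snps$maf >= 0.05))
})

test_that("planted geQTL effect size is recovered by OLS on log2 CPM", {
  # enough genes that the causal gene is a small share of the library,
  # otherwise CPM normalisation absorbs part of its own effect
  cfg <- sim_config(n_individuals = 200, n_genes = 10, effect_size = 1,
                    gene_effects = c("geQTL", rep("none", 9)),
                    tissues = c(a = "A"), seed = 103)
  g <- simulate_genotypes(cfg)
  cts <- simulate_counts(cfg, g)
  truth <- attr(cts, "truth")
  lcpm <- log2(cpm(cts$a$gene) + 0.5)
  d <- g$dosage[cts$a$gene$samples, truth$causal_snp[1]]
  fit <- lm(lcpm["gene01", ] ~ d)
  est <- summary(fit)$coefficients["d", ]
  expect_lt(abs(est["Estimate"] - 1), 2 * est["Std. Error"])
  # null gene shows no association with its window's central SNP
  d0 <- g$dosage[cts$a$gene$samples,
                 sqtlkit:::pick_causal(g, sim_features(cfg)[
                   sim_features(cfg)$feature_id == "gene02", ], cfg$window)]
  t0 <- summary(lm(lcpm["gene02", ] ~ d0))$coefficients[2, "t value"]
  expect_lt(abs(t0), 4)
})

test_that("planted sQTL shifts the target exon's inclusion by usage_shift", {
  cfg <- sim_config(n_individuals = 500, n_genes = 1, usage_shift = 0.3,
                    gene_effects = "sQTL", tissues = c(a = "A"), seed = 104)
  g <- simulate_genotypes(cfg)
  cts <- simulate_counts(cfg, g)
  truth <- attr(cts, "truth")
  incl <- inclusion_ratio(cts$a$exon, cts$a$gene)
  d <- g$dosage[cts$a$gene$samples, truth$causal_snp[1]]
  r <- incl$values[truth$target_exon[1], ]
  grp <- tapply(r, d, mean, na.rm = TRUE)
  expect_lt(abs((grp["2"] - grp["0"]) - 0.3), 0.05)
  # monotone in dosage, planted direction
  expect_true(grp["0"] < grp["1"] && grp["1"] < grp["2"])
})

test_that("intron cluster moves opposite to the included exon", {
  cfg <- sim_config(n_individuals = 400, n_genes = 1, usage_shift = 0.3,
                    gene_effects = "sQTL", tissues = c(a = "A"), seed = 105)
  g <- simulate_genotypes(cfg)
  cts <- simulate_counts(cfg, g)
  truth <- attr(cts, "truth")
  exc <- excision_ratio(cts$a$intron)
  d <- g$dosage[cts$a$intron$samples, truth$causal_snp[1]]
  # the junction adjacent to the target exon loses share as inclusion rises
  adj <- sprintf("%s_intron%d", truth$gene_id[1],
                 max(as.integer(sub(".*exon", "", truth$target_exon[1])) - 1,
                     1))
  grp <- tapply(exc$values[adj, ], d, mean, na.rm = TRUE)
  expect_true(grp["2"] < grp["0"])
})

test_that("GWAS summaries are calibrated under the null and weight by precision", {
  cfg <- sim_config(n_individuals = 2, n_genes = 100,
                    n_snps_per_window = 100, tissues = c(a = "A"),
                    seed = 106)
  g <- simulate_genotypes(cfg)
  gw <- simulate_gwas_summaries(cfg, g, n_traits = 1, se_bull = 1,
                                se_cow = 2)
  z <- gw$bull$B / gw$bull$se
  expect_lt(abs(mean(z)), 0.03)
  expect_lt(abs(var(z) - 1), 0.05)

  # planted effect: the weighted estimate leans toward the precise cohort
  eff <- matrix(0.5, nrow(g$snps), 1)
  gw2 <- simulate_gwas_summaries(cfg, g, n_traits = 1, true_effects = eff,
                                 se_bull = 1, se_cow = 2)
  w <- weighted_t(gw2$bull$B, gw2$bull$se, gw2$cow$B, gw2$cow$se)
  expect_lt(mean(abs(w$B_w - gw2$bull$B)), mean(abs(w$B_w - gw2$cow$B)))
})

test_that("cross-tissue genetic values realise the planted correlation", {
  cfg <- sim_config(n_individuals = 500, n_genes = 1,
                    n_snps_per_window = 60, tissues = c(a = "A"), seed = 107)
  g <- simulate_genotypes(cfg)
  # near-noiseless traits expose the genetic-value correlation directly
  yy <- simulate_bivar_phenotypes(g, h2 = 0.95, rg = 0.8, seed = 108)
  expect_lt(abs(cor(yy$y1, yy$y2) - 0.8 * 0.95), 0.1)
})

test_that("a simulated dataset writes and re-reads coherently", {
  cfg <- sim_config(n_individuals = 15, n_genes = 2, n_snps_per_window = 12,
                    tissues = c(a = "A", b = "B"), seed = 109)
  dir <- withr::local_tempdir()
  write_simulation(cfg, dir)
  g <- quiet(read_genotypes(file.path(dir, "genotypes.tsv"), maf_min = 0))
  gv <- quiet(read_genotypes(file.path(dir, "genotypes.vcf"), maf_min = 0))
  expect_identical(g$dosage[gv$samples, ], gv$dosage)
  feats <- read_features(file.path(dir, "features.tsv"))
  cm <- read_counts(file.path(dir, "a_gene.tsv"), feats)
  expect_equal(dim(cm$counts), c(2L, 15L))
  truth <- read.table(file.path(dir, "truth.tsv"), header = TRUE, sep = "\t")
  expect_true(all(stats::na.omit(truth$causal_snp) %in% g$snps$snp_id))
})
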