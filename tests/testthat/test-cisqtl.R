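scan_fixture <- function(n = 50, m = 8, seed = 51) {
  set.seed(seed)
  dos <- random_hwe_dosage(n, m)
  g <- toy_genotypes(dos, pos = seq(2000, by = 400, length.out = m))
  feats <- toy_features(n_exons = 2)
  list(g = g, feats = feats)
}

test_that("a noiseless phenotype recovers its constructed effect exactly", {
  fx <- scan_fixture()
  y <- 0.5 * fx$g$dosage[, 3]
  vals <- matrix(y, 1, length(y),
                 dimnames = list("g1_e1", fx$g$samples))
  ph <- pheno_matrix(vals, fx$feats, "inclusion")
  res <- scan_cis(ph, fx$g, window = 1e6)
  hit <- res[res$snp_id == "snp003", ]
  expect_equal(hit$beta, 0.5, tolerance = 1e-12)
  expect_lt(hit$p, 1e-200)
})

test_that("an orthogonalised dosage shows a null effect", {
  fx <- scan_fixture(seed = 52)
  y <- rnorm(50)
  x <- fx$g$dosage[, 1]
  y <- y - sum(y * x) / sum(x * x) * x  # orthogonal to snp001, no intercept
  y <- y - mean(y) + 0  # keep centred; residualisation vs intercept+dosage
  # orthogonalise against both intercept and dosage
  Xm <- cbind(1, x)
  y <- y - Xm %*% solve(crossprod(Xm), crossprod(Xm, y))
  vals <- matrix(as.numeric(y), 1, 50, dimnames = list("g1_e1", fx$g$samples))
  ph <- pheno_matrix(vals, fx$feats, "inclusion")
  res <- scan_cis(ph, fx$g)
  expect_lt(abs(res$statistic[res$snp_id == "snp001"]), 1e-6)
})

test_that("scan estimates match the lm() oracle on random fixtures", {
  set.seed(53)
  for (rep in 1:20) {
    n <- sample(30:60, 1)
    m <- sample(4:10, 1)
    dos <- random_hwe_dosage(n, m)
    g <- toy_genotypes(dos, pos = seq(1500, by = 300, length.out = m))
    feats <- toy_features(n_exons = 2)
    y <- rnorm(n)
    y[sample(n, 3)] <- NA  # exercise pairwise-complete handling
    covar <- tibble::tibble(sample_id = g$samples,
                            breed = sample(c("H", "J"), n, replace = TRUE))
    vals <- matrix(y, 1, n, dimnames = list("g1_e1", g$samples))
    ph <- pheno_matrix(vals, feats, "inclusion")
    res <- scan_cis(ph, g, covariates = covar)
    for (j in seq_len(nrow(res))) {
      d <- tibble::tibble(y = y, x = g$dosage[, res$snp_id[j]],
                          breed = covar$breed)
      fit <- summary(lm(y ~ x + breed, data = d))$coefficients
      expect_equal(res$beta[j], fit["x", "Estimate"], tolerance = 1e-8)
      expect_equal(res$se[j], fit["x", "Std. Error"], tolerance = 1e-8)
      expect_equal(res$p[j], fit["x", "Pr(>|t|)"], tolerance = 1e-8)
    }
  }
})

test_that("the cis window is symmetric about feature boundaries", {
  dos <- random_hwe_dosage(40, 4)
  feats <- toy_features(n_exons = 2)
  gene <- feats[feats$feature_id == "g1", ]
  w <- 10000
  pos <- c(gene$start - w, gene$start - w - 1, gene$end + w, gene$end + w + 1)
  g <- toy_genotypes(dos, pos = pos)
  vals <- matrix(rnorm(40), 1, 40, dimnames = list("g1", g$samples))
  ph <- pheno_matrix(vals, feats, "gene_expr")
  res <- scan_cis(ph, g, window = w)
  tested <- sort(res$pos)
  expect_equal(tested, c(gene$start - w, gene$end + w))
})

test_that("sQTL calls demand the same SNP to pass both exon and intron filters", {
  base <- tibble::tibble(kind = "exon", chrom = "1", pos = 1L, n = 50,
                         beta = 1, se = 0.1, statistic = 10)
  exon_assoc <- dplyr::bind_rows(
    dplyr::mutate(base, feature_id = "g1_e1", gene_id = "g1",
                  snp_id = "snpA", p = 1e-5, q = 0.05),
    dplyr::mutate(base, feature_id = "g1_e1", gene_id = "g1",
                  snp_id = "snpB", p = 1e-4, q = 0.05))
  intron_assoc <- dplyr::bind_rows(
    dplyr::mutate(base, kind = "intron", feature_id = "g1_intron1",
                  gene_id = "g1", snp_id = "snpA", p = 1e-3, q = 0.02),
    dplyr::mutate(base, kind = "intron", feature_id = "g1_intron1",
                  gene_id = "g1", snp_id = "snpB", p = 0.5, q = 0.9))
  feats <- toy_features(n_exons = 3)
  calls <- call_sqtls(exon_assoc, intron_assoc, feats)
  expect_equal(calls$snp_id, "snpA")
  expect_equal(calls$intron_ids, "g1_intron1")
  expect_equal(attr(calls, "combined_threshold"), 0.01)
  # snpB fails the intron side -> no call despite exon significance
  expect_false("snpB" %in% calls$snp_id)
})

test_that("QTL type membership mirrors the underlying significant sets", {
  fx <- scan_fixture(seed = 54)
  mk <- function(snp_ids, q, kind, fid) {
    tibble::tibble(feature_id = fid, kind = kind, gene_id = "g1",
                   snp_id = snp_ids, chrom = "1", pos = 1L, n = 50,
                   beta = 1, se = 1, statistic = 1, p = q, q = q)
  }
  incl <- mk(c("s1", "s2"), c(0.05, 0.5), "exon", "g1_e1")
  intr <- mk(c("s1", "s2"), c(0.05, 0.5), "intron", "g1_intron1")
  ee <- mk(c("s1", "s3"), c(0.005, 0.5), "exon", "g1_e1")
  ge <- mk(c("s3", "s4"), c(0.001, 0.002), "gene", "g1")
  mem <- classify_qtl_types(incl, intr, ee, ge, toy_features(3))
  expect_setequal(mem$snp_id, c("s1", "s2", "s3", "s4"))
  expect_equal(sum(mem$sQTL), 1)   # only s1 passes the conjunction
  expect_equal(sum(mem$eeQTL), 1)  # s1 at q < 0.01
  expect_equal(sum(mem$geQTL), 2)
  expect_true(all(!mem[mem$snp_id == "s2", c("sQTL", "eeQTL", "geQTL")]))
})

test_that("fitting breed as a covariate removes a breed-driven confound", {
  cfg <- sim_config(n_individuals = 200, n_genes = 1,
                    gene_effects = "breed_sQTL", breed_fraction = 0.5,
                    breed_freq_delta = 0.3, breed_splice_shift = 0.3,
                    tissues = c(milk = "A"), seed = 55)
  g <- simulate_genotypes(cfg)
  cts <- simulate_counts(cfg, g)
  info <- attr(cts, "samples_info")
  truth <- attr(cts, "truth")
  incl <- inclusion_ratio(cts$milk$exon, cts$milk$gene)
  ph <- quiet(normalize_ratios(incl))
  target <- truth$target_exon[1]
  keep <- rownames(ph$values) == target
  ph_t <- pheno_matrix(ph$values[keep, , drop = FALSE], ph$features, ph$kind)
  naive <- scan_cis(ph_t, g)
  adjusted <- scan_cis(ph_t, g,
                       covariates = info[c("sample_id", "breed")])
  # no causal SNP exists; breed stratification inflates the naive scan
  expect_gt(median(abs(naive$statistic)), median(abs(adjusted$statistic)))
  expect_lt(median(abs(adjusted$statistic)), 2)
})
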