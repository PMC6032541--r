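make_design <- function(n_animal, tissues, experiments = c("E1", "E2"),
                        repeat_animals = TRUE) {
  k <- length(tissues)
  tibble::tibble(
    sample_id = sprintf("a%02d_%s", rep(seq_len(n_animal), k),
                        rep(tissues, each = n_animal)),
    animal = if (repeat_animals) {
      rep(sprintf("an%02d", seq_len(n_animal)), k)
    } else sprintf("u%03d", seq_len(n_animal * k)),
    experiment = rep(rep_len(experiments, n_animal), k),
    tissue = rep(tissues, each = n_animal))
}

make_pheno <- function(n_feat, design, kind = "exon") {
  feats <- tibble::tibble(feature_id = sprintf("f%03d", seq_len(n_feat)),
                          kind = kind, chrom = "1", start = 1, end = 10,
                          strand = "+",
                          gene_id = sprintf("g%03d", seq_len(n_feat)),
                          tss = NA_integer_)
  vals <- matrix(rnorm(n_feat * nrow(design)), n_feat, nrow(design),
                 dimnames = list(feats$feature_id, design$sample_id))
  pheno_matrix(vals, feats, if (kind == "exon") "inclusion" else "excision")
}

test_that("the tissue model reduces exactly to OLS ANOVA with unique animals", {
  set.seed(31)
  design <- make_design(12, c("a", "b", "c"), repeat_animals = FALSE)
  ph <- make_pheno(15, design)
  res <- quiet(tissue_mixed_model(ph, design))
  f_ols <- sapply(seq_len(15), function(i) {
    d <- design
    d$y <- ph$values[i, ]
    a <- anova(lm(y ~ experiment + tissue, data = d))
    c(a["tissue", "F value"], a["tissue", "Pr(>F)"])
  })
  expect_equal(res$statistic, f_ols[1, ], tolerance = 1e-6)
  expect_equal(res$p, f_ols[2, ], tolerance = 1e-6)
})

test_that("a planted tissue shift is detected with overwhelming significance", {
  set.seed(32)
  design <- make_design(30, c("a", "b"))
  ph <- make_pheno(5, design)
  ph$values[1, design$tissue == "b"] <- ph$values[1, design$tissue == "b"] + 2
  res <- quiet(tissue_mixed_model(ph, design))
  expect_lt(res$p[res$feature_id == "f001"], 1e-6)
  expect_gt(min(res$p[res$feature_id != "f001"]), 1e-6)
})

test_that("repeated-animal designs use Satterthwaite denominator df", {
  set.seed(33)
  design <- make_design(10, c("a", "b", "c"))
  ph <- make_pheno(4, design)
  # add an animal effect so the random-effect variance is positive
  an_eff <- rnorm(10, sd = 2)[as.integer(factor(design$animal))]
  ph$values <- sweep(ph$values, 2, an_eff, "+")
  res <- quiet(tissue_mixed_model(ph, design))
  expect_true(all(res$df2 > 0))
  expect_true(all(res$df1 == 2))
  # with a strong animal variance the denominator df falls below the OLS df
  ols_df <- nrow(design) - 1 - 1 - 2  # intercept + experiment + tissue
  expect_true(any(res$df2 < ols_df))
})

test_that("the breed model equals the two-sample equal-variance t-test", {
  set.seed(34)
  design <- make_design(20, "milk")
  breed <- rep(c("H", "J"), 10)
  ph <- make_pheno(8, design)
  res <- breed_model(ph, breed)
  for (i in c(1, 5, 8)) {
    tt <- t.test(ph$values[i, ] ~ breed, var.equal = TRUE)
    expect_equal(res$p[i], tt$p.value, tolerance = 1e-12)
    expect_equal(abs(res$statistic[i]), abs(tt$statistic),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  # equal group means -> t = 0, p = 1
  ph$values[2, ] <- rep(c(1, 2, 2, 1), 5)  # both breeds average 1.5
  res2 <- breed_model(ph, breed)
  expect_equal(res2$statistic[2], 0, tolerance = 1e-12)
  expect_equal(res2$p[2], 1, tolerance = 1e-12)
  expect_error(breed_model(ph, rep("H", 20)), "2 breed")
})

test_that("q-values are monotone in p and bounded by BH", {
  set.seed(35)
  p <- c(runif(300), runif(100, 0, 1e-3))
  q <- qvalues(p)
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-12))
  expect_true(all(q <= p.adjust(p, "BH") + 1e-12))
  expect_identical(qvalues(p, method = "bh"), p.adjust(p, "BH"))
})

test_that("gene calls require the exon-intron conjunction", {
  feats <- toy_features(n_exons = 3)
  exon_res <- tibble::tibble(
    feature_id = c("g1_e1", "g1_e2"), kind = "exon", term = "tissue",
    statistic = 5, df1 = 1, df2 = 10, p = c(1e-4, 0.5),
    gene_id = "g1", q = c(0.01, 0.6))
  intron_res <- tibble::tibble(
    feature_id = c("g1_intron1", "g1_intron2"), kind = "intron",
    term = "tissue", statistic = 4, df1 = 1, df2 = 10, p = c(0.3, 1e-3),
    gene_id = "g1", q = c(0.4, 0.02))
  # e1 significant and its right-adjacent intron1 is not; intron2 is
  # significant but not adjacent to e1 -> no call
  calls <- call_differential_splicing(exon_res, intron_res, feats)
  expect_equal(nrow(calls), 0)
  expect_equal(attr(calls, "combined_threshold"), 0.01)

  # make the adjacent intron significant -> gene called
  intron_res$q[1] <- 0.05
  calls2 <- call_differential_splicing(exon_res, intron_res, feats)
  expect_equal(unique(calls2$gene_id), "g1")
  expect_true(all(calls2$exon_q < 0.1 & calls2$intron_q < 0.1))
  ranked <- attr(calls2, "ranked_genes")
  expect_equal(ranked$min_combined_q, min(calls2$combined_q))

  # conjunction count cannot exceed either marginal count
  expect_lte(length(unique(calls2$gene_id)),
             min(length(unique(exon_res$gene_id[exon_res$q < 0.1])),
                 length(unique(intron_res$gene_id[intron_res$q < 0.1]))))
})

test_that("adjacency prefers shared boundaries and falls back to nearest", {
  feats <- toy_features(n_exons = 3)
  adj <- adjacent_introns(feats)
  # middle exon touches both introns
  e2 <- adj[adj$exon_id == "g1_e2", ]
  expect_setequal(e2$intron_id, c("g1_intron1", "g1_intron2"))
  expect_true(all(e2$rule == "boundary"))

  # an exon isolated from introns falls back to the nearest within 10 kb
  extra <- tibble::tibble(feature_id = "g1_far", kind = "exon", chrom = "1",
                          start = 4000, end = 4100, strand = "+",
                          gene_id = "g1", tss = NA_integer_)
  adj2 <- adjacent_introns(dplyr::bind_rows(feats, extra))
  far <- adj2[adj2$exon_id == "g1_far", ]
  expect_equal(far$rule, "nearest")
  expect_equal(nrow(far), 1)
})
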