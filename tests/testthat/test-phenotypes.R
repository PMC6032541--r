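test_that("expression filter applies the strict breadth rule and is idempotent", {
  m <- matrix(10, 3, 10, dimnames = list(c("a", "b", "c"), NULL))
  m["a", 6:10] <- 0   # nonzero in 5/10 -> 0.5 > 0.4, retained
  m["b", 5:10] <- 0   # nonzero in 4/10 -> 0.4 not > 0.4, removed
  colnames(m) <- sprintf("s%d", 1:10)
  cm <- toy_counts(m)
  kept <- quiet(filter_expressed(cm))
  expect_setequal(rownames(kept$counts), c("a", "c"))

  set.seed(21)
  big <- matrix(rnbinom(50 * 12, mu = 2, size = 0.5), 50, 12,
                dimnames = list(sprintf("f%02d", 1:50), sprintf("s%d", 1:12)))
  big[, 1] <- pmax(big[, 1], 1)  # avoid zero library
  cm2 <- toy_counts(big)
  once <- quiet(filter_expressed(cm2))
  twice <- quiet(filter_expressed(once))
  expect_identical(once$counts, twice$counts)

  zero_lib <- toy_counts(matrix(0, 2, 2, dimnames = list(c("x", "y"),
                                                         c("s1", "s2"))))
  expect_error(quiet(filter_expressed(zero_lib)), "library")
})

test_that("inclusion ratios divide exon by gene abundance on the CPM scale", {
  feats <- toy_features(n_exons = 2)
  samples <- c("s1", "s2")
  gene_cts <- count_matrix(matrix(c(10, 10, 10, 0), 2, 2,
                                  dimnames = list(c("g1", "g2"), samples)),
                           dplyr::bind_rows(
                             toy_features(2)[toy_features(2)$kind == "gene", ],
                             tibble::tibble(feature_id = "g2", kind = "gene",
                                            chrom = "1", start = 9000,
                                            end = 9500, strand = "+",
                                            gene_id = "g2", tss = 9000)))
  exon_cts <- count_matrix(matrix(c(5, 15, 5, 15), 2, 2,
                                  dimnames = list(c("g1_e1", "g1_e2"),
                                                  samples)),
                           feats)
  # libraries are equal (20 per sample each side), so CPM ratio = raw ratio
  expect_error(inclusion_ratio(exon_cts, gene_cts), NA)
  r <- inclusion_ratio(exon_cts, gene_cts)
  expect_equal(unname(r$values["g1_e1", "s1"]), 0.5)
  expect_equal(unname(r$values["g1_e2", "s1"]), 1.5)

  # zero gene count yields missing, never 0 or Inf
  gene0 <- count_matrix(matrix(c(0, 30, 20, 20), 2, 2,
                               dimnames = list(c("g1", "g2"), samples)),
                        dplyr::bind_rows(
                          feats[feats$kind == "gene", ],
                          tibble::tibble(feature_id = "g2", kind = "gene",
                                         chrom = "1", start = 9000,
                                         end = 9500, strand = "+",
                                         gene_id = "g2", tss = 9000)))
  r0 <- inclusion_ratio(exon_cts, gene0)
  expect_true(all(is.na(r0$values[, "s1"])))
  expect_true(all(is.finite(r0$values[, "s2"])))

  # exon whose parent gene is not counted is an error
  orphan <- count_matrix(matrix(5, 1, 2, dimnames = list("g1_e1", samples)),
                         feats)
  gene_other <- count_matrix(matrix(5, 1, 2, dimnames = list("g2", samples)),
                             tibble::tibble(feature_id = "g2", kind = "gene",
                                            chrom = "1", start = 1, end = 10,
                                            strand = "+", gene_id = "g2",
                                            tss = 1))
  expect_error(inclusion_ratio(orphan, gene_other), "no gene counts")
})

test_that("excision ratios normalise within cluster and conserve mass", {
  feats <- toy_features(n_exons = 3)
  introns <- feats[feats$kind == "intron", ]
  cm <- count_matrix(matrix(c(6, 4, 0, 0), 2, 2,
                            dimnames = list(introns$feature_id,
                                            c("s1", "s2"))),
                     feats)
  r <- excision_ratio(cm)
  expect_equal(unname(r$values[, "s1"]), c(0.6, 0.4))
  expect_true(all(is.na(r$values[, "s2"])))  # zero cluster total -> missing

  # single-intron cluster is identically 1 where counted
  feats1 <- toy_features(n_exons = 2, gene_id = "gx")
  cm1 <- count_matrix(matrix(c(7, 0), 1, 2,
                             dimnames = list(
                               feats1$feature_id[feats1$kind == "intron"],
                               c("s1", "s2"))),
                      feats1)
  r1 <- excision_ratio(cm1)
  expect_equal(unname(r1$values[1, "s1"]), 1)

  # conservation on a random multi-cluster matrix
  set.seed(22)
  f2 <- dplyr::bind_rows(toy_features(4, gene_id = "ga"),
                         toy_features(4, gene_id = "gb", start = 50000))
  intr <- f2[f2$kind == "intron", ]
  m <- matrix(rpois(nrow(intr) * 8, 10) + 1, nrow(intr), 8,
              dimnames = list(intr$feature_id, sprintf("s%d", 1:8)))
  rr <- excision_ratio(count_matrix(m, f2))
  sums <- rowsum(rr$values, intr$gene_id)
  expect_true(all(abs(sums - 1) < 1e-12))
})

test_that("inverse-normal ranks hit the closed-form quantiles", {
  x <- c(0.1, 0.2, 0.4)
  expect_equal(sqtlkit:::inverse_normal(x),
               qnorm(c(1, 3, 5) / 6), tolerance = 1e-12)
  # rank preservation with missing entries interspersed
  y <- c(5, NA, 1, 3, NA, 2)
  out <- sqtlkit:::inverse_normal(y)
  expect_equal(order(out[!is.na(out)]), order(y[!is.na(y)]))
})

test_that("the normalisation chain standardises samples and drops degenerate features", {
  set.seed(23)
  feats <- toy_features(n_exons = 6)
  ex <- feats[feats$kind == "exon", ]
  vals <- matrix(runif(6 * 12, 0.05, 0.95), 6, 12,
                 dimnames = list(ex$feature_id, sprintf("s%d", 1:12)))
  vals[2, ] <- 0.5  # constant feature must be dropped
  r <- ratio_matrix(vals, feats, "inclusion")
  expect_warning(ph <- suppressMessages(normalize_ratios(r)), "dropping")
  expect_false("g1_e2" %in% rownames(ph$values))
  expect_equal(colMeans(ph$values, na.rm = TRUE), rep(0, 12),
               ignore_attr = TRUE, tolerance = 1e-10)
  expect_equal(apply(ph$values, 2, sd, na.rm = TRUE), rep(1, 12),
               ignore_attr = TRUE, tolerance = 1e-10)

  # sub-threshold ratios are removed per entry
  vals2 <- vals
  vals2[3, 1] <- 5e-4
  r2 <- ratio_matrix(vals2, feats, "inclusion")
  ph2 <- quiet(normalize_ratios(r2))
  expect_true(is.na(ph2$values["g1_e3", "s1"]))
})

test_that("expression normalisation matches the pseudocount formula and is depth-invariant", {
  # count 0 in a library of 1e6 -> log2(0.5e6 / (1e6 + 1))
  cnt <- matrix(c(0, 1e6 - 0), 2, 1, dimnames = list(c("a", "b"), "s1"))
  lib <- colSums(cnt)
  expect_equal(log2((0 + 0.5) / (lib + 1) * 1e6), -1, tolerance = 2e-6,
               ignore_attr = TRUE)

  set.seed(24)
  m <- matrix(rnbinom(40 * 10, mu = 200, size = 5) + 5, 40, 10,
              dimnames = list(sprintf("f%02d", 1:40), sprintf("s%d", 1:10)))
  cm <- toy_counts(m)
  ph <- quiet(normalize_expression(cm))
  m2 <- m
  m2[, 3] <- m2[, 3] * 2  # doubled sequencing depth for one sample
  ph2 <- quiet(normalize_expression(toy_counts(m2)))
  expect_equal(ph$values[, 3], ph2$values[, 3], tolerance = 1e-12)

  # rank order within each feature is preserved through the chain's
  # rank-based map (checked on the pre-z-score stage)
  lcpm <- log2(sweep(m + 0.5, 2, colSums(m) + 1, "/") * 1e6)
  post <- t(apply(lcpm, 1, sqtlkit:::inverse_normal))
  for (i in c(1, 20, 40)) {
    expect_equal(order(post[i, ]), order(lcpm[i, ]))
  }
})
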