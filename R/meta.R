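#' Inverse-variance weighted two-cohort effect
#'
#' Combines per-SNP effects estimated separately in two cohorts whose
#' phenotypic error differs (e.g. bulls and cows):
#' `B_w = (B1/se1^2 + B2/se2^2) / (1/se1^2 + 1/se2^2)`,
#' `se_w = 1/sqrt(1/se1^2 + 1/se2^2)`, `t_w = B_w/se_w`. With equal SEs
#' this reduces to `t_w = (t1 + t2)/sqrt(2)`.
#'
#' @param B1,se1 effect and standard error in cohort 1 (vectorised).
#' @param B2,se2 effect and standard error in cohort 2.
#' @return Tibble: `B_w`, `se_w`, `t_w`.
#' @export
weighted_t <- function(B1, se1, B2, se2) {
  if (any(se1 <= 0) || any(se2 <= 0)) abort("standard errors must be positive")
  w1 <- 1 / se1^2
  w2 <- 1 / se2^2
  B_w <- (B1 * w1 + B2 * w2) / (w1 + w2)
  se_w <- 1 / sqrt(w1 + w2)
  tibble(B_w = B_w, se_w = se_w, t_w = B_w / se_w)
}

#' Multi-trait chi-square statistic
#'
#' For each SNP with signed t values across `k` traits, `chi2 = t' V^{-1} t`
#' referred to chi-square with `k` df, where `V` is the correlation matrix
#' of the t values over SNPs (see [estimate_t_correlation()]).
#'
#' @param t numeric vector (one SNP) or matrix (SNPs x traits) of signed t
#'   values.
#' @param V trait-correlation matrix of the t values; symmetric positive
#'   definite.
#' @return Tibble with one row per SNP: `chi2`, `df`, `p`.
#' @export
multitrait_chisq <- function(t, V) {
  if (is.vector(t)) t <- matrix(t, nrow = 1)
  k <- ncol(t)
  stopifnot(nrow(V) == k, ncol(V) == k)
  if (max(abs(V - t(V))) > 1e-8) abort("V must be symmetric")
  Vi <- tryCatch(solve(V), error = function(e) {
    abort("V is singular; add a ridge or prune correlated traits")
  })
  chi2 <- rowSums((t %*% Vi) * t)
  tibble(chi2 = chi2, df = k, p = pchisq(chi2, k, lower.tail = FALSE))
}

#' Estimate the trait correlation of t values under the null
#'
#' Empirical correlation of signed t values across traits, restricted to
#' SNPs with `|t| < t_max` in every trait so that true signals do not
#' inflate the correlation.
#'
#' @param tmat matrix, SNPs x traits, of signed t values.
#' @param t_max null-restriction threshold (default 2).
#' @return Correlation matrix.
#' @export
estimate_t_correlation <- function(tmat, t_max = 2) {
  nullish <- rowSums(abs(tmat) >= t_max) == 0
  if (sum(nullish) < 10) abort("too few null SNPs to estimate V")
  cor(tmat[nullish, , drop = FALSE])
}

#' Multi-transcriptome meta-analysis statistic
#'
#' Combines one (SNP, feature) pair's signed t values from N tissues as
#' `chi2 = (sum_n t_n / sqrt(N))^2`, referred to chi-square with 1 df. The
#' null hypothesis is that the SNP has no association in any tissue;
#' cross-tissue independence of t under the null is assumed. Pairs missing
#' a t value in any tissue are excluded and counted.
#'
#' @param t_by_tissue long tibble `snp_id`, `feature_id`, `tissue`, `t`, or
#'   a numeric matrix (pairs x tissues).
#' @param effective_n apply an effective-N correction dividing the combined
#'   statistic by `mean(R)` where `R` is the cross-tissue t correlation
#'   (default FALSE, matching the independence assumption).
#' @return Tibble: `snp_id`, `feature_id` (when supplied), `N`, `chi2`,
#'   `p`.
#' @export
meta_combine <- function(t_by_tissue, effective_n = FALSE) {
  if (is.matrix(t_by_tissue)) {
    tm <- t_by_tissue
    keys <- tibble(snp_id = rownames(tm) %||% as.character(seq_len(nrow(tm))),
                   feature_id = NA_character_)
  } else {
    wide <- tidyr::pivot_wider(as_tibble(t_by_tissue),
                               id_cols = c("snp_id", "feature_id"),
                               names_from = "tissue", values_from = "t")
    tm <- as.matrix(wide[, setdiff(names(wide), c("snp_id", "feature_id")),
                         drop = FALSE])
    keys <- wide[c("snp_id", "feature_id")]
  }
  complete <- rowSums(is.na(tm)) == 0
  if (any(!complete)) {
    inform(sprintf("meta_combine: %d pair(s) excluded with missing tissue t",
                   sum(!complete)))
  }
  tm <- tm[complete, , drop = FALSE]
  keys <- keys[complete, , drop = FALSE]
  N <- ncol(tm)
  chi2 <- (rowSums(tm) / sqrt(N))^2
  if (effective_n) {
    R <- cor(tm)
    chi2 <- chi2 / mean(R)
  }
  dplyr::bind_cols(keys, tibble(N = N, chi2 = chi2,
                                p = pchisq(chi2, 1, lower.tail = FALSE)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fisher's exact overlap test
#'
#' One-sided (enrichment) hypergeometric test of the overlap between two id
#' sets against a background universe, with the sample odds ratio from the
#' 2x2 table.
#'
#' @param setA,setB character vectors of ids; must be subsets of
#'   `background`.
#' @param background character vector, the id universe.
#' @return One-row tibble: `n_both`, `n_a_only`, `n_b_only`, `n_neither`,
#'   `background_size`, `odds_ratio`, `p`.
#' @export
fisher_overlap <- function(setA, setB, background) {
  setA <- unique(setA); setB <- unique(setB); background <- unique(background)
  if (!all(setA %in% background) || !all(setB %in% background)) {
    abort("setA and setB must be subsets of the background")
  }
  both <- length(intersect(setA, setB))
  a_only <- length(setA) - both
  b_only <- length(setB) - both
  neither <- length(background) - both - a_only - b_only
  tab <- matrix(c(both, a_only, b_only, neither), 2)
  p <- fisher.test(tab, alternative = "greater")$p.value
  or <- (both * neither) / max(a_only * b_only, .Machine$double.eps)
  tibble(n_both = both, n_a_only = a_only, n_b_only = b_only,
         n_neither = neither, background_size = length(background),
         odds_ratio = or, p = p)
}

#' Cross-tissue validation by meta-analysis
#'
#' The validation design: (SNP, feature) pairs with single-tissue
#' `p < p_single` in each of the combined tissues are meta-analysed with
#' [meta_combine()]; meta-significance (`p < p_meta`) is cross-tabulated
#' against significance in a held-out tissue (`p < p_single`) and the
#' overlap tested with Fisher's exact test.
#'
#' @param tissues_combined named list of [scan_cis()] result tibbles (the
#'   tissues to combine).
#' @param holdout a [scan_cis()] result tibble for the held-out tissue.
#' @param p_single per-tissue candidate/holdout threshold (default 0.05).
#' @param p_meta meta-analysis significance threshold (default 1e-5).
#' @return Object of class `sqk_validation`: list with `table` (2x2
#'   matrix, meta x holdout), `fisher_p`, `odds_ratio`, `meta` (the
#'   per-pair meta results joined to holdout p), and the thresholds.
#' @export
run_validation <- function(tissues_combined, holdout, p_single = 0.05,
                           p_meta = 1e-5) {
  if (is.null(names(tissues_combined))) {
    names(tissues_combined) <- paste0("tissue", seq_along(tissues_combined))
  }
  long <- purrr::imap_dfr(tissues_combined, function(tbl, nm) {
    tibble(snp_id = tbl$snp_id, feature_id = tbl$feature_id, tissue = nm,
           t = tbl$statistic, p = tbl$p)
  })
  wide_p <- tidyr::pivot_wider(long, id_cols = c("snp_id", "feature_id"),
                               names_from = "tissue", values_from = "p")
  pm <- as.matrix(wide_p[, -(1:2)])
  candidates <- wide_p[rowSums(is.na(pm)) == 0 &
                         rowSums(pm < p_single, na.rm = TRUE) == ncol(pm),
                       c("snp_id", "feature_id")]
  if (!nrow(candidates)) abort("no candidate pairs pass the per-tissue filter")
  meta <- meta_combine(semi_join(long, candidates,
                                 by = c("snp_id", "feature_id")))
  meta <- meta %>%
    left_join(holdout %>% select("snp_id", "feature_id",
                                 holdout_p = "p"),
              by = c("snp_id", "feature_id")) %>%
    filter(!is.na(.data$holdout_p)) %>%
    mutate(meta_sig = .data$p < p_meta,
           holdout_sig = .data$holdout_p < p_single)
  tab <- matrix(c(sum(meta$meta_sig & meta$holdout_sig),
                  sum(!meta$meta_sig & meta$holdout_sig),
                  sum(meta$meta_sig & !meta$holdout_sig),
                  sum(!meta$meta_sig & !meta$holdout_sig)),
                2, dimnames = list(holdout = c("+", "-"),
                                   meta = c("+", "-")))
  fp <- fisher.test(tab, alternative = "greater")$p.value
  or <- (tab[1, 1] * tab[2, 2]) /
    max(tab[1, 2] * tab[2, 1], .Machine$double.eps)
  structure(list(table = tab, fisher_p = fp, odds_ratio = or, meta = meta,
                 p_single = p_single, p_meta = p_meta),
            class = "sqk_validation")
}

#' @export
print.sqk_validation <- function(x, ...) {
  cat(sprintf("<sqk_validation> meta p < %g vs holdout p < %g; Fisher p = %.3g, OR = %.2f\n",
              x$p_meta, x$p_single, x$fisher_p, x$odds_ratio))
  print(x$table)
  invisible(x)
}

#' Greedy lead-SNP locus clumping
#'
#' Utility: repeatedly takes the most significant remaining SNP and removes
#' all SNPs within `dist` bp of it on the same chromosome.
#'
#' @param assoc tibble with `snp_id`, `chrom`, `pos`, `p`.
#' @param dist clumping half-width in bp (default 1e6).
#' @return Tibble of lead SNPs (subset of `assoc` rows).
#' @export
clump_loci <- function(assoc, dist = 1e6) {
  assoc <- assoc %>% arrange(.data$p)
  leads <- assoc[0, ]
  while (nrow(assoc)) {
    lead <- assoc[1, ]
    leads <- bind_rows(leads, lead)
    assoc <- assoc %>%
      filter(!(.data$chrom == lead$chrom & abs(.data$pos - lead$pos) <= dist))
  }
  leads
}
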