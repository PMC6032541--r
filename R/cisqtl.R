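#' Cis association scan
#'
#' For every feature and every SNP within `window` bp of the feature's
#' boundaries on the same chromosome, ordinary least squares of the
#' normalised phenotype on the alt-allele dosage plus optional covariates.
#' Missing phenotype entries are excluded pairwise; a (SNP, feature) pair
#' with fewer than `ncov + 3` complete observations, or with no dosage
#' variance among them, is skipped. q-values are computed within each
#' feature kind of the scan (one scan = one tissue x one phenotype class).
#'
#' @param pheno a [pheno_matrix()].
#' @param genotypes a [geno_matrix()] with samples covering
#'   `pheno$samples`.
#' @param window cis half-width in bp, anchored at the feature boundaries
#'   (default 1e6).
#' @param covariates optional tibble `sample_id` plus covariate columns
#'   (e.g. breed), fitted alongside dosage.
#' @param fdr_method `"storey"` or `"bh"`.
#' @return Tibble: `feature_id`, `kind`, `gene_id`, `snp_id`, `chrom`,
#'   `pos`, `n`, `beta`, `se`, `statistic` (t = beta/se), `p`, `q`; sorted
#'   by (chrom, pos) within feature.
#' @export
scan_cis <- function(pheno, genotypes, window = 1e6, covariates = NULL,
                     fdr_method = "storey") {
  samp <- pheno$samples
  gidx <- match(samp, genotypes$samples)
  if (anyNA(gidx)) abort("phenotype samples missing from genotypes")
  D <- genotypes$dosage[gidx, , drop = FALSE]
  snps <- genotypes$snps
  C <- NULL
  if (!is.null(covariates)) {
    covariates <- as_tibble(covariates)
    ci <- match(samp, covariates$sample_id)
    if (anyNA(ci)) abort("covariate table missing samples")
    C <- model.matrix(~ ., data = covariates[ci, setdiff(names(covariates),
                                                         "sample_id"),
                                             drop = FALSE])
  }
  ncov <- if (is.null(C)) 0L else ncol(C) - 1L
  feats <- pheno$features

  res <- purrr::map_dfr(seq_len(nrow(pheno$values)), function(i) {
    f <- feats[i, ]
    in_win <- snps$chrom == f$chrom &
      snps$pos >= f$start - window & snps$pos <= f$end + window
    if (!any(in_win)) return(NULL)
    y <- pheno$values[i, ]
    ok <- !is.na(y)
    if (sum(ok) < ncov + 3L) return(NULL)
    yv <- y[ok]
    X <- D[ok, in_win, drop = FALSE]
    if (is.null(C)) {
      Q <- matrix(1 / sqrt(length(yv)), length(yv), 1)
    } else {
      Q <- qr.Q(qr(C[ok, , drop = FALSE]))
    }
    p_base <- ncol(Q)
    # Frisch-Waugh: residualise y and each dosage column on the covariates
    yr <- yv - Q %*% crossprod(Q, yv)
    Xr <- X - Q %*% crossprod(Q, X)
    ssx <- colSums(Xr^2)
    keep <- ssx > 1e-12
    if (!any(keep)) return(NULL)
    Xr <- Xr[, keep, drop = FALSE]
    ssx <- ssx[keep]
    xy <- crossprod(Xr, yr)[, 1]
    beta <- xy / ssx
    dfree <- length(yv) - p_base - 1L
    rss <- sum(yr^2) - beta * xy
    rss[rss < 0] <- 0
    se <- sqrt(rss / dfree / ssx)
    tval <- beta / se
    sn <- snps[in_win, , drop = FALSE][keep, , drop = FALSE]
    tibble(feature_id = f$feature_id, kind = f$kind, gene_id = f$gene_id,
           snp_id = sn$snp_id, chrom = sn$chrom, pos = sn$pos,
           n = length(yv), beta = unname(beta), se = unname(se),
           statistic = unname(tval),
           p = unname(2 * pt(-abs(tval), dfree)))
  })
  if (!nrow(res)) return(res)
  res %>%
    group_by(.data$kind) %>%
    mutate(q = qvalues(.data$p, method = fdr_method)) %>%
    ungroup() %>%
    arrange(.data$feature_id, .data$chrom, .data$pos)
}

#' Call splicing QTLs by the SNP-level conjunction rule
#'
#' A (SNP, exon) pair is an sQTL when the SNP is significantly associated
#' (q < `fdr`) with the exon's inclusion ratio AND the same SNP is
#' significantly associated (q < `fdr`) with the excision of at least one
#' intron adjacent to that exon. The combined threshold is reported as
#' `fdr * fdr`.
#'
#' @param exon_assoc [scan_cis()] output on inclusion phenotypes.
#' @param intron_assoc [scan_cis()] output on excision phenotypes from the
#'   same tissue.
#' @param features feature tibble (for adjacency).
#' @param fdr per-scan FDR threshold, default 0.1.
#' @return Tibble: `snp_id`, `exon_id`, `gene_id`, `exon_q`,
#'   `best_intron_q`, `n_introns`, `intron_ids` (comma-joined); attribute
#'   `combined_threshold` = `fdr^2`.
#' @export
call_sqtls <- function(exon_assoc, intron_assoc, features, fdr = 0.1) {
  adj <- adjacent_introns(features)
  sig_ex <- exon_assoc %>% filter(.data$q < fdr)
  sig_in <- intron_assoc %>% filter(.data$q < fdr)
  calls <- sig_ex %>%
    select(exon_id = "feature_id", "gene_id", "snp_id", exon_q = "q") %>%
    dplyr::inner_join(adj %>% select("exon_id", "intron_id"), by = "exon_id",
                      relationship = "many-to-many") %>%
    dplyr::inner_join(sig_in %>% select(intron_id = "feature_id", "snp_id",
                                        intron_q = "q"),
                      by = c("intron_id", "snp_id")) %>%
    group_by(.data$snp_id, .data$exon_id, .data$gene_id, .data$exon_q) %>%
    summarise(best_intron_q = min(.data$intron_q),
              n_introns = dplyr::n(),
              intron_ids = paste(.data$intron_id, collapse = ","),
              .groups = "drop") %>%
    arrange(.data$exon_q)
  attr(calls, "combined_threshold") <- fdr^2
  calls
}

#' Classify SNPs into sQTL / eeQTL / geQTL memberships
#'
#' sQTL membership follows the conjunction rule of [call_sqtls()] at
#' `fdr_sqtl`; eeQTL and geQTL membership are q < `fdr_expr` in the exon
#' and gene expression scans. Note the printed thresholds differ by design:
#' the sQTL conjunction uses two FDR < 0.1 filters while eeQTL/geQTL use a
#' single FDR < 0.01.
#'
#' @param inclusion_assoc,intron_assoc,exon_assoc,gene_assoc [scan_cis()]
#'   outputs for inclusion, excision, exon expression and gene expression
#'   phenotypes from one tissue.
#' @param features feature tibble.
#' @param fdr_sqtl conjunction FDR (default 0.1).
#' @param fdr_expr expression-QTL FDR (default 0.01).
#' @return Tibble: `snp_id`, logical `sQTL`, `eeQTL`, `geQTL`, covering the
#'   union of SNPs appearing in any scan.
#' @export
classify_qtl_types <- function(inclusion_assoc, intron_assoc, exon_assoc,
                               gene_assoc, features,
                               fdr_sqtl = 0.1, fdr_expr = 0.01) {
  sq <- call_sqtls(inclusion_assoc, intron_assoc, features, fdr = fdr_sqtl)
  ee <- unique(exon_assoc$snp_id[exon_assoc$q < fdr_expr])
  ge <- unique(gene_assoc$snp_id[gene_assoc$q < fdr_expr])
  universe <- unique(c(inclusion_assoc$snp_id, intron_assoc$snp_id,
                       exon_assoc$snp_id, gene_assoc$snp_id))
  tibble(snp_id = universe,
         sQTL = universe %in% sq$snp_id,
         eeQTL = universe %in% ee,
         geQTL = universe %in% ge)
}
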