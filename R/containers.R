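#' Genotype dosage container
#'
#' Bundles a samples-by-SNPs dosage matrix (alt-allele counts 0/1/2) with the
#' per-SNP metadata table. Effect signs throughout the package refer to the
#' alt allele.
#'
#' @param dosage numeric matrix, samples in rows, SNPs in columns; values must
#'   be 0, 1 or 2 with no missing entries.
#' @param snps tibble with columns `snp_id`, `chrom`, `pos`, `ref`, `alt`;
#'   `maf` is recomputed from `dosage`.
#' @return An object of class `geno_matrix` with elements `dosage`, `snps`
#'   and `samples`.
#' @export
geno_matrix <- function(dosage, snps) {
  snps <- as_tibble(snps)
  stopifnot(ncol(dosage) == nrow(snps))
  if (is.null(rownames(dosage))) {
    abort("dosage matrix must have sample ids as rownames")
  }
  if (anyNA(dosage)) {
    abort("missing genotypes are not permitted; impute upstream")
  }
  if (!all(dosage %in% c(0, 1, 2))) {
    abort("dosages must be 0, 1 or 2")
  }
  if (anyDuplicated(snps$snp_id)) {
    abort("duplicate snp_id in genotype input")
  }
  storage.mode(dosage) <- "integer"
  colnames(dosage) <- snps$snp_id
  snps$maf <- fold_maf(colMeans(dosage) / 2)
  ord <- order(snps$chrom, snps$pos)
  structure(
    list(dosage = dosage[, ord, drop = FALSE],
         snps = snps[ord, , drop = FALSE],
         samples = rownames(dosage)),
    class = "geno_matrix"
  )
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("<geno_matrix> %d samples x %d SNPs, %d chromosome(s)\n",
              length(x$samples), nrow(x$snps), length(unique(x$snps$chrom))))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosage)

fold_maf <- function(f) pmin(f, 1 - f)

#' Subset a genotype matrix to a set of SNPs
#'
#' @param genotypes a [geno_matrix()].
#' @param snp_ids character vector of SNP ids to keep (order preserved as in
#'   the genotype matrix).
#' @return A `geno_matrix` restricted to those SNPs.
#' @export
subset_snps <- function(genotypes, snp_ids) {
  keep <- genotypes$snps$snp_id %in% snp_ids
  geno_matrix(genotypes$dosage[, keep, drop = FALSE],
              genotypes$snps[keep, , drop = FALSE])
}

#' Count matrix container
#'
#' Features (genes, exons or intron junctions) by samples, non-negative
#' integer counts, with a feature annotation table.
#'
#' @param counts non-negative integer matrix, features in rows (rownames =
#'   feature ids), samples in columns.
#' @param features tibble as returned by [read_features()]; only rows
#'   matching the count rownames are retained, in count order.
#' @return An object of class `count_matrix` with elements `counts`,
#'   `features`, `samples`.
#' @export
count_matrix <- function(counts, features) {
  features <- as_tibble(features)
  if (is.null(rownames(counts))) abort("counts must have feature_id rownames")
  if (any(counts < 0)) abort("counts must be non-negative")
  idx <- match(rownames(counts), features$feature_id)
  if (anyNA(idx)) {
    abort(sprintf("count rows missing from feature table: %s",
                  paste(head(rownames(counts)[is.na(idx)]), collapse = ", ")))
  }
  structure(
    list(counts = counts, features = features[idx, , drop = FALSE],
         samples = colnames(counts)),
    class = "count_matrix"
  )
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d features (%s) x %d samples\n",
              nrow(x$counts),
              paste(unique(x$features$kind), collapse = "/"),
              length(x$samples)))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Ratio matrix container
#'
#' Exon inclusion or intron excision ratios, features by samples. Entries are
#' missing (NA) where the denominator was zero.
#'
#' @param values numeric matrix of non-negative ratios, NA allowed.
#' @param features feature tibble matching the rownames of `values`.
#' @param kind `"inclusion"` or `"excision"`.
#' @return An object of class `ratio_matrix`.
#' @export
ratio_matrix <- function(values, features, kind = c("inclusion", "excision")) {
  kind <- match.arg(kind)
  features <- as_tibble(features)
  idx <- match(rownames(values), features$feature_id)
  if (anyNA(idx)) abort("ratio rows missing from feature table")
  if (any(values < 0, na.rm = TRUE)) abort("ratios must be non-negative")
  structure(
    list(values = values, features = features[idx, , drop = FALSE],
         samples = colnames(values), kind = kind),
    class = "ratio_matrix"
  )
}

#' @export
print.ratio_matrix <- function(x, ...) {
  cat(sprintf("<ratio_matrix:%s> %d features x %d samples (%.1f%% missing)\n",
              x$kind, nrow(x$values), ncol(x$values),
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' Normalised phenotype container
#'
#' Regression-ready phenotypes after the log2 / rank-inverse-normal /
#' individual z-score chain. The provenance tag records which phenotype class
#' the values represent.
#'
#' @param values numeric matrix, features by samples, NA allowed.
#' @param features feature tibble matching the rownames of `values`.
#' @param kind provenance tag, one of `"inclusion"`, `"excision"`,
#'   `"exon_expr"`, `"gene_expr"`.
#' @return An object of class `pheno_matrix`.
#' @export
pheno_matrix <- function(values,
                         features,
                         kind = c("inclusion", "excision", "exon_expr",
                                  "gene_expr")) {
  kind <- match.arg(kind)
  features <- as_tibble(features)
  idx <- match(rownames(values), features$feature_id)
  if (anyNA(idx)) abort("phenotype rows missing from feature table")
  structure(
    list(values = values, features = features[idx, , drop = FALSE],
         samples = colnames(values), kind = kind),
    class = "pheno_matrix"
  )
}

#' @export
print.pheno_matrix <- function(x, ...) {
  cat(sprintf("<pheno_matrix:%s> %d features x %d samples\n",
              x$kind, nrow(x$values), ncol(x$values)))
  invisible(x)
}
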