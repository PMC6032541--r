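#' Read a genotype dosage matrix
#'
#' Reads biallelic SNP genotypes from either a VCF (GT field) or the plain
#' TSV dialect written by [write_genotypes()]: a header row of
#' `snp_id chrom pos ref alt <sample ids...>` followed by one row per SNP with
#' dosages coded as alt-allele counts 0/1/2. SNPs are folded-MAF filtered and
#' returned sorted by (chrom, pos).
#'
#' Non-biallelic VCF sites are skipped with a warning. Missing genotypes are
#' a hard error: the pipeline expects fully imputed input and silent mean
#' imputation would mask upstream problems.
#'
#' @param path path to a `.vcf` / `.vcf.gz` file or a TSV file.
#' @param maf_min minor-allele-frequency threshold; SNPs with folded MAF
#'   `<= maf_min` are removed. Default 0.01.
#' @param format `"auto"` (by extension), `"vcf"` or `"tsv"`.
#' @return A [geno_matrix()].
#' @export
read_genotypes <- function(path, maf_min = 0.01,
                           format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  }
  g <- if (format == "vcf") read_genotypes_vcf(path) else read_genotypes_tsv(path)
  n0 <- nrow(g$snps)
  keep <- g$snps$maf > maf_min
  g <- geno_matrix(g$dosage[, keep, drop = FALSE],
                   g$snps[keep, , drop = FALSE])
  inform(sprintf("read_genotypes: %d SNPs read, %d removed at MAF <= %g, %d retained",
                 n0, n0 - nrow(g$snps), maf_min, nrow(g$snps)))
  g
}

read_genotypes_tsv <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("snp_id", "chrom", "pos", "ref", "alt")
  if (!all(need %in% names(tab))) {
    abort(sprintf("genotype TSV must start with columns: %s",
                  paste(need, collapse = ", ")))
  }
  samp <- setdiff(names(tab), need)
  dosage <- t(as.matrix(tab[, samp, drop = FALSE]))
  colnames(dosage) <- tab$snp_id
  if (anyNA(dosage)) abort("missing genotype in TSV; imputation is out of scope")
  snps <- tibble(snp_id = as.character(tab$snp_id),
                 chrom = as.character(tab$chrom),
                 pos = as.integer(tab$pos),
                 ref = as.character(tab$ref),
                 alt = as.character(tab$alt))
  geno_matrix(dosage, snps)
}

read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT) | nchar(fix$REF) != 1L | nchar(fix$ALT) != 1L
  if (any(multi)) {
    warn(sprintf("skipping %d non-biallelic-SNP site(s)", sum(multi)))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[!multi, , drop = FALSE]
  fix <- fix[!multi, , drop = FALSE]
  if (anyNA(gt)) abort("missing genotype in VCF; imputation is out of scope")
  # count alt alleles irrespective of phasing separator
  dose <- vapply(seq_len(ncol(gt)), function(j) {
    alleles <- strsplit(gt[, j], "[/|]")
    vapply(alleles, function(a) sum(a == "1"), numeric(1))
  }, numeric(nrow(gt)))
  if (is.null(dim(dose))) dose <- matrix(dose, nrow = nrow(gt))
  dosage <- t(dose)
  rownames(dosage) <- colnames(gt)
  ids <- fix$ID
  if (any(is.na(ids) | ids == ".")) {
    ids <- ifelse(is.na(ids) | ids == ".",
                  paste0(fix$CHROM, "_", fix$POS), ids)
  }
  colnames(dosage) <- ids
  snps <- tibble(snp_id = ids, chrom = fix$CHROM, pos = as.integer(fix$POS),
                 ref = fix$REF, alt = fix$ALT)
  geno_matrix(dosage, snps)
}

#' Write genotypes to the TSV dialect
#'
#' @param genotypes a [geno_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(genotypes, path) {
  tab <- data.frame(snp_id = genotypes$snps$snp_id,
                    chrom = genotypes$snps$chrom,
                    pos = genotypes$snps$pos,
                    ref = genotypes$snps$ref,
                    alt = genotypes$snps$alt,
                    t(genotypes$dosage),
                    check.names = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# sqtlkit genotype dosage matrix (alt-allele counts)", con)
  write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write genotypes as a minimal VCF
#'
#' Emits a VCFv4.2 file with GT-only genotype fields; dosages 0/1/2 are
#' written as 0/0, 0/1 and 1/1.
#'
#' @param genotypes a [geno_matrix()].
#' @param path output path (plain text).
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(genotypes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=sqtlkit",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", genotypes$samples), collapse = "\t")),
             con)
  gt_code <- c("0/0", "0/1", "1/1")
  s <- genotypes$snps
  for (j in seq_len(nrow(s))) {
    gts <- gt_code[genotypes$dosage[, j] + 1L]
    writeLines(paste(c(s$chrom[j], s$pos[j], s$snp_id[j], s$ref[j], s$alt[j],
                       ".", "PASS", ".", "GT", gts), collapse = "\t"), con)
  }
  invisible(path)
}
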