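# shared fixture builders; everything is generated in code at test time

quiet <- function(expr) suppressMessages(suppressWarnings(expr))

# minimal feature table: one gene, `n_exons` exons with introns between them
toy_features <- function(n_exons = 3, gene_id = "g1", start = 1000,
                         exon_len = 200, intron_len = 300, strand = "+") {
  ex_start <- start + (seq_len(n_exons) - 1) * (exon_len + intron_len)
  feats <- dplyr::bind_rows(
    tibble::tibble(feature_id = gene_id, kind = "gene", chrom = "1",
                   start = start,
                   end = ex_start[n_exons] + exon_len - 1,
                   strand = strand, gene_id = gene_id),
    tibble::tibble(feature_id = sprintf("%s_e%d", gene_id, seq_len(n_exons)),
                   kind = "exon", chrom = "1",
                   start = ex_start, end = ex_start + exon_len - 1,
                   strand = strand, gene_id = gene_id))
  sqtlkit:::build_feature_table(feats)
}

# geno_matrix from a raw dosage matrix (samples x snps), positions supplied
toy_genotypes <- function(dosage, pos = NULL, chrom = "1") {
  n_snp <- ncol(dosage)
  if (is.null(rownames(dosage))) {
    rownames(dosage) <- sprintf("s%03d", seq_len(nrow(dosage)))
  }
  if (is.null(pos)) pos <- seq(1000, by = 500, length.out = n_snp)
  geno_matrix(dosage,
              tibble::tibble(snp_id = sprintf("snp%03d", seq_len(n_snp)),
                             chrom = chrom, pos = as.integer(pos),
                             ref = "A", alt = "B"))
}

random_hwe_dosage <- function(n, m, maf_range = c(0.1, 0.5)) {
  p <- runif(m, maf_range[1], maf_range[2])
  matrix(rbinom(n * m, 2, rep(p, each = n)), n, m,
         dimnames = list(sprintf("s%03d", seq_len(n)), NULL))
}

# count_matrix over arbitrary feature ids (gene kind) for filter tests
toy_counts <- function(counts, kind = "gene") {
  ids <- rownames(counts)
  parent <- if (kind == "gene") ids else rep("g1", length(ids))
  feats <- tibble::tibble(feature_id = ids, kind = kind, chrom = "1",
                          start = 1, end = 10, strand = "+",
                          gene_id = parent, tss = NA_integer_)
  count_matrix(counts, feats)
}
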