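#' Read a count matrix from TSV
#'
#' Expects a header row `feature_id <sample ids...>` and one row of
#' non-negative integer counts per feature. Lines starting with `#` are
#' metadata and skipped.
#'
#' @param path TSV path.
#' @param features feature tibble (see [read_features()]) supplying the
#'   annotation for the counted features.
#' @return A [count_matrix()].
#' @export
read_counts <- function(path, features) {
  tab <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  storage.mode(m) <- "numeric"
  count_matrix(m, features)
}

#' Write a count matrix to TSV
#'
#' @param counts a [count_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sqtlkit count matrix (%s features)",
                     paste(unique(counts$features$kind), collapse = "/")), con)
  tab <- data.frame(feature_id = rownames(counts$counts), counts$counts,
                    check.names = FALSE)
  write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a phenotype matrix to TSV
#'
#' The provenance tag is recorded in the `#` header line and restored by
#' [read_phenotypes()].
#'
#' @param pheno a [pheno_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(pheno, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sqtlkit phenotype matrix kind=%s", pheno$kind), con)
  tab <- data.frame(feature_id = rownames(pheno$values), pheno$values,
                    check.names = FALSE)
  write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype matrix written by [write_phenotypes()]
#'
#' @param path TSV path.
#' @param features feature tibble.
#' @return A [pheno_matrix()].
#' @export
read_phenotypes <- function(path, features) {
  first <- readLines(path, n = 1)
  kind <- sub(".*kind=", "", first)
  if (!kind %in% c("inclusion", "excision", "exon_expr", "gene_expr")) {
    abort("phenotype TSV lacks a 'kind=' provenance header")
  }
  tab <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  storage.mode(m) <- "numeric"
  pheno_matrix(m, features, kind)
}
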