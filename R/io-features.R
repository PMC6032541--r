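#' Read a feature annotation table
#'
#' Loads genes, exons and intron junctions into the package's feature table.
#' Three dialects are supported:
#'
#' * `"tsv"`: columns `feature_id, kind, chrom, start, end, strand, gene_id`
#'   (1-based inclusive coordinates; `gene_id` empty or equal to `feature_id`
#'   for genes);
#' * `"gff3"`: `gene` / `exon` / `intron` rows with `ID=` and `Parent=`
#'   attributes (1-based inclusive, as GFF3 specifies);
#' * `"bed"`: 6-column BED plus a companion parent map TSV
#'   (`feature_id, kind, gene_id`) given as `parent_path`. BED's 0-based
#'   half-open starts are converted to 1-based inclusive on read.
#'
#' Internally all coordinates are 1-based inclusive. When a gene has exon
#' rows but no intron rows, introns are derived as the gaps between
#' consecutive exons. Gene TSS is the start for + strand genes and the end
#' for − strand genes.
#'
#' @param path annotation file path.
#' @param format `"auto"` (by extension), `"tsv"`, `"gff3"` or `"bed"`.
#' @param parent_path parent-map TSV, required for BED input.
#' @param derive_introns derive missing introns from exon gaps (default TRUE).
#' @return A tibble with columns `feature_id, kind, chrom, start, end,
#'   strand, gene_id, tss` (tss is NA for non-genes).
#' @export
read_features <- function(path, format = c("auto", "tsv", "gff3", "bed"),
                          parent_path = NULL, derive_introns = TRUE) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gff3?$", path)) "gff3"
      else if (grepl("\\.bed$", path)) "bed" else "tsv"
  }
  feats <- switch(format,
    tsv = read_features_tsv(path),
    gff3 = read_features_gff3(path),
    bed = read_features_bed(path, parent_path))
  build_feature_table(feats, derive_introns = derive_introns)
}

read_features_tsv <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
  need <- c("feature_id", "kind", "chrom", "start", "end", "strand", "gene_id")
  if (!all(need %in% names(tab))) {
    abort(sprintf("feature TSV needs columns: %s", paste(need, collapse = ", ")))
  }
  as_tibble(tab[need])
}

read_features_gff3 <- function(path) {
  g <- rtracklayer::import(path, format = "gff3")
  parent <- vapply(as.list(g$Parent), function(p) {
    if (length(p)) p[[1]] else NA_character_
  }, character(1))
  tibble(feature_id = as.character(g$ID),
         kind = as.character(g$type),
         chrom = as.character(GenomicRanges::seqnames(g)),
         start = GenomicRanges::start(g),
         end = GenomicRanges::end(g),
         strand = as.character(GenomicRanges::strand(g)),
         gene_id = parent)
}

read_features_bed <- function(path, parent_path) {
  if (is.null(parent_path)) abort("BED input requires parent_path")
  bed <- read.table(path, sep = "\t", stringsAsFactors = FALSE,
                    col.names = c("chrom", "start", "end", "name", "score",
                                  "strand"))
  parents <- read.table(parent_path, header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE)
  tibble(feature_id = bed$name,
         kind = parents$kind[match(bed$name, parents$feature_id)],
         chrom = as.character(bed$chrom),
         start = as.integer(bed$start) + 1L,  # BED is 0-based half-open
         end = as.integer(bed$end),
         strand = bed$strand,
         gene_id = parents$gene_id[match(bed$name, parents$feature_id)])
}

build_feature_table <- function(feats, derive_introns = TRUE) {
  feats <- as_tibble(feats)
  feats$kind <- tolower(feats$kind)
  bad_kind <- setdiff(unique(feats$kind), c("gene", "exon", "intron"))
  if (length(bad_kind)) {
    abort(sprintf("unknown feature kind(s): %s", paste(bad_kind, collapse = ", ")))
  }
  if (any(feats$start > feats$end)) {
    abort("feature with start > end")
  }
  is_gene <- feats$kind == "gene"
  feats$gene_id[is_gene] <- feats$feature_id[is_gene]
  genes <- feats$feature_id[is_gene]
  orphan <- !is_gene & !(feats$gene_id %in% genes)
  if (any(orphan)) {
    abort(sprintf("exon/intron without parent gene: %s",
                  paste(head(feats$feature_id[orphan]), collapse = ", ")))
  }
  if (derive_introns && !any(feats$kind == "intron") && any(feats$kind == "exon")) {
    feats <- bind_rows(feats, derive_introns_from_exons(feats))
  }
  feats$tss <- ifelse(feats$kind == "gene",
                      ifelse(feats$strand == "+", feats$start, feats$end),
                      NA_integer_)
  feats[order(feats$chrom, feats$start, feats$end), , drop = FALSE]
}

derive_introns_from_exons <- function(feats) {
  ex <- feats[feats$kind == "exon", , drop = FALSE]
  out <- lapply(split(ex, ex$gene_id), function(e) {
    if (nrow(e) < 2) return(NULL)
    e <- e[order(e$start), , drop = FALSE]
    tibble(feature_id = paste0(e$gene_id[1], "_intron", seq_len(nrow(e) - 1)),
           kind = "intron",
           chrom = e$chrom[1],
           start = e$end[-nrow(e)] + 1L,
           end = e$start[-1] - 1L,
           strand = e$strand[1],
           gene_id = e$gene_id[1])
  })
  bind_rows(out)
}

#' Write a feature table to TSV
#'
#' @param features a feature tibble from [read_features()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# sqtlkit feature table (1-based inclusive coordinates)", con)
  cols <- c("feature_id", "kind", "chrom", "start", "end", "strand", "gene_id")
  write.table(as.data.frame(features)[cols], con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Distance from a SNP to a gene's transcription start site
#'
#' @param snp one row of a SNP table (needs `chrom`, `pos`).
#' @param gene one row of a feature table with kind `"gene"` (needs `chrom`,
#'   `tss`).
#' @return Absolute distance in base pairs.
#' @export
tss_distance <- function(snp, gene) {
  if (!identical(as.character(snp$chrom), as.character(gene$chrom))) {
    abort("SNP and gene are on different chromosomes")
  }
  if (is.na(gene$tss)) abort("feature has no TSS (is it a gene?)")
  abs(as.numeric(snp$pos) - as.numeric(gene$tss))
}
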