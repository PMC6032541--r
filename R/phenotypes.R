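#' Counts per million
#'
#' @param counts a [count_matrix()] or plain matrix.
#' @return Matrix of CPM values.
#' @export
cpm <- function(counts) {
  m <- if (inherits(counts, "count_matrix")) counts$counts else counts
  lib <- colSums(m)
  if (any(lib == 0)) abort("sample with zero library size")
  sweep(m, 2, lib, "/") * 1e6
}

#' Filter features by expression breadth
#'
#' Retains features whose CPM exceeds `cpm_min` in strictly more than
#' `frac_min` of samples. With the defaults this is the "CPM > 0 in more
#' than 40% of samples" rule: a feature expressed in exactly 40% of samples
#' is removed.
#'
#' @param counts a [count_matrix()].
#' @param cpm_min CPM threshold (default 0).
#' @param frac_min sample fraction threshold (default 0.40, strict).
#' @return The filtered [count_matrix()].
#' @export
filter_expressed <- function(counts, cpm_min = 0, frac_min = 0.40) {
  x <- cpm(counts)
  keep <- rowMeans(x > cpm_min) > frac_min
  inform(sprintf("filter_expressed: %d of %d features retained (CPM > %g in > %.0f%% of %d samples)",
                 sum(keep), nrow(x), cpm_min, 100 * frac_min, ncol(x)))
  count_matrix(counts$counts[keep, , drop = FALSE], counts$features)
}

#' Exon inclusion ratios
#'
#' Inclusion = exon abundance over parent-gene abundance, computed on the
#' CPM scale so per-sample sequencing depth cancels identically. Entries are
#' missing where the parent gene has zero count.
#'
#' @param exon_counts a [count_matrix()] of exon counts.
#' @param gene_counts a [count_matrix()] of gene counts, same sample order.
#' @return A [ratio_matrix()] with kind `"inclusion"`.
#' @export
inclusion_ratio <- function(exon_counts, gene_counts) {
  stopifnot(identical(exon_counts$samples, gene_counts$samples))
  parent <- exon_counts$features$gene_id
  missing <- setdiff(parent, rownames(gene_counts$counts))
  if (length(missing)) {
    abort(sprintf("exons with no gene counts: parent gene(s) %s",
                  paste(head(missing), collapse = ", ")))
  }
  ex <- cpm(exon_counts)
  gn <- cpm(gene_counts)[parent, , drop = FALSE]
  vals <- ex / gn
  vals[gene_counts$counts[parent, , drop = FALSE] == 0] <- NA_real_
  ratio_matrix(vals, exon_counts$features, "inclusion")
}

#' Intron excision ratios
#'
#' Each intron junction's count over the total of its cluster (all junctions
#' of the same gene) within each sample. Ratios sum to 1 over a cluster
#' wherever the cluster total is non-zero; entries are missing where the
#' total is 0.
#'
#' @param intron_counts a [count_matrix()] of intron junction counts with
#'   `gene_id` as the cluster key.
#' @return A [ratio_matrix()] with kind `"excision"`.
#' @export
excision_ratio <- function(intron_counts) {
  cl <- intron_counts$features$gene_id
  if (any(is.na(cl) | cl == "")) abort("introns must carry a gene_id cluster key")
  m <- intron_counts$counts
  totals <- rowsum(m, cl)[as.character(cl), , drop = FALSE]
  vals <- m / totals
  vals[totals == 0] <- NA_real_
  ratio_matrix(vals, intron_counts$features, "excision")
}

# Rank-based inverse normal transform of one feature's values; ties get
# average ranks, offset-0.5 plotting positions.
inverse_normal <- function(x) {
  ok <- !is.na(x)
  r <- rank(x[ok], ties.method = "average")
  x[ok] <- qnorm((r - 0.5) / sum(ok))
  x
}

normalize_chain <- function(vals, kind, features, log2_first = TRUE,
                            common_distribution = FALSE) {
  if (log2_first) vals <- log2(vals)
  n_ok <- rowSums(!is.na(vals))
  sds <- apply(vals, 1, sd, na.rm = TRUE)
  drop <- n_ok < 3 | is.na(sds) | sds == 0
  if (any(drop)) {
    warn(sprintf("dropping %d feature(s) with < 3 non-missing values or zero variance",
                 sum(drop)))
    vals <- vals[!drop, , drop = FALSE]
  }
  if (common_distribution) {
    # map every feature onto the pooled empirical distribution
    ref <- sort(vals[!is.na(vals)])
    vals <- t(apply(vals, 1, function(x) {
      ok <- !is.na(x)
      x[ok] <- quantile(ref, (rank(x[ok], ties.method = "average") - 0.5) /
                          sum(ok), names = FALSE)
      x
    }))
  } else {
    vals <- t(apply(vals, 1, inverse_normal))
  }
  # individual-wise z-score over non-missing entries
  mu <- colMeans(vals, na.rm = TRUE)
  sdv <- apply(vals, 2, sd, na.rm = TRUE)
  sdv[sdv == 0 | is.na(sdv)] <- 1
  vals <- sweep(sweep(vals, 2, mu, "-"), 2, sdv, "/")
  pheno_matrix(vals, features, kind)
}

#' Normalise inclusion/excision ratios into phenotypes
#'
#' Per-entry filtering of ratios below `ratio_min`, log2 transform, a
#' per-feature rank-based inverse-normal map onto standard normal quantiles
#' (offset-0.5 ranks), then individual-wise z-score standardisation.
#' Features left with fewer than 3 non-missing values, or with zero
#' variance, are dropped with a warning.
#'
#' @param ratios a [ratio_matrix()].
#' @param ratio_min entries strictly below this are set missing
#'   (default 0.001, applied per entry).
#' @param common_distribution map all features onto a common empirical
#'   distribution instead of the standard normal (default FALSE).
#' @return A [pheno_matrix()] with the matching provenance tag.
#' @export
normalize_ratios <- function(ratios, ratio_min = 0.001,
                             common_distribution = FALSE) {
  vals <- ratios$values
  n_rm <- sum(vals < ratio_min, na.rm = TRUE)
  vals[vals < ratio_min] <- NA_real_
  inform(sprintf("normalize_ratios: %d entries < %g set missing (per-entry rule)",
                 n_rm, ratio_min))
  normalize_chain(vals, ratios$kind, ratios$features,
                  common_distribution = common_distribution)
}

#' Normalise expression counts into phenotypes
#'
#' log2-CPM with a 0.5 pseudocount (`log2((count + 0.5) * 1e6 / (lib + 1))`),
#' then the same per-feature inverse-normal and individual z-score chain as
#' [normalize_ratios()]. Observation-level precision weights are not
#' computed: all observations are weighted equally in downstream
#' regressions.
#'
#' @param counts a filtered [count_matrix()] of gene or exon counts.
#' @param kind provenance tag, `"gene_expr"` or `"exon_expr"`; defaults by
#'   the feature kind in `counts`.
#' @param common_distribution see [normalize_ratios()].
#' @return A [pheno_matrix()].
#' @export
normalize_expression <- function(counts, kind = NULL,
                                 common_distribution = FALSE) {
  if (is.null(kind)) {
    kind <- if (all(counts$features$kind == "gene")) "gene_expr" else "exon_expr"
  }
  lib <- colSums(counts$counts)
  if (any(lib == 0)) abort("sample with zero library size")
  logcpm <- log2(sweep(counts$counts + 0.5, 2, lib + 1, "/") * 1e6)
  normalize_chain(logcpm, kind, counts$features, log2_first = FALSE,
                  common_distribution = common_distribution)
}
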