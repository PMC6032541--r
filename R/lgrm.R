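#' Build a local genomic relationship matrix
#'
#' Realised-relatedness matrix from the SNPs inside a feature's cis window
#' only. Two constructions are provided:
#'
#' * `"vanraden"` (default): centred dosages `W = M - 2p`, `G = W W' /
#'   (2 sum p(1-p))`;
#' * `"gcta"`: per-SNP standardised dosages `Z`, `G = Z Z' / m`.
#'
#' Monomorphic SNPs are excluded; a small ridge is added to the diagonal so
#' local windows with few SNPs stay invertible.
#'
#' @param genotypes a [geno_matrix()].
#' @param feature one row of a feature tibble (needs `chrom`, `start`,
#'   `end`), or NULL to use every SNP.
#' @param window cis half-width in bp (default 1e6).
#' @param method `"vanraden"` or `"gcta"`.
#' @param ridge diagonal ridge (default 1e-6).
#' @param min_snps minimum SNPs required in the window (default 10).
#' @return An object of class `local_grm`: list with `G` (samples x
#'   samples), `samples`, `n_snps`, `method`, `feature_id`.
#' @export
build_lgrm <- function(genotypes, feature = NULL, window = 1e6,
                       method = c("vanraden", "gcta"), ridge = 1e-6,
                       min_snps = 10) {
  method <- match.arg(method)
  s <- genotypes$snps
  if (is.null(feature)) {
    in_win <- rep(TRUE, nrow(s))
    fid <- NA_character_
  } else {
    in_win <- s$chrom == feature$chrom &
      s$pos >= feature$start - window & s$pos <= feature$end + window
    fid <- feature$feature_id
  }
  M <- genotypes$dosage[, in_win, drop = FALSE]
  p <- colMeans(M) / 2
  poly <- p > 0 & p < 1
  M <- M[, poly, drop = FALSE]
  p <- p[poly]
  m <- ncol(M)
  if (m < min_snps) {
    abort(sprintf("only %d polymorphic SNP(s) in window (need >= %d); widen the window",
                  m, min_snps))
  }
  G <- if (method == "vanraden") {
    W <- sweep(M, 2, 2 * p, "-")
    tcrossprod(W) / (2 * sum(p * (1 - p)))
  } else {
    Z <- sweep(sweep(M, 2, 2 * p, "-"), 2, sqrt(2 * p * (1 - p)), "/")
    tcrossprod(Z) / m
  }
  G <- G + diag(ridge, nrow(G))
  dimnames(G) <- list(genotypes$samples, genotypes$samples)
  structure(list(G = G, samples = genotypes$samples, n_snps = m,
                 method = method, feature_id = fid),
            class = "local_grm")
}

#' @export
print.local_grm <- function(x, ...) {
  cat(sprintf("<local_grm> %d samples, %d SNPs (%s), mean diag %.3f\n",
              length(x$samples), x$n_snps, x$method, mean(diag(x$G))))
  invisible(x)
}
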