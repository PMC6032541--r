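#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a bivariate REML fit
#'
#' @param x a [bivariate_reml()] fit.
#' @param ... unused.
#' @return Tibble with one row per (co)variance parameter.
#' @method tidy bivar_fit
#' @export
tidy.bivar_fit <- function(x, ...) {
  tibble(term = c("var_g1", "var_g2", "cov_g", "var_e1", "var_e2", "cov_e"),
         estimate = c(x$var_g1, x$var_g2, x$cov_g,
                      x$var_e1, x$var_e2, x$cov_e))
}

#' One-row summary of a bivariate REML fit
#'
#' @param x a [bivariate_reml()] fit.
#' @param ... unused.
#' @return One-row tibble: `r_lg`, `se_r`, heritability-like variance
#'   shares, `loglik`, `converged`, `n_iter`.
#' @method glance bivar_fit
#' @export
glance.bivar_fit <- function(x, ...) {
  tibble(r_lg = x$r_lg, se_r = x$se_r,
         h2_1 = x$var_g1 / (x$var_g1 + x$var_e1),
         h2_2 = x$var_g2 / (x$var_g2 + x$var_e2),
         loglik = x$loglik, converged = x$converged, n_iter = x$n_iter)
}

#' Tidy a cross-tissue validation result
#'
#' @param x a [run_validation()] object.
#' @param ... unused.
#' @return Tibble of the four cell counts with the Fisher p and odds ratio.
#' @method tidy sqk_validation
#' @export
tidy.sqk_validation <- function(x, ...) {
  tibble(holdout = rep(rownames(x$table), 2),
         meta = rep(colnames(x$table), each = 2),
         n = as.vector(x$table),
         odds_ratio = x$odds_ratio, fisher_p = x$fisher_p)
}
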