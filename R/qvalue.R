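#' Storey q-values
#'
#' Per-analysis false discovery rate estimates. The null proportion `pi0` is
#' estimated on the lambda grid 0.05-0.95 with a df-3 smoothing spline
#' evaluated at the largest lambda, clamped to (0, 1]; q-values are then
#' `pi0 * p * m / rank`, enforced monotone from the largest p down. With
#' `method = "bh"` (or when too few p-values make the smoother unstable,
#' in which case `pi0` is set to 1) this reduces to Benjamini-Hochberg.
#'
#' @param p numeric vector of p-values.
#' @param method `"storey"` (default) or `"bh"`.
#' @param lambda grid for the pi0 smoother.
#' @return Numeric vector of q-values, same order as `p`.
#' @export
qvalues <- function(p, method = c("storey", "bh"),
                    lambda = seq(0.05, 0.95, 0.05)) {
  method <- match.arg(method)
  if (!length(p)) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values outside [0, 1]")
  if (method == "bh") return(p.adjust(p, "BH"))
  ok <- !is.na(p)
  m <- sum(ok)
  pi0 <- if (m < 100) 1 else estimate_pi0(p[ok], lambda)
  q <- rep(NA_real_, length(p))
  q[ok] <- pi0 * p.adjust(p[ok], "BH")
  q
}

estimate_pi0 <- function(p, lambda) {
  pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
  fit <- try(smooth.spline(lambda, pi0_l, df = 3), silent = TRUE)
  pi0 <- if (inherits(fit, "try-error")) min(pi0_l) else
    predict(fit, x = max(lambda))$y
  min(max(pi0, 1e-8), 1)
}
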