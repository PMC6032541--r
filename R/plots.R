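#' Manhattan-style plot of a cis scan
#'
#' Plots -log10(p) against SNP position for one feature (or all features
#' faceted). Following the convention used for scan figures, points can be
#' pre-filtered to `p < p_max` before plotting; the filter never affects
#' calling, only display.
#'
#' @param assoc a [scan_cis()] result tibble.
#' @param feature_id optional feature to restrict to.
#' @param p_max plot-only significance pre-filter (default 1, i.e. none;
#'   1e-4 reproduces the usual scan-figure filter).
#' @return A ggplot object.
#' @export
plot_scan <- function(assoc, feature_id = NULL, p_max = 1) {
  if (!is.null(feature_id)) {
    assoc <- assoc %>% filter(.data$feature_id == !!feature_id)
  }
  assoc <- assoc %>% filter(.data$p < p_max)
  gg <- ggplot2::ggplot(assoc,
                        ggplot2::aes(x = .data$pos / 1e6,
                                     y = -log10(.data$p))) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::labs(x = "position (Mb)", y = expression(-log[10](p)))
  if (is.null(feature_id) && length(unique(assoc$feature_id)) > 1) {
    gg <- gg + ggplot2::facet_wrap(~feature_id, scales = "free_x")
  }
  gg
}

#' Plot meta-analysis significance against a single tissue
#'
#' Scatter of the multi-transcriptome -log10(p) against the held-out
#' tissue's -log10(p), coloured by meta-significance.
#'
#' @param object a [run_validation()] result.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot sqk_validation
#' @export
autoplot.sqk_validation <- function(object, ...) {
  ggplot2::ggplot(object$meta,
                  ggplot2::aes(x = -log10(.data$holdout_p),
                               y = -log10(.data$p),
                               colour = .data$meta_sig)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(object$p_meta),
                        linetype = "dashed") +
    ggplot2::geom_vline(xintercept = -log10(object$p_single),
                        linetype = "dashed") +
    ggplot2::labs(x = "holdout tissue -log10(p)",
                  y = "meta-analysis -log10(p)", colour = "meta significant")
}

#' Plot the REML log-likelihood path of a bivariate fit
#'
#' @param object a [bivariate_reml()] fit.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot bivar_fit
#' @export
autoplot.bivar_fit <- function(object, ...) {
  d <- tibble(iteration = seq_along(object$ll_path) - 1,
              loglik = object$ll_path)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$iteration, y = .data$loglik)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "AI-REML iteration", y = "restricted log-likelihood")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
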