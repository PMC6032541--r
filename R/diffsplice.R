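#' Exon-intron adjacency map
#'
#' An intron is adjacent to an exon when it shares a boundary
#' (`intron start == exon end + 1` or `intron end == exon start - 1`); for
#' exons with no boundary-sharing intron, the nearest intron of the same
#' gene within `max_gap` bp is used as a fallback. The rule applied is
#' recorded per pair.
#'
#' @param features feature tibble containing exons and introns.
#' @param max_gap fallback search distance in bp (default 10 kb).
#' @return Tibble: `exon_id`, `intron_id`, `gene_id`, `rule`
#'   (`"boundary"` or `"nearest"`).
#' @export
adjacent_introns <- function(features, max_gap = 10000) {
  ex <- features[features$kind == "exon", , drop = FALSE]
  it <- features[features$kind == "intron", , drop = FALSE]
  out <- lapply(seq_len(nrow(ex)), function(i) {
    e <- ex[i, ]
    gi <- it[it$gene_id == e$gene_id, , drop = FALSE]
    if (!nrow(gi)) return(NULL)
    hit <- gi$start == e$end + 1L | gi$end == e$start - 1L
    if (any(hit)) {
      tibble(exon_id = e$feature_id, intron_id = gi$feature_id[hit],
             gene_id = e$gene_id, rule = "boundary")
    } else {
      d <- pmin(abs(gi$start - e$end), abs(e$start - gi$end))
      j <- which.min(d)
      if (d[j] <= max_gap) {
        tibble(exon_id = e$feature_id, intron_id = gi$feature_id[j],
               gene_id = e$gene_id, rule = "nearest")
      } else NULL
    }
  })
  bind_rows(out)
}

#' Differential splicing across tissues (mixed model)
#'
#' Per feature, fits `y = animal(random) + experiment(fixed) +
#' tissue(fixed) + e` by REML and reports the tissue-term F test with
#' Satterthwaite denominator degrees of freedom. When every animal is
#' observed exactly once the random effect is unidentifiable and the model
#' reduces exactly to the fixed-effect two-way ANOVA, which is then fitted
#' directly by OLS.
#'
#' @param pheno a [pheno_matrix()] of inclusion or excision phenotypes.
#' @param design tibble with columns `sample_id`, `animal`, `experiment`,
#'   `tissue`, one row per sample of `pheno`.
#' @return Tibble: `feature_id`, `kind`, `term`, `statistic` (F), `df1`,
#'   `df2`, `p`, `q` (Storey q within each feature kind), `gene_id`.
#' @export
tissue_mixed_model <- function(pheno, design) {
  design <- as_tibble(design)
  stopifnot(all(pheno$samples %in% design$sample_id))
  design <- design[match(pheno$samples, design$sample_id), , drop = FALSE]
  if (length(unique(design$tissue)) < 2) abort("need >= 2 tissues")
  design$animal <- factor(design$animal)
  design$experiment <- factor(design$experiment)
  design$tissue <- factor(design$tissue)
  single_obs <- max(table(design$animal)) == 1L

  res <- purrr::map_dfr(seq_len(nrow(pheno$values)), function(i) {
    y <- pheno$values[i, ]
    ok <- !is.na(y)
    d <- design[ok, , drop = FALSE]
    d$y <- y[ok]
    d <- droplevels(d)
    if (length(unique(d$tissue)) < 2 || nrow(d) < 4) {
      warn(sprintf("feature %s skipped: deficient design", rownames(pheno$values)[i]))
      return(NULL)
    }
    use_fixed <- single_obs || max(table(d$animal)) == 1L
    fstat <- tryCatch({
      if (use_fixed) {
        form <- if (length(unique(d$experiment)) > 1) {
          y ~ experiment + tissue
        } else y ~ tissue
        a <- anova(lm(form, data = d))
        r <- a["tissue", , drop = FALSE]
        c(F = r$`F value`, df1 = r$Df, df2 = a["Residuals", "Df"],
          p = r$`Pr(>F)`)
      } else {
        form <- if (length(unique(d$experiment)) > 1) {
          y ~ experiment + tissue + (1 | animal)
        } else y ~ tissue + (1 | animal)
        m <- suppressMessages(suppressWarnings(
          lmerTest::lmer(form, data = d,
                         control = lme4::lmerControl(calc.derivs = FALSE,
                                                     check.conv.singular = "ignore"))))
        a <- suppressWarnings(anova(m, type = 3, ddf = "Satterthwaite"))
        r <- a["tissue", , drop = FALSE]
        c(F = r$`F value`, df1 = r$NumDF, df2 = r$DenDF, p = r$`Pr(>F)`)
      }
    }, error = function(e) {
      warn(sprintf("feature %s skipped: %s",
                   rownames(pheno$values)[i], conditionMessage(e)))
      NULL
    })
    if (is.null(fstat)) return(NULL)
    tibble(feature_id = rownames(pheno$values)[i],
           kind = pheno$features$kind[i],
           term = "tissue",
           statistic = unname(fstat["F"]), df1 = unname(fstat["df1"]),
           df2 = unname(fstat["df2"]), p = unname(fstat["p"]),
           gene_id = pheno$features$gene_id[i])
  })
  add_q_by_kind(res)
}

#' Differential splicing between breeds (linear model)
#'
#' Per feature, ordinary least squares of the phenotype on a two-level
#' breed indicator; reports the breed t statistic and p value. Equivalent
#' to the two-sample equal-variance t-test.
#'
#' @param pheno a [pheno_matrix()].
#' @param breed per-sample breed labels (exactly 2 levels), in the order of
#'   `pheno$samples` or a tibble `sample_id`, `breed`.
#' @return Tibble: `feature_id`, `kind`, `term`, `statistic` (t), `df`,
#'   `p`, `q`, `gene_id`.
#' @export
breed_model <- function(pheno, breed) {
  if (is.data.frame(breed)) {
    breed <- breed$breed[match(pheno$samples, breed$sample_id)]
  }
  breed <- factor(breed)
  if (nlevels(breed) != 2) abort("exactly 2 breed levels required")
  res <- purrr::map_dfr(seq_len(nrow(pheno$values)), function(i) {
    y <- pheno$values[i, ]
    ok <- !is.na(y)
    if (length(unique(breed[ok])) < 2 || sum(ok) < 3) return(NULL)
    fit <- lm(y[ok] ~ breed[ok])
    s <- summary(fit)$coefficients
    tibble(feature_id = rownames(pheno$values)[i],
           kind = pheno$features$kind[i],
           term = "breed",
           statistic = s[2, "t value"], df = fit$df.residual,
           p = s[2, "Pr(>|t|)"],
           gene_id = pheno$features$gene_id[i])
  })
  add_q_by_kind(res)
}

add_q_by_kind <- function(res, method = "storey") {
  if (!nrow(res)) return(res)
  res %>%
    group_by(.data$kind) %>%
    mutate(q = qvalues(.data$p, method = method)) %>%
    ungroup()
}

#' Call differentially spliced genes by the exon-intron conjunction rule
#'
#' A gene is called when at least one of its exons is significant
#' (q < `fdr`) AND at least one intron adjacent to that exon is also
#' significant (q < `fdr`), with the two FDR filters applied separately to
#' the exon and intron result sets. The effective combined threshold is
#' reported as `fdr^2` (0.1 x 0.1 = 0.01 at the default).
#'
#' @param exon_results,intron_results outputs of [tissue_mixed_model()] or
#'   [breed_model()] on inclusion and excision phenotypes respectively.
#' @param features feature tibble (for the adjacency rule).
#' @param fdr per-set FDR threshold, default 0.1.
#' @return Tibble of called genes: `gene_id`, `exon_id`, `intron_id`,
#'   `exon_q`, `intron_q`, `combined_q`, `adjacency_rule`; attribute
#'   `combined_threshold` = `fdr^2`. The attribute `ranked_genes` holds all
#'   called genes ordered by the minimum combined exon x intron q.
#' @export
call_differential_splicing <- function(exon_results, intron_results,
                                       features, fdr = 0.1) {
  adj <- adjacent_introns(features)
  sig_ex <- exon_results %>% filter(.data$q < fdr)
  sig_in <- intron_results %>% filter(.data$q < fdr)
  calls <- adj %>%
    dplyr::inner_join(sig_ex %>% select(exon_id = "feature_id",
                                        exon_q = "q"),
                      by = "exon_id") %>%
    dplyr::inner_join(sig_in %>% select(intron_id = "feature_id",
                                        intron_q = "q"),
                      by = "intron_id") %>%
    mutate(combined_q = .data$exon_q * .data$intron_q) %>%
    select("gene_id", "exon_id", "intron_id", "exon_q", "intron_q",
           "combined_q", adjacency_rule = "rule") %>%
    arrange(.data$combined_q)
  attr(calls, "combined_threshold") <- fdr^2
  attr(calls, "ranked_genes") <- if (nrow(calls)) {
    calls %>%
      group_by(.data$gene_id) %>%
      summarise(min_combined_q = min(.data$combined_q), .groups = "drop") %>%
      arrange(.data$min_combined_q)
  } else {
    tibble(gene_id = character(0), min_combined_q = numeric(0))
  }
  calls
}
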