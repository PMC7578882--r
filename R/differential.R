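# Differential abundance: Wilcoxon rank-sum screening and
# Kruskal-Wallis + linear-discriminant effect-size scoring (two-class,
# single-factor reimplementation of the LEfSe procedure).

# two-sided Mann-Whitney/Wilcoxon rank-sum p-value.
# Exact enumeration when both groups are small and tie-free (wilcox.test's
# default rule); otherwise the tie-corrected normal approximation without
# continuity correction, so that the two-group case agrees algebraically
# with the Kruskal-Wallis chi-squared test.
wilcoxon_p <- function(x, y) {
  if (length(x) < 1L || length(y) < 1L) abort("both groups must be non-empty")
  if (stats::var(c(x, y)) == 0) return(1)
  suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided",
                                      correct = FALSE)$p.value)
}

#' Wilcoxon rank-sum screen of features
#'
#' Tests every feature (column) for a two-sided location difference between
#' the two groups with the Mann-Whitney/Wilcoxon rank-sum test and flags
#' features with p below `alpha`.  Following common biomarker-screen
#' practice, no multiple-testing adjustment is applied by default (raw
#' p < alpha); Benjamini-Hochberg adjustment is available via `adjust`.
#'
#' @param abund Samples x features abundance matrix (or an `otu_table`,
#'   converted to relative abundance).
#' @param groups Two-level per-sample labels.
#' @param alpha Selection threshold on the (optionally adjusted) p-value.
#' @param case_level Which level is the case group (default: a level named
#'   `"case"` if present, else the first level).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return A data.frame of class `differential_result` with columns
#'   `feature_id`, `mean_case`, `mean_control`, `direction`, `p_value`,
#'   `p_adjusted`, `selected`.
#' @export
wilcoxon_screen <- function(abund, groups, alpha = 0.05, case_level = NULL,
                            adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  m <- as_abundance(abund, normalise = inherits(abund, "otu_table"))
  groups <- as_group_factor(groups, n = nrow(m))
  if (any(table(groups) < 2L)) abort("each group needs at least 2 samples")
  case_level <- resolve_case_level(groups, case_level)
  control_level <- setdiff(levels(groups), case_level)
  is_case <- groups == case_level
  if (is.null(colnames(m))) colnames(m) <- paste0("feature_", seq_len(ncol(m)))

  p <- vapply(seq_len(ncol(m)), function(j) {
    wilcoxon_p(m[is_case, j], m[!is_case, j])
  }, numeric(1))
  mean_case <- colMeans(m[is_case, , drop = FALSE])
  mean_control <- colMeans(m[!is_case, , drop = FALSE])
  p_adj <- if (adjust == "BH") stats::p.adjust(p, "BH") else p
  out <- data.frame(
    feature_id = colnames(m),
    mean_case = mean_case,
    mean_control = mean_control,
    direction = ifelse(mean_case > mean_control, "enriched_case",
                       ifelse(mean_case < mean_control, "enriched_control",
                              "none")),
    p_value = p,
    p_adjusted = p_adj,
    selected = p_adj < alpha,
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(out, "alpha") <- alpha
  attr(out, "case_level") <- case_level
  attr(out, "control_level") <- control_level
  class(out) <- c("differential_result", "data.frame")
  out
}

#' Kruskal-Wallis rank-sum test p-value
#'
#' Tie-corrected Kruskal-Wallis statistic referred to a chi-squared
#' distribution with k - 1 degrees of freedom.  Returns p = 1 when every
#' observation is identical (degenerate statistic).
#'
#' @param values Numeric vector of observations.
#' @param groups Per-observation group labels (>= 2 groups, none empty).
#' @return Two-sided p-value.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- as_group_factor(groups, n = length(values), two_level = FALSE)
  if (nlevels(groups) < 2L) abort("at least 2 non-empty groups are required")
  if (stats::var(values) == 0) return(1)
  stats::kruskal.test(values, groups)$p.value
}

#' Linear-discriminant effect size of differentially abundant features
#'
#' Two-class, single-factor effect-size scoring in the style of LEfSe:
#' features are prescreened with the Kruskal-Wallis rank-sum test at
#' `kw_alpha`; for each feature the abundances (row-normalised and scaled to
#' sum `scale_to`, 1e6 by convention) are bootstrapped `n_boot` times within
#' groups, the absolute difference of group means along the per-feature
#' discriminant is averaged over bootstraps, and the effect is reported as
#' `log10` of that difference, floored at 1 for any non-zero effect.  A
#' feature passes when the Kruskal-Wallis p is below `kw_alpha` AND the
#' log10 score is at least `lda_threshold` (the conventional cutoff is 2).
#' A feature with zero variance overall gets score 0 and never passes.
#'
#' @param abund Samples x features abundance matrix or `otu_table`.
#' @param groups Two-level per-sample labels.
#' @param kw_alpha Kruskal-Wallis prescreen threshold (default 0.05).
#' @param lda_threshold Log10 effect-size cutoff (default 2).
#' @param n_boot Bootstrap resamples for effect averaging (default 30).
#' @param seed Integer seed for the bootstrap.
#' @param scale_to Total abundance each sample is scaled to before scoring
#'   (default 1e6).
#' @param case_level As in [wilcoxon_screen()].
#' @return Data.frame of class `lda_effect_result` with columns
#'   `feature_id`, `mean_case`, `mean_control` (scaled units),
#'   `enriched_group`, `kw_p`, `lda_score_log10`, `passes`.
#' @export
lda_effect_size <- function(abund, groups, kw_alpha = 0.05,
                            lda_threshold = 2, n_boot = 30, seed = NULL,
                            scale_to = 1e6, case_level = NULL) {
  m <- as_abundance(abund, normalise = inherits(abund, "otu_table"))
  groups <- as_group_factor(groups, n = nrow(m))
  case_level <- resolve_case_level(groups, case_level)
  control_level <- setdiff(levels(groups), case_level)
  is_case <- groups == case_level
  if (sum(is_case) < 2L || sum(!is_case) < 2L) {
    abort("each group needs at least 2 samples")
  }
  if (is.null(colnames(m))) colnames(m) <- paste0("feature_", seq_len(ncol(m)))
  scaled <- m / rowSums(m) * scale_to

  kw_p <- vapply(seq_len(ncol(m)), function(j) {
    kruskal_wallis(scaled[, j], groups)
  }, numeric(1))

  case_idx <- which(is_case)
  ctrl_idx <- which(!is_case)
  eff <- with_seed(seed, {
    acc <- numeric(ncol(m))
    for (b in seq_len(n_boot)) {
      bi <- sample(case_idx, replace = TRUE)
      bj <- sample(ctrl_idx, replace = TRUE)
      acc <- acc + (colMeans(scaled[bi, , drop = FALSE]) -
                      colMeans(scaled[bj, , drop = FALSE]))
    }
    acc / n_boot
  })
  zero_var <- apply(scaled, 2L, stats::var) == 0
  raw <- abs(eff)
  score <- ifelse(zero_var | raw == 0, 0, pmax(1, log10(raw)))
  mean_case <- colMeans(scaled[case_idx, , drop = FALSE])
  mean_control <- colMeans(scaled[ctrl_idx, , drop = FALSE])
  out <- data.frame(
    feature_id = colnames(m),
    mean_case = mean_case,
    mean_control = mean_control,
    enriched_group = ifelse(mean_case >= mean_control, case_level,
                            control_level),
    kw_p = kw_p,
    lda_score_log10 = score,
    passes = kw_p < kw_alpha & score >= lda_threshold & !zero_var,
    stringsAsFactors = FALSE, row.names = NULL
  )
  class(out) <- c("lda_effect_result", "data.frame")
  out
}
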