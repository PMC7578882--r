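# Random-forest marker selection: permutation-importance ranking, repeated
# stratified k-fold cross-validation error curves over nested feature
# prefixes, and the minimum-error-plus-one-SD selection rule.

#' Rank features by random-forest permutation importance
#'
#' Fits a random forest (all parameters default except `importance = TRUE`)
#' on all features and ranks them by decreasing mean decrease in accuracy.
#' Ties are broken by column order, so the ranking is deterministic for a
#' given seed.
#'
#' @param abund Samples x features abundance matrix or `otu_table`.
#' @param groups Two-level per-sample labels.
#' @param n_trees Ensemble size (default 500).
#' @param seed Integer seed.
#' @return Character vector of feature ids, most important first, with the
#'   importance scores attached as attribute `"importance"`.
#' @export
rank_features_by_importance <- function(abund, groups, n_trees = 500,
                                        seed = NULL) {
  m <- as_abundance(abund, normalise = inherits(abund, "otu_table"))
  if (ncol(m) < 2L) abort("at least 2 features are required")
  groups <- as_group_factor(groups, n = nrow(m))
  if (is.null(colnames(m))) colnames(m) <- paste0("feature_", seq_len(ncol(m)))
  rf <- with_seed(seed, randomForest::randomForest(
    x = m, y = groups, ntree = n_trees, importance = TRUE))
  imp <- rf$importance[, "MeanDecreaseAccuracy"]
  ord <- order(imp, decreasing = TRUE)  # stable: ties keep column order
  structure(colnames(m)[ord], importance = imp[ord])
}

#' Cross-validation error curve over nested feature sets
#'
#' For each prefix of the importance ranking (sizes given by `sizes`,
#' default 1..K), runs `n_trials` independent rounds of stratified
#' `n_folds`-fold cross-validation of a random forest restricted to that
#' prefix.  The error of a trial is the misclassification rate pooled over
#' all held-out folds.  Each trial draws a fresh fold partition, shared
#' across sizes within the trial.
#'
#' @param abund Samples x features abundance matrix or `otu_table`.
#' @param groups Two-level per-sample labels.
#' @param ranked Ordered feature ids (most important first).
#' @param n_trials Number of cross-validation rounds (default 5).
#' @param n_folds Number of folds (default 5); each group must have at
#'   least `n_folds` members.
#' @param n_trees Trees per forest (default 500).
#' @param seed Integer seed.
#' @param sizes Feature-set sizes to evaluate (default every prefix).
#' @return Object of class `cv_error_curve`: list with `feature_counts`,
#'   `errors` (trials x sizes matrix), `mean_error`, `sd_error`.
#' @export
cv_error_curve <- function(abund, groups, ranked, n_trials = 5, n_folds = 5,
                           n_trees = 500, seed = NULL,
                           sizes = seq_along(ranked)) {
  m <- as_abundance(abund, normalise = inherits(abund, "otu_table"))
  groups <- as_group_factor(groups, n = nrow(m))
  if (length(ranked) == 0L) abort("ranked feature list is empty")
  if (!all(ranked %in% colnames(m))) {
    abort("ranked features missing from the abundance matrix: %s",
          paste(setdiff(ranked, colnames(m)), collapse = ", "))
  }
  if (length(sizes) == 0L || any(sizes < 1) || any(sizes > length(ranked)) ||
      is.unsorted(sizes, strictly = TRUE)) {
    abort("sizes must be strictly increasing integers in 1..length(ranked)")
  }
  tab <- table(groups)
  if (any(tab < n_folds)) {
    abort(paste0("smallest group (n = %d) has fewer members than n_folds ",
                 "(%d); reduce n_folds"), min(tab), n_folds)
  }
  n <- nrow(m)
  errors <- matrix(NA_real_, n_trials, length(sizes),
                   dimnames = list(paste0("trial_", seq_len(n_trials)),
                                   paste0("size_", sizes)))
  with_seed(seed, {
    for (trial in seq_len(n_trials)) {
      fold <- integer(n)  # stratified: shuffle fold labels within groups
      for (g in levels(groups)) {
        idx <- which(groups == g)
        fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
      }
      for (si in seq_along(sizes)) {
        feats <- ranked[seq_len(sizes[si])]
        wrong <- 0L
        for (f in seq_len(n_folds)) {
          test <- fold == f
          rf <- randomForest::randomForest(
            x = m[!test, feats, drop = FALSE], y = groups[!test],
            ntree = n_trees)
          pred <- stats::predict(rf, m[test, feats, drop = FALSE])
          wrong <- wrong + sum(pred != groups[test])
        }
        errors[trial, si] <- wrong / n
      }
    }
  })
  structure(list(feature_counts = as.integer(sizes), errors = errors,
                 mean_error = colMeans(errors),
                 sd_error = apply(errors, 2L, function(e) {
                   if (length(e) > 1L) stats::sd(e) else 0
                 })),
            class = "cv_error_curve")
}

#' @export
print.cv_error_curve <- function(x, ...) {
  cat(sprintf("CV error curve: %d trials x %d feature-set sizes\n",
              nrow(x$errors), length(x$feature_counts)))
  i <- which.min(x$mean_error)
  cat(sprintf("  minimum mean error %.4f at %d feature(s) (SD %.4f)\n",
              x$mean_error[i], x$feature_counts[i], x$sd_error[i]))
  invisible(x)
}

#' @export
plot.cv_error_curve <- function(x, ...) {
  graphics::plot(x$feature_counts, x$mean_error, type = "b", pch = 19,
                 ylim = range(c(x$mean_error - x$sd_error,
                                x$mean_error + x$sd_error)),
                 xlab = "Number of top-ranked features",
                 ylab = "Cross-validation error", ...)
  graphics::arrows(x$feature_counts, x$mean_error - x$sd_error,
                   x$feature_counts, x$mean_error + x$sd_error,
                   angle = 90, code = 3, length = 0.03)
  invisible(x)
}

#' Select the optimal marker set from a CV error curve
#'
#' Applies the minimum-error-plus-SD rule: the cutoff is the minimum mean
#' cross-validation error plus the between-trial SD at the minimising size
#' (ties resolved to the smallest size); every size with mean error strictly
#' below the cutoff is a candidate, and the smallest candidate wins.  When
#' the SD at the minimum is 0 the comparison is relaxed to "at or below",
#' otherwise the minimum itself would be excluded.
#'
#' @param curve A `cv_error_curve`.
#' @param ranked Ordered feature ids (as passed to [cv_error_curve()]);
#'   truncated to the chosen size.  Optional.
#' @return Object of class `marker_set`: list with `ranked_features`
#'   (chosen markers), `chosen_size`, `min_error`, `sd_at_min`, `cutoff`,
#'   `candidate_sizes`, `full_ranking`.
#' @export
select_optimal_markers <- function(curve, ranked = NULL) {
  stopifnot(inherits(curve, "cv_error_curve"))
  me <- curve$mean_error
  if (length(me) == 0L) abort("empty error curve")
  i_min <- which(me == min(me))[1L]
  min_error <- me[i_min]
  sd_at_min <- curve$sd_error[i_min]
  cutoff <- min_error + sd_at_min
  below <- if (sd_at_min == 0) me <= cutoff else me < cutoff
  candidate_sizes <- curve$feature_counts[below]
  chosen_size <- min(candidate_sizes)
  structure(list(
    ranked_features = if (is.null(ranked)) NULL
                      else ranked[seq_len(chosen_size)],
    chosen_size = as.integer(chosen_size),
    min_error = unname(min_error),
    sd_at_min = unname(sd_at_min),
    cutoff = unname(cutoff),
    candidate_sizes = as.integer(candidate_sizes),
    full_ranking = ranked
  ), class = "marker_set")
}

#' @export
print.marker_set <- function(x, ...) {
  cat(sprintf("Marker set: %d feature(s) chosen\n", x$chosen_size))
  cat(sprintf("  min CV error %.4f (SD %.4f), cutoff %.4f, candidate sizes: %s\n",
              x$min_error, x$sd_at_min, x$cutoff,
              paste(x$candidate_sizes, collapse = ", ")))
  if (!is.null(x$ranked_features)) {
    cat("  markers:", paste(x$ranked_features, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Discover an optimal microbial marker set
#'
#' The full marker-discovery pipeline on a labeled discovery cohort:
#' relative abundance -> Wilcoxon rank-sum screen (raw p < `screen_alpha`)
#' -> random-forest permutation-importance ranking of the screened features
#' -> `cv_trials` trials of stratified `cv_folds`-fold cross-validation over
#' nested feature prefixes -> minimum-error-plus-SD selection.  The full
#' audit trail (screen table, ranking, error curve) is kept on the result.
#'
#' @param table An `otu_table` (discovery cohort).
#' @param meta A `sample_metadata` data.frame, or a per-sample label vector.
#' @param screen_alpha Wilcoxon screen threshold (default 0.05).
#' @param n_trees Trees for the importance ranking (default 500).
#' @param cv_trials,cv_folds Cross-validation layout (default five trials
#'   of fivefold).
#' @param cv_trees Trees per cross-validation fit (default `n_trees`).
#' @param seed Master seed; ranking and cross-validation use sub-streams
#'   derived with [derive_seed()].
#' @param case_level As in [wilcoxon_screen()].
#' @return A `marker_set` with extra elements `screen` (the
#'   `differential_result`), `curve` (the `cv_error_curve`) and `config`.
#' @export
discover_markers <- function(table, meta, screen_alpha = 0.05,
                             n_trees = 500, cv_trials = 5, cv_folds = 5,
                             cv_trees = n_trees, seed = 1,
                             case_level = NULL) {
  stopifnot(inherits(table, "otu_table"))
  groups <- if (is.data.frame(meta)) align_metadata(table, meta)$group
            else meta
  rel <- relative_abundance(table)
  screen <- wilcoxon_screen(rel, groups, alpha = screen_alpha,
                            case_level = case_level)
  keep <- screen$feature_id[screen$selected]
  if (length(keep) == 0L) {
    abort("the Wilcoxon screen selected no features at alpha = %g",
          screen_alpha)
  }
  if (length(keep) == 1L) {
    ranked <- keep  # a single screened feature needs no ranking
  } else {
    ranked <- rank_features_by_importance(rel[, keep, drop = FALSE], groups,
                                          n_trees = n_trees,
                                          seed = derive_seed(seed, 1))
  }
  curve <- cv_error_curve(rel[, keep, drop = FALSE], groups, ranked,
                          n_trials = cv_trials, n_folds = cv_folds,
                          n_trees = cv_trees, seed = derive_seed(seed, 2))
  ms <- select_optimal_markers(curve, ranked)
  ms$screen <- screen
  ms$curve <- curve
  ms$config <- list(screen_alpha = screen_alpha, n_trees = n_trees,
                    cv_trials = cv_trials, cv_folds = cv_folds,
                    cv_trees = cv_trees, seed = seed)
  ms
}
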