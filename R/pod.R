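# Probability-of-disease (POD) classification: final marker-based random
# forest, per-sample tree-vote score, and ROC/AUC evaluation across
# cohorts.

#' Train the marker-based POD ensemble
#'
#' Fits a random forest on the marker features only.  The handle exposes
#' per-tree votes for any new sample (via [pod_index()]) and remembers the
#' training sample ids so later evaluations can refuse leaked samples.
#'
#' @param table An `otu_table` (or samples x features abundance matrix).
#' @param groups Two-level per-sample labels (>= 2 samples per group).
#' @param markers Character vector of marker feature ids, or a
#'   `marker_set` from [discover_markers()].
#' @param n_trees Ensemble size (default 500).
#' @param seed Integer seed.
#' @param case_level As in [wilcoxon_screen()].
#' @return Object of class `pod_model`.
#' @export
train_pod_model <- function(table, groups, markers, n_trees = 500,
                            seed = NULL, case_level = NULL) {
  if (inherits(markers, "marker_set")) markers <- markers$ranked_features
  markers <- as.character(markers)
  if (length(markers) == 0L) abort("no marker features given")
  m <- as_abundance(table, normalise = inherits(table, "otu_table"))
  missing <- setdiff(markers, colnames(m))
  if (length(missing) > 0L) {
    abort("markers absent from the table: %s", paste(missing, collapse = ", "))
  }
  groups <- as_group_factor(groups, n = nrow(m))
  if (any(base::table(groups) < 2L)) abort("each group needs at least 2 samples")
  case_level <- resolve_case_level(groups, case_level)
  control_level <- setdiff(levels(groups), case_level)
  rf <- with_seed(seed, randomForest::randomForest(
    x = m[, markers, drop = FALSE], y = groups, ntree = n_trees))
  structure(list(forest = rf, markers = markers, n_trees = n_trees,
                 case_level = case_level, control_level = control_level,
                 training_ids = rownames(m), seed = seed),
            class = "pod_model")
}

#' @export
print.pod_model <- function(x, ...) {
  cat(sprintf("POD model: %d-tree random forest on %d marker(s)\n",
              x$n_trees, length(x$markers)))
  cat("  markers:", paste(x$markers, collapse = ", "), "\n")
  cat(sprintf("  trained on %d samples (case level: '%s')\n",
              length(x$training_ids), x$case_level))
  invisible(x)
}

#' Save / load a POD model
#'
#' Serialises the fitted ensemble so that reloaded models produce identical
#' per-tree votes.
#'
#' @param model A `pod_model`.
#' @param path File path.
#' @return `save_pod_model` returns `path` invisibly; `load_pod_model`
#'   returns the `pod_model`.
#' @export
save_pod_model <- function(model, path) {
  stopifnot(inherits(model, "pod_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_pod_model
#' @export
load_pod_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "pod_model")) abort("%s does not contain a pod_model", path)
  model
}

#' Per-sample probability-of-disease (POD) index
#'
#' Scores each sample by the share of ensemble trees voting for the case
#' class: `pod = n_trees_case / (n_trees_case + n_trees_control)`.  The
#' literal case/control vote ratio (unbounded, `Inf` when no tree votes
#' control) is available with `type = "ratio"`; both orderings are
#' identical, so ROC results do not depend on the choice.
#'
#' @param model A `pod_model`.
#' @param table An `otu_table` or abundance matrix containing all marker
#'   features.
#' @param type `"fraction"` (default) or `"ratio"`.
#' @return Data.frame of class `pod_scores` with columns `sample_id`,
#'   `n_trees_case`, `n_trees_control`, `pod`.
#' @export
pod_index <- function(model, table, type = c("fraction", "ratio")) {
  stopifnot(inherits(model, "pod_model"))
  type <- match.arg(type)
  m <- as_abundance(table, normalise = inherits(table, "otu_table"))
  missing <- setdiff(model$markers, colnames(m))
  if (length(missing) > 0L) {
    abort("marker column(s) missing from the table: %s",
          paste(missing, collapse = ", "))
  }
  votes <- stats::predict(model$forest,
                          newdata = m[, model$markers, drop = FALSE],
                          type = "vote", norm.votes = FALSE)
  n_case <- votes[, model$case_level]
  n_control <- votes[, model$control_level]
  pod <- if (type == "fraction") n_case / (n_case + n_control)
         else n_case / n_control
  out <- data.frame(sample_id = rownames(m),
                    n_trees_case = as.integer(n_case),
                    n_trees_control = as.integer(n_control),
                    pod = pod, stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("pod_scores", "data.frame")
  out
}

#' ROC curve and AUC with confidence interval
#'
#' Empirical ROC over all distinct score thresholds (case = positive
#' class); the AUC equals the normalised Mann-Whitney statistic with ties
#' counted one half.  The 95% confidence interval uses DeLong's method by
#' default (the pROC default), or a seeded stratified bootstrap.
#'
#' @param scores Numeric scores (higher = more case-like), or a
#'   `pod_scores` data.frame (its `pod` column is used).
#' @param labels Two-level per-sample labels.
#' @param case_level As in [wilcoxon_screen()].
#' @param ci_method `"delong"` (default) or `"bootstrap"`.
#' @param n_boot Bootstrap resamples when `ci_method = "bootstrap"`.
#' @param seed Seed for the bootstrap CI.
#' @return Object of class `roc_result`: list with `thresholds`,
#'   `sensitivity`, `specificity`, `auc`, `ci_low`, `ci_high`, `n_case`,
#'   `n_control`, `ci_method`.
#' @export
roc_auc <- function(scores, labels, case_level = NULL,
                    ci_method = c("delong", "bootstrap"), n_boot = 2000,
                    seed = NULL) {
  ci_method <- match.arg(ci_method)
  if (inherits(scores, "pod_scores")) scores <- scores$pod
  labels <- as_group_factor(labels, n = length(scores))
  case_level <- resolve_case_level(labels, case_level)
  control_level <- setdiff(levels(labels), case_level)
  r <- pROC::roc(response = labels, predictor = scores,
                 levels = c(control_level, case_level), direction = "<",
                 quiet = TRUE)
  ci <- if (ci_method == "delong") {
    suppressWarnings(pROC::ci.auc(r, method = "delong"))
  } else {
    with_seed(seed, suppressWarnings(
      pROC::ci.auc(r, method = "bootstrap", boot.n = n_boot,
                   progress = "none")))
  }
  structure(list(thresholds = r$thresholds,
                 sensitivity = r$sensitivities,
                 specificity = r$specificities,
                 auc = as.numeric(pROC::auc(r)),
                 ci_low = max(0, as.numeric(ci[1L])),
                 ci_high = min(1, as.numeric(ci[3L])),
                 n_case = sum(labels == case_level),
                 n_control = sum(labels == control_level),
                 ci_method = ci_method),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC %.4f (95%% CI %.4f-%.4f, %s), %d cases vs %d controls\n",
              x$auc, x$ci_low, x$ci_high, x$ci_method, x$n_case, x$n_control))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  graphics::plot(1 - x$specificity, x$sensitivity, type = "l",
                 xlab = "1 - specificity", ylab = "Sensitivity",
                 xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Evaluate a POD model on held-out cohorts
#'
#' Scores and evaluates each cohort with the trained model; refuses any
#' cohort that shares sample ids with the training set (leakage guard).
#' The per-cohort result includes a two-sided Wilcoxon rank-sum p-value
#' comparing POD between groups.
#'
#' @param model A `pod_model`.
#' @param cohorts Named list; each element a list with `table` (an
#'   `otu_table`) and `groups` (labels) or `metadata` (a `sample_metadata`).
#' @return Named list; per cohort a list with `pod` (a `pod_scores`),
#'   `roc` (a `roc_result`) and `pod_group_p`.
#' @export
evaluate_cohorts <- function(model, cohorts) {
  stopifnot(inherits(model, "pod_model"))
  if (is.null(names(cohorts)) || any(!nzchar(names(cohorts)))) {
    abort("cohorts must be a named list")
  }
  lapply(cohorts, function(co) {
    table <- co$table
    groups <- if (!is.null(co$groups)) co$groups
              else align_metadata(table, co$metadata)$group
    overlap <- intersect(table$sample_ids, model$training_ids)
    if (length(overlap) > 0L) {
      abort("evaluation cohort shares %d sample id(s) with the training set (leakage): %s",
            length(overlap), paste(utils::head(overlap, 5L), collapse = ", "))
    }
    scores <- pod_index(model, table)
    groups <- as_group_factor(groups, n = nrow(scores))
    case <- resolve_case_level(groups, model$case_level)
    list(pod = scores,
         roc = roc_auc(scores$pod, groups, case_level = case),
         pod_group_p = wilcoxon_p(scores$pod[groups == case],
                                  scores$pod[groups != case]))
  })
}
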