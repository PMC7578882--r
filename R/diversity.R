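# Alpha diversity estimators and rarefaction curves.
#
# The estimators are implemented directly from their classical definitions
# (with explicit handling of the degenerate cases) and are cross-checked
# against vegan in the test suite.

#' Observed richness
#' @param counts Non-negative count vector for one sample.
#' @return Number of taxa with count > 0.
#' @export
observed_otus <- function(counts) {
  check_count_vector(counts, allow_zero_total = TRUE)
  sum(counts > 0)
}

#' Shannon diversity index
#'
#' H = -sum p_i log(p_i) over taxa with positive proportion p_i.  Natural
#' log by default (so a uniform community of S taxa has H = log(S)).
#'
#' @param counts Non-negative count (or abundance) vector.
#' @param base Logarithm base; `exp(1)` (default) or e.g. `2`.
#' @return Shannon entropy (>= 0).
#' @export
shannon <- function(counts, base = exp(1)) {
  check_count_vector(counts)
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p)) / log(base)
}

#' Bias-corrected Chao1 richness estimator
#'
#' S_chao1 = S_obs + F1 (F1 - 1) / (2 (F2 + 1)), where F1 and F2 are the
#' numbers of singletons and doubletons.  The bias-corrected form stays
#' finite when there are no doubletons.
#'
#' @param counts Non-negative integer count vector.
#' @return Estimated richness (>= observed richness).
#' @export
chao1 <- function(counts) {
  check_count_vector(counts, integer_only = TRUE)
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' ACE richness estimator
#'
#' Classical abundance-based coverage estimator: taxa with count >
#' `rare_threshold` are counted directly; the rare taxa are estimated
#' through the sample coverage C = 1 - F1 / N_rare and the squared
#' coefficient of variation of the rare abundances,
#' gamma^2 = max(S_rare / C * sum_i i (i - 1) F_i / (N_rare (N_rare - 1)) - 1, 0).
#' When the coverage is degenerate (C = 0, i.e. every rare taxon is a
#' singleton) the estimator falls back to the bias-corrected Chao1.
#'
#' @param counts Non-negative integer count vector.
#' @param rare_threshold Count at or below which a taxon is "rare"
#'   (default 10, the standard choice).
#' @return Estimated richness (>= observed richness).
#' @export
ace <- function(counts, rare_threshold = 10) {
  check_count_vector(counts, integer_only = TRUE)
  rare <- counts[counts > 0 & counts <= rare_threshold]
  s_abund <- sum(counts > rare_threshold)
  s_rare <- length(rare)
  if (s_rare == 0L) return(s_abund)
  n_rare <- sum(rare)
  f1 <- sum(rare == 1)
  c_ace <- 1 - f1 / n_rare
  if (c_ace == 0) return(chao1(counts))
  ivals <- seq_len(rare_threshold)
  fi <- vapply(ivals, function(i) sum(rare == i), numeric(1))
  gamma2 <- if (n_rare > 1) {
    max(s_rare / c_ace * sum(ivals * (ivals - 1) * fi) /
          (n_rare * (n_rare - 1)) - 1, 0)
  } else 0
  s_abund + s_rare / c_ace + f1 / c_ace * gamma2
}

check_count_vector <- function(x, integer_only = FALSE,
                               allow_zero_total = FALSE) {
  if (!is.numeric(x)) abort("counts must be numeric")
  if (anyNA(x) || any(x < 0)) abort("counts must be non-negative and non-missing")
  if (integer_only && any(x != round(x))) abort("counts must be integers")
  if (!allow_zero_total && sum(x) <= 0) abort("total count must be positive")
  invisible(x)
}

#' Per-sample alpha diversity
#'
#' Computes observed OTUs, Shannon, bias-corrected Chao1 and ACE for every
#' sample of an OTU table.
#'
#' @param table An `otu_table`.
#' @param rare_threshold ACE rare/abundant threshold (default 10).
#' @param base Logarithm base for Shannon.
#' @return A data.frame with columns `sample_id`, `observed_otus`,
#'   `shannon`, `chao1`, `ace`.
#' @export
alpha_diversity <- function(table, rare_threshold = 10, base = exp(1)) {
  stopifnot(inherits(table, "otu_table"))
  m <- table$counts
  data.frame(
    sample_id = table$sample_ids,
    observed_otus = apply(m, 1L, observed_otus),
    shannon = apply(m, 1L, shannon, base = base),
    chao1 = apply(m, 1L, chao1),
    ace = apply(m, 1L, ace, rare_threshold = rare_threshold),
    stringsAsFactors = FALSE
  )
}

#' Rarefaction curve
#'
#' Mean observed richness after repeated random subsampling to each depth,
#' averaged over samples (optionally within groups) and over `reps`
#' independent subsamples.  Samples shallower than a depth are excluded at
#' that depth.
#'
#' @param table An `otu_table`.
#' @param depths Increasing vector of positive integer depths.
#' @param reps Number of random subsamples per depth.
#' @param seed Integer seed.
#' @param groups Optional per-sample group labels; default one pooled group.
#' @return Data.frame with columns `depth`, `group`, `mean_observed_otus`,
#'   `n_samples`.
#' @export
rarefaction_curve <- function(table, depths, reps = 10, seed = NULL,
                              groups = NULL) {
  stopifnot(inherits(table, "otu_table"))
  if (length(depths) == 0L) abort("depths must be a non-empty vector")
  if (any(depths <= 0) || any(depths != round(depths)) ||
      is.unsorted(depths, strictly = TRUE)) {
    abort("depths must be strictly increasing positive integers")
  }
  tot <- sample_totals(table)
  if (min(depths) > max(tot)) abort("all depths exceed the deepest sample")
  if (is.null(groups)) groups <- rep("all", nrow(table$counts))
  groups <- factor(groups)
  with_seed(seed, {
    out <- lapply(depths, function(d) {
      keep <- tot >= d
      if (!any(keep)) return(NULL)
      obs <- matrix(0, reps, sum(keep))
      for (r in seq_len(reps)) {
        sub <- quiet_rrarefy(table$counts[keep, , drop = FALSE], d)
        obs[r, ] <- rowSums(sub > 0)
      }
      per_sample <- colMeans(obs)
      g <- droplevels(groups[keep])
      data.frame(depth = d, group = levels(g),
                 mean_observed_otus = as.numeric(tapply(per_sample, g, mean)),
                 n_samples = as.integer(base::table(g)),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
}
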