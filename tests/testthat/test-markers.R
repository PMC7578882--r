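# Importance ranking, the CV error curve, the minimum-error-plus-SD rule
# and the end-to-end marker discovery pipeline.

# build a cv_error_curve with exactly controlled per-size mean and SD
curve_from_moments <- function(sizes, means, sds) {
  spread <- c(-1, -0.5, 0, 0.5, 1)
  spread <- spread / stats::sd(spread)
  errors <- vapply(seq_along(sizes), function(i) means[i] + sds[i] * spread,
                   numeric(5))
  dimnames(errors) <- list(paste0("trial_", 1:5), paste0("size_", sizes))
  structure(list(feature_counts = as.integer(sizes), errors = errors,
                 mean_error = colMeans(errors),
                 sd_error = apply(errors, 2, stats::sd)),
            class = "cv_error_curve")
}

test_that("importance ranking finds a planted separating feature", {
  hits <- 0
  for (s in 1:40) {
    set.seed(700 + s)
    n <- 40
    g <- rep(c("case", "control"), each = n / 2)
    x <- matrix(rnorm(n * 21), n, 21,
                dimnames = list(NULL, c("signal", paste0("noise", 1:20))))
    x[, "signal"] <- x[, "signal"] + ifelse(g == "case", 3, 0)
    ranked <- rank_features_by_importance(x, g, n_trees = 200, seed = s)
    hits <- hits + (ranked[1] == "signal")
  }
  expect_gte(hits, 38)  # >= 95% of runs
})

test_that("importance ranking is deterministic and rejects one-class labels", {
  ab <- toy_abund(n_per = 6)
  r1 <- rank_features_by_importance(ab$abund, ab$groups, seed = 3)
  r2 <- rank_features_by_importance(ab$abund, ab$groups, seed = 3)
  expect_identical(r1, r2)
  expect_error(rank_features_by_importance(ab$abund, rep("case", 12)),
               "2 groups")
})

test_that("under permuted labels the true feature's importance rank is uniform", {
  set.seed(701)
  n <- 30
  x <- matrix(rnorm(n * 8), n, 8,
              dimnames = list(NULL, c("signal", paste0("n", 1:7))))
  base_g <- rep(c("case", "control"), each = n / 2)
  x[, "signal"] <- x[, "signal"] + ifelse(base_g == "case", 2, 0)
  ranks <- vapply(1:80, function(i) {
    g <- sample(base_g)   # break the label-feature link
    which(rank_features_by_importance(x, g, n_trees = 100,
                                      seed = 9000 + i) == "signal")
  }, integer(1))
  # chi-squared goodness of fit against the uniform distribution over 8 ranks
  gof <- suppressWarnings(stats::chisq.test(tabulate(ranks, nbins = 8),
                                            p = rep(1 / 8, 8)))
  expect_gt(gof$p.value, 0.01)
})

test_that("cv error curve is exact on separable data and bounded on noise", {
  set.seed(702)
  n <- 30
  g <- rep(c("case", "control"), each = n / 2)
  x <- cbind(perfect = ifelse(g == "case", 1, 0) + rnorm(n, 0, 1e-4),
             junk = rnorm(n))
  colnames(x) <- c("perfect", "junk")
  curve <- cv_error_curve(x, g, ranked = c("perfect", "junk"),
                          n_trials = 3, n_folds = 5, n_trees = 100, seed = 1)
  expect_true(all(curve$errors[, "size_1"] == 0))
  expect_true(all(curve$errors >= 0 & curve$errors <= 1))
  # chance level on pure noise (fresh noise per replicate)
  errs <- vapply(1:10, function(s) {
    set.seed(7000 + s)
    noise <- matrix(rnorm(n * 4), n, 4,
                    dimnames = list(NULL, paste0("f", 1:4)))
    cv <- cv_error_curve(noise, g, ranked = colnames(noise), n_trials = 2,
                         n_folds = 5, n_trees = 100, seed = s)
    mean(cv$mean_error)
  }, numeric(1))
  expect_lt(abs(mean(errs) - 0.5), 0.1)
  # leave-one-out on separable data agrees with the exhaustive answer: zero
  loo <- cv_error_curve(x, g, ranked = "perfect", n_trials = 1, n_folds = 15,
                        n_trees = 100, seed = 2, sizes = 1L)
  expect_equal(unname(loo$mean_error), 0)
  expect_error(cv_error_curve(x, g, ranked = "perfect", n_folds = 50),
               "reduce n_folds")
})

test_that("the minimum-error-plus-SD rule picks the smallest adequate size", {
  curve <- curve_from_moments(1:4, c(0.30, 0.10, 0.09, 0.10),
                              c(0, 0.03, 0.02, 0.05))
  ms <- select_optimal_markers(curve, ranked = paste0("f", 1:4))
  expect_equal(ms$min_error, 0.09)
  expect_equal(ms$sd_at_min, 0.02)
  expect_equal(ms$cutoff, 0.11)
  expect_identical(ms$candidate_sizes, c(2L, 3L, 4L))
  expect_identical(ms$chosen_size, 2L)
  expect_identical(ms$ranked_features, c("f1", "f2"))
})

test_that("degenerate curves and trial order do not break selection", {
  # all equal with zero SD: the <= relaxation keeps size 1
  flat <- curve_from_moments(1:3, rep(0.2, 3), rep(0, 3))
  expect_identical(select_optimal_markers(flat)$chosen_size, 1L)
  # ties at the minimum resolve to the smallest size
  tie <- curve_from_moments(1:3, c(0.3, 0.1, 0.1), c(0, 0.02, 0.01))
  expect_equal(select_optimal_markers(tie)$sd_at_min, 0.02)
  # permuting the trial rows changes nothing (depends only on mean/SD)
  curve <- curve_from_moments(1:4, c(0.30, 0.10, 0.09, 0.10),
                              c(0, 0.03, 0.02, 0.05))
  shuffled <- curve
  shuffled$errors <- shuffled$errors[c(4, 2, 5, 1, 3), ]
  shuffled$mean_error <- colMeans(shuffled$errors)
  shuffled$sd_error <- apply(shuffled$errors, 2, stats::sd)
  expect_identical(select_optimal_markers(curve)$chosen_size,
                   select_optimal_markers(shuffled)$chosen_size)
})

test_that("marker discovery on the worked example is pinned and deterministic", {
  co <- spike_worked_example()
  ms <- discover_markers(co$table, co$metadata, seed = 1)
  # regression-pinned behaviour of the frozen fixture
  expect_identical(ms$chosen_size, 3L)
  expect_identical(sort(ms$ranked_features),
                   c("OTU_0004", "OTU_0017", "OTU_0030"))
  expect_true(all(ms$ranked_features %in% co$truth$diff_otu_ids))
  expect_equal(ms$min_error, 0.09)
  ms2 <- discover_markers(co$table, co$metadata, seed = 1)
  expect_identical(ms$ranked_features, ms2$ranked_features)
  expect_identical(ms$curve$errors, ms2$curve$errors)
})

test_that("discovery fails loudly when the screen selects nothing", {
  co <- generate_cohort(synthetic_spec(n_case = 6, n_control = 6,
                                       n_otus = 8, n_diff = 0, seed = 2))
  expect_error(discover_markers(co$table, co$metadata, screen_alpha = 1e-6,
                                seed = 1),
               "selected no features")
})
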