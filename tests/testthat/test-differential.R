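# Wilcoxon screen, Kruskal-Wallis, taxonomy aggregation and the
# linear-discriminant effect size.

test_that("wilcoxon screen handles exact, degenerate and tied cases", {
  ab <- cbind(sep = c(1, 2, 3, 4, 5, 6), const = rep(2, 6))
  g <- c("case", "case", "case", "control", "control", "control")
  res <- wilcoxon_screen(ab, g, alpha = 0.05)
  # complete separation of 3 vs 3: exact two-sided p = 2/choose(6,3)*... = 0.1
  expect_equal(res$p_value[res$feature_id == "sep"], 0.1)
  expect_false(res$selected[res$feature_id == "sep"])
  expect_equal(res$p_value[res$feature_id == "const"], 1)
  expect_identical(res$direction[res$feature_id == "const"], "none")
})

test_that("wilcoxon screen is invariant under monotone transforms", {
  set.seed(601)
  ab <- matrix(rlnorm(80), 20, 4, dimnames = list(NULL, paste0("f", 1:4)))
  g <- rep(c("case", "control"), 10)
  p1 <- wilcoxon_screen(ab, g)$p_value
  p2 <- wilcoxon_screen(log(ab + 1), g)$p_value
  p3 <- wilcoxon_screen(ab^3, g)$p_value
  expect_equal(p1, p2, tolerance = 1e-12)
  expect_equal(p1, p3, tolerance = 1e-12)
})

test_that("wilcoxon screen is powerful on planted effects and reports direction", {
  frac <- vapply(1:20, function(s) {
    co <- generate_cohort(synthetic_spec(log2_fold_change = 3,
                                         seed = 9000 + s))
    scr <- wilcoxon_screen(relative_abundance(co$table), co$metadata$group)
    mean(scr$selected[match(co$truth$diff_otu_ids, scr$feature_id)])
  }, numeric(1))
  expect_gte(mean(frac), 0.9)
})

test_that("screen power increases with the planted fold change", {
  power_at <- function(lfc) {
    mean(vapply(1:8, function(s) {
      co <- generate_cohort(synthetic_spec(log2_fold_change = lfc,
                                           seed = 9600 + s))
      scr <- wilcoxon_screen(relative_abundance(co$table), co$metadata$group)
      mean(scr$selected[match(co$truth$diff_otu_ids, scr$feature_id)])
    }, numeric(1)))
  }
  p <- vapply(c(0.5, 3), power_at, numeric(1))
  expect_gt(p[2], p[1])
})

test_that("kruskal-wallis matches its formula and collapses to wilcoxon for k = 2", {
  set.seed(602)
  for (i in 1:20) {
    v <- c(rnorm(5), rnorm(6, 1), rnorm(4, 2))
    g <- rep(c("a", "b", "c"), c(5, 6, 4))
    expect_equal(kruskal_wallis(v, g), kruskal_bf(v, g), tolerance = 1e-9)
    # two-group equivalence with the tie-corrected normal approximation
    v2 <- round(c(rnorm(8), rnorm(8, 0.5)), 1)  # rounding induces ties
    g2 <- rep(c("a", "b"), each = 8)
    pw <- suppressWarnings(stats::wilcox.test(v2[g2 == "a"], v2[g2 == "b"],
                                              exact = FALSE,
                                              correct = FALSE)$p.value)
    expect_equal(kruskal_wallis(v2, g2), pw, tolerance = 1e-9)
  }
  expect_equal(kruskal_wallis(rep(3, 9), rep(c("a", "b", "c"), 3)), 1)
  expect_error(kruskal_wallis(1:4, factor(c("a", "a", "a", "a"))), "2")
})

test_that("taxonomy aggregation conserves counts and matches group-by sums", {
  co <- spike_worked_example()
  set.seed(603)
  genera <- sample(paste0("g", 1:6), 30, replace = TRUE)
  tax <- taxonomy_map(data.frame(otu_id = co$table$otu_ids,
                                 phylum = "Firmicutes", genus = genera))
  agg <- aggregate_taxa(co$table, tax, "genus")
  expect_equal(sample_totals(agg), sample_totals(co$table))
  for (g in unique(genera)) {
    expect_equal(agg$counts[, g],
                 rowSums(co$table$counts[, genera == g, drop = FALSE]))
  }
  # all OTUs in one genus collapse to the row totals
  tax1 <- taxonomy_map(data.frame(otu_id = co$table$otu_ids,
                                  genus = "Blautia"))
  agg1 <- aggregate_taxa(co$table, tax1, "genus")
  expect_equal(unname(agg1$counts[, "Blautia"]),
               unname(sample_totals(co$table)))
  # unassigned at rank pools under the parent
  tax2 <- taxonomy_map(data.frame(otu_id = co$table$otu_ids,
                                  phylum = "Bacteroidota",
                                  genus = NA_character_))
  agg2 <- aggregate_taxa(co$table, tax2, "genus")
  expect_identical(colnames(agg2$counts), "Bacteroidota_norank")
  expect_error(aggregate_taxa(co$table, tax, "species"), "not present")
})

test_that("lda effect size scores planted effects and respects its thresholds", {
  # equal group means: score floored below the cutoff, no pass
  ab <- toy_abund(n_per = 8, shift = 0)
  r0 <- lda_effect_size(ab$abund, ab$groups, seed = 1)
  expect_true(all(!r0$passes))
  # huge scaled separation with tiny variance passes toward the case group
  set.seed(604)
  big <- cbind(marker = c(rnorm(8, 0.10, 0.001), rnorm(8, 0.001, 0.0005)),
               rest = 1)
  big <- pmax(big, 1e-6)
  g <- rep(c("case", "control"), each = 8)
  r1 <- lda_effect_size(big / rowSums(big), g, seed = 2)
  row1 <- r1[r1$feature_id == "marker", ]
  expect_true(row1$passes)
  expect_identical(row1$enriched_group, "case")
  expect_gt(row1$lda_score_log10, 4)  # ~1e5-scale scaled-unit difference
  # a zero-variance feature scores 0 and never passes
  flat <- cbind(flat = rep(0.5, 16), other = rep(0.5, 16))
  r2 <- lda_effect_size(flat, g, seed = 3)
  expect_true(all(r2$lda_score_log10 == 0))
  expect_true(all(!r2$passes))
  # deterministic given the seed
  expect_identical(lda_effect_size(big / rowSums(big), g, seed = 9),
                   lda_effect_size(big / rowSums(big), g, seed = 9))
})

test_that("lda effect size is symmetric under label exchange on null data", {
  co <- generate_cohort(synthetic_spec(n_case = 15, n_control = 15,
                                       n_otus = 20, n_diff = 0, seed = 31))
  rel <- relative_abundance(co$table)
  obs <- lda_effect_size(rel, co$metadata$group, seed = 5)
  perm_means <- vapply(1:30, function(i) {
    set.seed(100 + i)
    g <- sample(co$metadata$group)
    mean(lda_effect_size(rel, g, seed = 5)$lda_score_log10)
  }, numeric(1))
  # observed mean score sits inside the permutation distribution
  expect_gt(mean(obs$lda_score_log10), min(perm_means) - 0.5)
  expect_lt(mean(obs$lda_score_log10), max(perm_means) + 0.5)
})
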