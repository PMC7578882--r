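# Generator: determinism, structural invariants, planted-effect moments,
# sparsity calibration and the fixed worked example.

test_that("identical specs generate bit-identical cohorts", {
  spec <- synthetic_spec(n_case = 8, n_control = 8, n_otus = 25, seed = 42)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a$table$counts, b$table$counts)
  expect_identical(a$metadata, b$metadata)
  expect_identical(a$truth, b$truth)
  # a different seed changes the draw
  expect_false(identical(a$table$counts,
                         generate_cohort(spec, seed = 43)$table$counts))
})

test_that("row totals equal the drawn library sizes and counts are integral", {
  co <- generate_cohort(synthetic_spec(n_case = 10, n_control = 10,
                                       n_otus = 40, seed = 3))
  expect_true(is.integer(co$table$counts))
  expect_true(all(co$table$counts >= 0))
  # totals are whole library sizes, not deflated by the zero-inflation step
  expect_true(all(sample_totals(co$table) >= 50))
})

test_that("ground truth matches the spec and lives in the table", {
  co <- generate_cohort(synthetic_spec(n_diff = 5, seed = 9))
  expect_length(co$truth$diff_otu_ids, 5)
  expect_true(all(co$truth$diff_otu_ids %in% co$table$otu_ids))
  expect_setequal(unique(co$truth$direction),
                  c("enriched_case", "enriched_control"))
  null <- generate_cohort(synthetic_spec(n_diff = 0, seed = 9))
  expect_length(null$truth$diff_otu_ids, 0)
})

test_that("planted fold change is realised in the sampled abundances", {
  num <- den <- numeric(0)
  for (s in 1:60) {
    co <- generate_cohort(synthetic_spec(log2_fold_change = 3,
                                         seed = 5000 + s))
    rel <- relative_abundance(co$table)
    g <- co$metadata$group
    ids <- co$truth$diff_otu_ids
    up <- co$truth$direction[ids] == "enriched_case"
    ca <- colMeans(rel[g == "case", ids, drop = FALSE])
    ct <- colMeans(rel[g == "control", ids, drop = FALSE])
    num <- c(num, ca[up], ct[!up])
    den <- c(den, ct[up], ca[!up])
  }
  ratio <- sum(num) / sum(den)   # pooled over seeds: enriched over depleted side
  expect_gt(ratio, 2^2.5)
  expect_lt(ratio, 2^3.5)
})

test_that("marginal zero fraction tracks the sparsity target", {
  spec <- synthetic_spec()
  zf <- vapply(1:20, function(s) {
    mean(generate_cohort(synthetic_spec(seed = 7000 + s))$table$counts == 0)
  }, numeric(1))
  expect_lt(abs(mean(zf) - synthetic_spec()$sparsity), 0.05)
})

test_that("clinical indicators shift by group in the stated direction", {
  co <- generate_cohort(synthetic_spec(seed = 77))
  meta <- co$metadata
  is_case <- meta$group == "case"
  expect_gt(mean(meta$SCr[is_case]), mean(meta$SCr[!is_case]))
  expect_lt(mean(meta$eGFR[is_case]), mean(meta$eGFR[!is_case]))
})

test_that("an infeasible sparsity target is diagnosed", {
  spec <- synthetic_spec(sparsity = 0.05)
  expect_error(generate_cohort(spec, seed = 1), "infeasible sparsity")
})

test_that("the worked example is fixed, small and has 5 planted markers", {
  a <- spike_worked_example()
  b <- spike_worked_example()
  expect_identical(a$table$counts, b$table$counts)
  expect_identical(dim(a$table$counts), c(20L, 30L))
  expect_length(a$truth$diff_otu_ids, 5)
  expect_identical(a$truth$diff_otu_ids,
                   c("OTU_0003", "OTU_0004", "OTU_0017", "OTU_0026",
                     "OTU_0030"))
})

test_that("a null generator keeps the Wilcoxon screen near its nominal level", {
  rates <- vapply(1:60, function(s) {
    co <- generate_cohort(synthetic_spec(n_case = 20, n_control = 20,
                                         n_otus = 50, n_diff = 0,
                                         seed = 8000 + s))
    scr <- wilcoxon_screen(relative_abundance(co$table), co$metadata$group)
    mean(scr$selected)
  }, numeric(1))
  se <- stats::sd(rates) / sqrt(length(rates))
  expect_lt(abs(mean(rates) - 0.05), max(3 * se, 0.015))
})

test_that("cohort draws from one spec share the population ground truth", {
  spec <- synthetic_spec(seed = 55)
  a <- generate_cohort(spec, "discovery", seed = 1)
  b <- generate_cohort(spec, "validation", seed = 2)
  expect_identical(a$truth$diff_otu_ids, b$truth$diff_otu_ids)
  expect_identical(a$truth$direction, b$truth$direction)
  expect_false(identical(unname(a$table$counts), unname(b$table$counts)))
})
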