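# OTU-table construction, file round trips, normalisation and rarefaction.

test_that("otu_table validates counts and identifiers", {
  m <- matrix(c(5L, 0L, 2L, 9L), 2, 2,
              dimnames = list(c("s1", "s2"), c("o1", "o2")))
  tab <- otu_table(m)
  expect_identical(tab$counts, m)
  expect_error(otu_table(matrix(c(1, -3), 1, 2)), "non-negative")
  expect_error(otu_table(matrix(c(1, 2.5), 1, 2)), "non-negative integers")
  expect_error(otu_table(m, sample_ids = c("a", "a")), "duplicated sample")
  expect_error(otu_table(m, otu_ids = c("x", "x", "y")), "does not match")
})

test_that("a minimal one-cell TSV parses losslessly", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#OTU ID\tsampleA", "OTU_1\t7"), f)
  tab <- read_otu_table(f)
  expect_identical(unname(tab$counts), matrix(7L, 1, 1))
  expect_identical(tab$sample_ids, "sampleA")
  expect_identical(tab$otu_ids, "OTU_1")
})

test_that("negative or non-numeric cells are rejected with their location", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#OTU ID\ts1\ts2", "OTU_1\t4\t-3"), f)
  expect_error(read_otu_table(f), "OTU_1.*s2|s2.*OTU_1")
  writeLines(c("#OTU ID\ts1", "OTU_1\tseven"), f)
  expect_error(read_otu_table(f), "non-numeric")
})

test_that("write/read round trips are the identity in both formats and orientations", {
  set.seed(301)
  m <- matrix(rpois(12, 8), 3, 4,
              dimnames = list(paste0("s", 1:3), paste0("OTU_", 1:4)))
  tab <- otu_table(m)
  for (fmt in c("tsv", "biom-json")) {
    f <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_otu_table(tab, f, format = fmt)
    back <- read_otu_table(f, format = fmt)
    expect_identical(back$counts[tab$sample_ids, tab$otu_ids], tab$counts,
                     info = fmt)
  }
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_otu_table(tab, f2, samples_in = "rows")
  back2 <- read_otu_table(f2, samples_in = "rows")
  expect_identical(back2$counts, tab$counts)
})

test_that("an empty-sample table writes a header-only TSV", {
  tab <- otu_table(matrix(integer(0), 0, 2,
                          dimnames = list(NULL, c("o1", "o2"))))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_otu_table(tab, f, samples_in = "rows")
  expect_identical(readLines(f), "#Sample ID\to1\to2")
})

test_that("relative abundance rows sum to one with no pseudocount", {
  expect_equal(unname(relative_abundance(otu_table(matrix(c(2L, 2L), 1)))[1, ]),
               c(0.5, 0.5))
  expect_equal(unname(relative_abundance(otu_table(matrix(c(1L, 0L, 3L), 1)))[1, ]),
               c(0.25, 0, 0.75))
  set.seed(302)
  tab <- otu_table(matrix(rpois(40, 5) + 1L, 5, 8))
  expect_true(all(abs(rowSums(relative_abundance(tab)) - 1) < 1e-12))
  zero <- otu_table(matrix(c(0L, 0L, 3L, 4L), 2, 2, byrow = TRUE,
                           dimnames = list(c("empty", "ok"), NULL)))
  expect_error(relative_abundance(zero), "empty")
})

test_that("rarefaction is exact at the depth, preserves zeros, and is seeded", {
  tab <- otu_table(matrix(c(1000L, 0L, 500L, 500L), 2, 2, byrow = TRUE,
                          dimnames = list(c("a", "b"), c("o1", "o2"))))
  r <- rarefy(tab, depth = 100, seed = 1)
  expect_true(all(sample_totals(r) == 100))
  expect_identical(unname(r$counts["a", ]), c(100L, 0L))
  expect_identical(rarefy(tab, depth = 100, seed = 7)$counts,
                   rarefy(tab, depth = 100, seed = 7)$counts)
  expect_error(rarefy(tab, depth = 0), "positive integer")
  # sample at exactly the depth is unchanged
  expect_identical(rarefy(tab, depth = 1000, seed = 3)$counts["a", ],
                   tab$counts["a", ])
  # shallow samples are dropped with a warning naming them
  tab2 <- otu_table(matrix(c(10L, 5L, 200L, 100L), 2, 2, byrow = TRUE,
                           dimnames = list(c("shallow", "deep"), NULL)))
  expect_warning(r2 <- rarefy(tab2, depth = 50, seed = 1), "shallow")
  expect_identical(rownames(r2$counts), "deep")
})

test_that("rarefied counts match hypergeometric expectation and never exceed the original", {
  tab <- otu_table(matrix(c(900L, 100L), 1, 2,
                          dimnames = list("s", c("big", "small"))))
  draws <- vapply(1:1000, function(s) {
    rarefy(tab, depth = 100, seed = s)$counts[1, "small"]
  }, integer(1))
  # hypergeometric mean 10, var 100*0.1*0.9*(900/999)
  se <- sqrt(100 * 0.1 * 0.9 * (900 / 999) / 1000)
  expect_lt(abs(mean(draws) - 10), 3 * se)
  set.seed(303)
  tab3 <- otu_table(matrix(rpois(30, 20), 3, 10))
  r3 <- rarefy(tab3, depth = min(sample_totals(tab3)), seed = 4)
  expect_true(all(r3$counts <= tab3$counts))
  expect_true(all(r3$counts[tab3$counts == 0] == 0))
})
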