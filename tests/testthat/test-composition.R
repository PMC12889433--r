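toy_cells <- function(n_ad, n_total, clusters) {
  purrr::map2_dfr(seq_along(n_ad), clusters, function(i, cl) {
    tibble::tibble(
      cluster = cl,
      condition = c(rep("AD", n_ad[i]), rep("healthy", n_total[i] - n_ad[i]))
    )
  })
}

test_that("cluster enrichment matches the hand-evaluated worked example", {
  cells <- toy_cells(c(5, 5), c(10, 20), c("A", "B"))
  res <- cluster_enrichment(cells)
  expect_equal(res$naive_score, c(0.5, 0.25))
  expect_equal(res$normalized_score, c(4 / 3, 2 / 3), tolerance = 1e-12)
})

test_that("normalized enrichment scores always average to one", {
  for (s in 1:5) {
    cells <- gen_cell_table(small_cohort_config(s))$cells
    res <- cluster_enrichment(cells)
    expect_equal(mean(res$normalized_score), 1, tolerance = 1e-9)
  }
})

test_that("identical AD fractions normalise to 1 and empty clusters to 0", {
  cells <- toy_cells(c(3, 6), c(6, 12), c("A", "B"))
  expect_true(all(cluster_enrichment(cells)$normalized_score == 1))
  cells2 <- toy_cells(c(0, 6), c(6, 12), c("A", "B"))
  res2 <- cluster_enrichment(cells2)
  expect_equal(res2$normalized_score[res2$cluster == "A"], 0)
})

test_that("enrichment normalization is undefined when no cells match", {
  cells <- toy_cells(c(0, 0), c(5, 5), c("A", "B"))
  expect_error(cluster_enrichment(cells), "normalization undefined")
})

test_that("bam_ratio_score evaluates, bounds and reciprocates correctly", {
  expect_identical(bam_ratio_score(7, 7, 100), 1)
  expect_equal(bam_ratio_score(10, 5, 100), exp(0.05), tolerance = 1e-12)
  expect_equal(bam_ratio_score(0, 10, 50), exp(-0.2), tolerance = 1e-12)
  expect_error(bam_ratio_score(1, 1, 0), "positive")
  expect_error(bam_ratio_score(10, 2, 5), "at least")
  # reciprocity and bounds over random counts
  set.seed(1)
  for (i in 1:50) {
    n <- sample(10:500, 1)
    a <- sample(0:n, 1); b <- sample(0:(n - a), 1)
    s <- bam_ratio_score(a, b, n)
    expect_equal(s * bam_ratio_score(b, a, n), 1, tolerance = 1e-12)
    expect_gte(s, exp(-1)); expect_lte(s, exp(1))
  }
})

test_that("patient filter respects the inclusive 0.1% boundary and is idempotent", {
  cells <- tibble::tibble(
    patient_id = c(rep("below", 2000), rep("above", 1000), rep("exact", 1000)),
    cluster = c("mac", rep("other", 1999),             # 0.05%
                rep("mac", 5), rep("other", 995),      # 0.5%
                "mac", rep("other", 999))              # exactly 0.1%
  )
  kept <- filter_patients(cells, "mac")
  expect_setequal(unique(kept$patient_id), c("above", "exact"))
  expect_identical(filter_patients(kept, "mac"), kept)
  expect_error(filter_patients(cells, character(0)), "non-empty")
  expect_error(filter_patients(cells, "mac", min_fraction = 0), "0, 1")
})

test_that("signature_ratio assigns clusters by their elevated program", {
  set.seed(42)
  genes <- sprintf("g%02d", 1:40)
  expr <- matrix(rexp(40 * 60), 40, 60, dimnames = list(genes, NULL))
  clusters <- rep(c("c1", "c2"), each = 30)
  set_a <- genes[1:5]; set_b <- genes[6:10]
  expr[set_a, clusters == "c1"] <- expr[set_a, clusters == "c1"] * 2
  res <- signature_ratio(expr, clusters, set_a, set_b, seed = 7)
  expect_identical(res$assignment[res$cluster == "c1"], "set_a")

  # identical sets tie exactly; all-zero expression ties exactly
  res_same <- signature_ratio(expr, clusters, set_a, set_a, seed = 7)
  expect_true(all(res_same$ratio == 1))
  expect_true(all(res_same$assignment == "tie"))
  res_zero <- signature_ratio(matrix(0, 40, 60, dimnames = list(genes, NULL)),
                              clusters, set_a, set_b, seed = 7)
  expect_true(all(res_zero$ratio == 1))
  expect_true(all(res_zero$assignment == "tie"))

  expect_error(signature_ratio(expr, clusters, c("nope", set_a), set_b),
               "nope")
})

test_that("Hampel flags follow the median/MAD rule and its edge cases", {
  d <- c(a = 0, b = 0, c = 0, d = 0, e = 10)
  res <- gwas_delta_flags(d, k = 3)
  expect_identical(res$flag, c("none", "none", "none", "none", "enriched"))

  expect_true(all(gwas_delta_flags(c(a = 2, b = 2, c = 2))$flag == "none"))
  expect_error(gwas_delta_flags(c(a = 1, b = 2)), "at least 3")

  set.seed(3)
  x <- setNames(rnorm(18), paste0("c", 1:18))
  base <- gwas_delta_flags(x, k = 3)
  shifted <- gwas_delta_flags(x + 5, k = 3)
  expect_identical(base$flag, shifted$flag)
  mirrored <- gwas_delta_flags(-x, k = 3)
  expect_identical(
    base$flag,
    dplyr::recode(mirrored$flag, enriched = "depleted", depleted = "enriched")
  )
})

test_that("standard-normal deltas at k = 3 are rarely flagged", {
  set.seed(11)
  n_flagged <- replicate(200, {
    sum(gwas_delta_flags(rnorm(18), k = 3)$flag != "none")
  })
  # k = 3 corresponds to ~0.27% per cluster if the MAD were exact; small-n
  # MAD noise inflates this, but most draws must still flag nothing
  expect_gt(mean(n_flagged == 0), 0.6)
  expect_lt(mean(n_flagged), 1)
})
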