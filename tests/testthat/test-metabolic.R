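test_that("pseudobulk partitions strata into full groups and drops the rest", {
  m <- matrix(seq_len(2 * 25), 2, 25,
              dimnames = list(c("f1", "f2"), sprintf("c%02d", 1:25)))
  expect_warning(
    pb <- pseudobulk(cbind(m, matrix(1, 2, 3, dimnames = list(NULL, c("x1", "x2", "x3")))),
                     c(rep("big", 25), rep("tiny", 3)), group_size = 10, seed = 1),
    "tiny")
  expect_equal(ncol(pb$values), 2L)
  expect_equal(sum(is.na(pb$membership$metacell)), 5L + 3L)
  # metacell values are sums over exactly 10 member cells
  mem <- pb$membership[!is.na(pb$membership$metacell), ]
  for (id in unique(mem$metacell)) {
    cells <- mem$cell[mem$metacell == id]
    expect_length(cells, 10L)
    expect_equal(pb$values[, id], rowSums(m[, cells]))
  }
})

test_that("group size 1 is an order-permuted identity and seeds reproduce", {
  m <- matrix(rnorm(3 * 8), 3, 8, dimnames = list(NULL, paste0("c", 1:8)))
  pb <- pseudobulk(m, rep("s", 8), group_size = 1, seed = 2)
  expect_equal(ncol(pb$values), 8L)
  expect_equal(sort(unname(colSums(pb$values))), sort(unname(colSums(m))))
  # each metacell is exactly one original cell
  mem <- pb$membership
  for (k in seq_len(nrow(mem))) {
    expect_equal(unname(pb$values[, mem$metacell[k]]), unname(m[, mem$cell[k]]))
  }
  pb2 <- pseudobulk(m, rep("s", 8), group_size = 1, seed = 2)
  expect_identical(pb$membership, pb2$membership)
})

test_that("penalty_to_flux implements -log1p with min-fix and z-scoring", {
  expect_equal(penalty_to_flux(matrix(0, 1, 3), min_fix = FALSE,
                               zscore = FALSE)$values[1, ], rep(0, 3))
  raw <- penalty_to_flux(matrix(c(0, exp(1) - 1), 1, 2), min_fix = FALSE,
                         zscore = FALSE)$values
  expect_equal(raw[1, 2], -1, tolerance = 1e-12)

  set.seed(4)
  pen <- matrix(rexp(50 * 20), 50, 20)
  fx <- penalty_to_flux(pen)
  expect_equal(unname(rowMeans(fx$values)), rep(0, 50), tolerance = 1e-9)
  expect_equal(unname(apply(fx$values, 1, sd)), rep(1, 50), tolerance = 1e-9)
  expect_error(penalty_to_flux(matrix(-1, 1, 1)), "non-negative")
})

test_that("min-fix is provably inconsequential after z-scoring", {
  set.seed(5)
  pen <- matrix(rexp(40 * 15), 40, 15)
  with_fix <- penalty_to_flux(pen, min_fix = TRUE)$values
  without_fix <- penalty_to_flux(pen, min_fix = FALSE)$values
  expect_equal(with_fix, without_fix, tolerance = 1e-12)
})

test_that("raw flux is monotone decreasing in penalty; constant rows flagged", {
  p <- seq(0, 5, by = 0.5)
  raw <- penalty_to_flux(matrix(p, 1), min_fix = FALSE, zscore = FALSE)$values
  expect_true(all(diff(raw[1, ]) < 0))
  fx <- penalty_to_flux(rbind(const = rep(2, 5), vary = 1:5))
  expect_identical(unname(fx$constant), c(TRUE, FALSE))
  expect_true(all(fx$values["const", ] == 0))
})

test_that("Cohen's d matches the hand example and its invariances", {
  m <- matrix(c(0, 2, 1, 3), 1, 4, dimnames = list("r1", paste0("s", 1:4)))
  eff <- reaction_effects(m, c("s1", "s2"), c("s3", "s4"))
  expect_equal(eff$cohen_d, -1 / sqrt(2), tolerance = 1e-12)

  set.seed(6)
  m2 <- matrix(rnorm(10 * 12), 10, 12, dimnames = list(NULL, paste0("s", 1:12)))
  ga <- paste0("s", 1:6); gb <- paste0("s", 7:12)
  base <- reaction_effects(m2, ga, gb)
  swapped <- reaction_effects(m2, gb, ga)
  expect_equal(swapped$cohen_d, -base$cohen_d)
  expect_equal(swapped$p, base$p)
  scaled <- reaction_effects(3.7 * m2 + 2, ga, gb)
  expect_equal(scaled$cohen_d, base$cohen_d, tolerance = 1e-12)

  ident <- reaction_effects(cbind(m2[, 1:6], m2[, 1:6],
                                  deparse.level = 0)[, , drop = FALSE],
                            1:6, 7:12)
  expect_true(all(ident$cohen_d == 0))
  expect_true(all(base$p_adj >= base$p))
})

test_that("zero pooled SD with unequal means yields a flagged infinity", {
  m <- rbind(c(1, 1, 2, 2))
  colnames(m) <- paste0("s", 1:4)
  expect_warning(eff <- reaction_effects(m, c("s1", "s2"), c("s3", "s4")),
                 "infinity")
  expect_identical(eff$cohen_d, -Inf)
})

test_that("subsystem summaries apply the size and threshold rules", {
  eff <- tibble::tibble(
    reaction_id = paste0("r", 1:8),
    cohen_d = c(0.2, 0.3, 0.4, 0.05, -0.05, 0.02, 1, -1),
    p = rep(0.01, 8), p_adj = rep(0.05, 8), n_a = 10, n_b = 10
  )
  map <- tibble::tibble(reaction_id = paste0("r", 1:8),
                        subsystem = c("up", "up", "up", "null", "null", "null",
                                      "small", "small"))
  ss <- subsystem_summarize(eff, map)
  expect_setequal(ss$subsystem, c("up", "null"))  # "small" has 2 reactions
  expect_equal(attr(ss, "n_excluded"), 1L)
  expect_equal(ss$median_d[ss$subsystem == "up"], 0.3)
  expect_true(ss$enriched[ss$subsystem == "up"])
  expect_identical(ss$direction[ss$subsystem == "up"], 1)
  expect_equal(ss$median_d[ss$subsystem == "null"], 0.02)
  expect_false(ss$enriched[ss$subsystem == "null"])
  expect_error(subsystem_summarize(eff, map[1:3, ]), "without subsystem")
})

test_that("transition distances match geometry and the brute-force loop", {
  m <- matrix(c(0, 0, 3, 4), 2, 2)
  td <- transition_distance(m, c("healthy", "AD"))
  expect_equal(td$distances$distance, 5)
  m2 <- matrix(rnorm(6), 6, 1)
  td2 <- transition_distance(cbind(m2, m2), c("healthy", "AD"))
  expect_equal(td2$distances$distance, 0)

  set.seed(7)
  for (i in 1:5) {
    x <- matrix(rnorm(50 * 20), 50, 20)
    labs <- rep(c("healthy", "AD"), each = 10)
    td3 <- transition_distance(x, labs)
    oracle <- loop_distances(x[, 1:10], x[, 11:20])
    expect_equal(sort(td3$distances$distance), sort(as.vector(oracle)),
                 tolerance = 1e-8)
  }
  expect_error(transition_distance(x, rep("healthy", 20)), "lacks")
})

test_that("distances are symmetric in group order and obey the triangle inequality", {
  set.seed(8)
  x <- matrix(rnorm(10 * 9), 10, 9)
  labs <- rep(c("healthy", "AD"), c(4, 5))
  a <- transition_distance(x, labs)
  b <- transition_distance(x, labs, conditions = c("AD", "healthy"))
  expect_equal(sort(a$distances$distance), sort(b$distances$distance))
  # triangle inequality on sampled triples of the expansion-based distances
  D <- bamscape:::cross_distances(x, x)
  for (i in 1:30) {
    tri <- sample(9, 3)
    expect_lte(D[tri[1], tri[2]],
               D[tri[1], tri[3]] + D[tri[3], tri[2]] + 1e-12)
  }
})
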