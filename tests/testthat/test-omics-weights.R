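test_that("identical samples get unit size factors", {
  counts <- matrix(c(5, 9, 3, 5, 9, 3), ncol = 2,
                   dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  norm <- median_of_ratios(counts)
  expect_equal(unname(norm$size_factors), c(1, 1))
})

test_that("the two-by-two example recovers hand-computed factors", {
  counts <- matrix(c(2, 8, 4, 16), ncol = 2,
                   dimnames = list(c("g1", "g2"), c("s1", "s2")))
  norm <- median_of_ratios(counts)
  # geometric means are sqrt(8) and sqrt(128); the column ratios are
  # 1/sqrt(2) and sqrt(2)
  expect_equal(unname(norm$size_factors), c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-12)
  mat <- as.matrix(norm$normalized[, -1])
  expect_equal(mat[, 1], mat[, 2], ignore_attr = TRUE)
})

test_that("normalization is equivariant to per-sample scaling", {
  # scaling one of m samples by c rescales the geometric-mean reference by
  # c^(1/m), so the scaled sample's factor gains c * c^(-1/m), every other
  # factor gains c^(-1/m), relative factors gain exactly c, and the
  # normalized matrix is rescaled by the common c^(1/m)
  set.seed(7)
  counts <- matrix(rpois(30, 20) + 1, ncol = 3,
                   dimnames = list(paste0("g", 1:10), paste0("s", 1:3)))
  base <- median_of_ratios(counts)
  scaled <- counts
  scaled[, 2] <- scaled[, 2] * 5
  res <- median_of_ratios(scaled)
  m <- ncol(counts)
  expect_equal(res$size_factors[["s2"]],
               5^((m - 1) / m) * base$size_factors[["s2"]])
  expect_equal(res$size_factors[["s1"]],
               5^(-1 / m) * base$size_factors[["s1"]])
  expect_equal(res$size_factors[["s2"]] / res$size_factors[["s1"]],
               5 * base$size_factors[["s2"]] / base$size_factors[["s1"]])
  expect_equal(as.matrix(res$normalized[, -1]),
               5^(1 / m) * as.matrix(base$normalized[, -1]))
})

test_that("zero-total genes are removed; all-zero references rejected", {
  counts <- matrix(c(0, 4, 2, 0, 6, 3), ncol = 2,
                   dimnames = list(c("dead", "g2", "g3"), c("s1", "s2")))
  norm <- median_of_ratios(counts)
  expect_equal(norm$removed_genes, "dead")
  expect_equal(nrow(norm$normalized), 2)

  # a gene with one zero is kept in the output but not used for factors
  counts2 <- matrix(c(0, 4, 5, 6), ncol = 2,
                    dimnames = list(c("g1", "g2"), c("s1", "s2")))
  norm2 <- median_of_ratios(counts2)
  expect_equal(nrow(norm2$normalized), 2)

  all_zeroish <- matrix(c(0, 4, 5, 0), ncol = 2,
                        dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_error(median_of_ratios(all_zeroish), "positive counts")
})

test_that("gene weights are log2 means with the threshold boundary active", {
  mat <- matrix(c(0.125, 1, 0, 0.125, 1, 0), ncol = 2,
                dimnames = list(c("boundary", "unit", "silent"),
                                c("s1", "s2")))
  gw <- gene_weights(mat, threshold = -3)
  expect_equal(unname(gw$weight[gw$gene == "boundary"]), -3)
  expect_true(gw$active[gw$gene == "boundary"])
  expect_equal(unname(gw$weight[gw$gene == "unit"]), 0)
  expect_true(gw$active[gw$gene == "unit"])
  expect_equal(unname(gw$weight[gw$gene == "silent"]), -Inf)
  expect_false(gw$active[gw$gene == "silent"])

  # rescaling all samples shifts weights by a constant; the active set is
  # preserved when the threshold shifts accordingly
  gw2 <- gene_weights(mat * 4, threshold = -3 + 2)
  expect_equal(unname(gw2$weight[is.finite(gw2$weight)]),
               unname(gw$weight[is.finite(gw$weight)]) + 2)
  expect_equal(gw2$active, gw$active)
})

test_that("normalization chains into weights from a tibble front end", {
  counts <- tibble::tibble(gene = c("g1", "g2"), s1 = c(2, 8),
                           s2 = c(4, 16))
  gw <- counts |>
    median_of_ratios() |>
    gene_weights()
  expect_equal(nrow(gw), 2)
  expect_true(all(c("gene", "weight", "active") %in% names(gw)))
})
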