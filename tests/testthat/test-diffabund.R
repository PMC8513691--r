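test_that("size factors follow the median-of-ratios definition", {
  a <- c(10, 20, 40, 5)
  counts <- cbind(A = a, B = 2 * a)
  rownames(counts) <- paste0("f", 1:4)
  s <- size_factors(counts)
  expect_equal(unname(s), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)

  same <- cbind(A = a, B = a, C = a)
  rownames(same) <- paste0("f", 1:4)
  expect_equal(unname(size_factors(same)), rep(1, 3))

  # scaling one sample by 3 scales its factor by 3 (up to the global
  # geometric-mean renormalization 3^(1/n))
  set.seed(8)
  x <- matrix(rpois(60, 30) + 1L, 20, 3, dimnames = list(paste0("f", 1:20), paste0("s", 1:3)))
  s0 <- size_factors(x)
  x3 <- x
  x3[, 2] <- x[, 2] * 3L
  s3 <- size_factors(x3)
  expect_equal(unname(s3[2] / s0[2]), 3 / 3^(1 / 3), tolerance = 1e-10)

  # invariant to feature order; all-zero features change nothing
  expect_equal(size_factors(x[sample(20), ]), s0)
  x0 <- rbind(x, zero = 0L)
  expect_equal(size_factors(x0), s0)
})

test_that("identical groups give zero fold change and p = 1", {
  set.seed(4)
  block <- matrix(rpois(40, 25), 10, 4, dimnames = list(paste0("f", 1:10), NULL))
  counts <- cbind(block, block)
  colnames(counts) <- paste0("s", 1:8)
  md <- tibble::tibble(sample_id = colnames(counts),
                       sample_type = rep(c("ga", "gb"), each = 4))
  res <- nb_wald_two_group(counts, md, "ga", "gb", group_col = "sample_type")
  expect_true(all(res$lfc == 0))
  expect_true(all(res$p == 1))
  expect_true(all(res$p_adj >= res$p))
  expect_true(all(sign(res$wald) == sign(res$lfc)))
})

test_that("swapping the group labels flips the fold-change sign", {
  set.seed(6)
  counts <- matrix(rnbinom(200, mu = 60, size = 10), 20, 10,
                   dimnames = list(paste0("f", 1:20), paste0("s", 1:10)))
  md <- tibble::tibble(sample_id = colnames(counts),
                       grp = rep(c("a", "b"), each = 5))
  ab <- nb_wald_two_group(counts, md, "a", "b", group_col = "grp")
  ba <- nb_wald_two_group(counts, md, "b", "a", group_col = "grp")
  expect_equal(ab$lfc, -ba$lfc)
  expect_equal(ab$p, ba$p)
  # and sample order does not matter
  perm <- sample(10)
  ab2 <- nb_wald_two_group(counts[, perm], md, "a", "b", group_col = "grp")
  expect_equal(ab2$lfc, ab$lfc)
})

test_that("power increases with the planted fold change", {
  # 100 planted features on a null background of 400, so the size-factor
  # normalization is anchored by unchanged features
  power_at <- function(fold) {
    set.seed(50 + fold)
    n <- 10
    mu <- 100
    planted <- cbind(
      matrix(rnbinom(100 * n, mu = mu, size = 20), 100, n),
      matrix(rnbinom(100 * n, mu = mu * fold, size = 20), 100, n)
    )
    null_bg <- matrix(rnbinom(400 * 2 * n, mu = mu, size = 20), 400, 2 * n)
    counts <- rbind(planted, null_bg)
    dimnames(counts) <- list(paste0("f", seq_len(nrow(counts))),
                             paste0("s", 1:(2 * n)))
    md <- tibble::tibble(sample_id = colnames(counts),
                         grp = rep(c("a", "b"), each = n))
    res <- nb_wald_two_group(counts, md, "a", "b", group_col = "grp")
    mean(res$p_adj[1:100] < 0.01)
  }
  p1 <- power_at(1)
  p2 <- power_at(2)
  p4 <- power_at(4)
  expect_lte(p1, p2)
  expect_lt(p2, p4)
  expect_gt(p4, 0.9)
})

test_that("Benjamini-Hochberg step-up arithmetic and bounds", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(benjamini_hochberg(0.2), 0.2)
  expect_equal(benjamini_hochberg(rep(1, 5)), rep(1, 5))
  p <- runif(20)
  adj <- benjamini_hochberg(p)
  expect_true(all(adj >= p - 1e-15))
  expect_true(all(adj <= 1))
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(benjamini_hochberg(c(-0.1)), "\\[0, 1\\]")
})

test_that("group size and empty-feature preconditions are enforced", {
  counts <- matrix(1L, 3, 4, dimnames = list(paste0("f", 1:3), paste0("s", 1:4)))
  md <- tibble::tibble(sample_id = colnames(counts),
                       grp = c("a", "b", "b", "b"))
  expect_error(nb_wald_two_group(counts, md, "a", "b", group_col = "grp"),
               "at least 2 samples")
  # all-zero features are excluded from testing
  counts2 <- rbind(counts, zero = 0L)
  md2 <- tibble::tibble(sample_id = colnames(counts), grp = rep(c("a", "b"), each = 2))
  res <- nb_wald_two_group(counts2, md2, "a", "b", group_col = "grp")
  expect_false("zero" %in% res$feature_id)
})

test_that("taxonomic binning labels features by their lowest assigned rank", {
  res <- tibble::tibble(feature_id = c("F1", "F2", "F3"),
                        lfc = c(2, -1, 3), p_adj = c(0.001, 0.5, 0.002))
  tax <- tibble::tibble(
    feature_id = c("F1", "F2", "F3"),
    kingdom = "Bacteria", phylum = "P", class = "C", order = "O",
    family = c("Famy", "Famy", "Famy"),
    genus = c("Genu", "UNASSIGNED", "UNASSIGNED"),
    species = "UNASSIGNED"
  )
  bins <- bin_by_lowest_rank(res, tax, alpha = 0.01)
  expect_setequal(bins$bin, c("Genu", "Famy"))
  expect_equal(sum(bins$n_features), 2)
})
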