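test_that("niche weight has the Gaussian closed form and symmetry", {
  expect_equal(niche_weight(80, 80, 25), 1.0)
  expect_equal(niche_weight(105, 80, 25), exp(-1 / 2))
  d <- runif(20, -60, 60)
  expect_equal(niche_weight(80 + d, 80, 25), niche_weight(80 - d, 80, 25))
  expect_error(niche_weight(NaN, 80, 25), "finite")
  expect_error(niche_weight(80, 80, 0), "> 0")
})

test_that("simulation is bit-identical under a fixed seed", {
  a <- simulate_dataset(sim_config(), seed = 7)
  b <- simulate_dataset(sim_config(), seed = 7)
  expect_identical(a$dataset$counts, b$dataset$counts)
  expect_identical(a$dataset$taxonomy, b$dataset$taxonomy)
  expect_identical(a$truth$features, b$truth$features)
  expect_identical(a$truth$mixing, b$truth$mixing)
})

test_that("column sums equal the drawn library sizes exactly", {
  sim <- simulate_dataset(sim_config(), seed = 3)
  lib <- sim$truth$library_sizes
  expect_equal(unname(colSums(sim$dataset$counts)[lib$sample_id]),
               as.numeric(lib$library_size))
})

test_that("zero carryover leaves drill cores free of fluid-specific taxa", {
  sim <- simulate_dataset(sim_config(carryover_fixed = 0), seed = 5)
  cores <- sim$dataset$metadata$sample_id[sim$dataset$metadata$sample_type == "drill_core"]
  df_feat <- sim$truth$features$feature_id[sim$truth$features$origin == "drillfluid_only"]
  expect_true(all(sim$dataset$counts[df_feat, cores] == 0))
  expect_true(all(sim$truth$mixing$c_j == 0))
})

test_that("pre-cleaning compositional error increases with the carryover mean", {
  seeds <- 1:20
  err_at <- function(shape1) {
    mean(vapply(seeds, function(s) {
      sim <- simulate_dataset(sim_config(carryover_shape1 = shape1), seed = s)
      as.numeric(composition_error(sim$dataset$counts, sim$truth))
    }, numeric(1)))
  }
  low <- err_at(2)    # Beta(2, 6), mean 0.25
  high <- err_at(6)   # Beta(6, 6), mean 0.50
  expect_lt(low, high)
})

test_that("an infinitely wide thermal niche makes same-deposit cores exchangeable", {
  sim <- simulate_dataset(
    sim_config(niche_width_C = 1e6, inflow_fraction = 0, carryover_fixed = 0),
    seed = 2
  )
  exp_prof <- sim$truth$expected
  design <- default_core_design()
  for (dep in c("subaerial", "submarine")) {
    ids <- design$sample_id[design$deposit == dep]
    prof <- exp_prof[, ids]
    pairs <- utils::combn(length(ids), 2)
    bc <- apply(pairs, 2, function(p) {
      sum(abs(prof[, p[1]] - prof[, p[2]])) / sum(prof[, p[1]] + prof[, p[2]])
    })
    expect_true(all(bc < 0.05))
  }
})

test_that("call scoring matches the confusion-matrix definitions", {
  truth <- structure(list(
    features = tibble::tibble(
      feature_id = sprintf("F%02d", 1:20),
      origin = rep(c("drillfluid_only", "endemic_submarine"), each = 10)
    ),
    mixing = tibble::tibble(sample_id = character(0), c_j = numeric(0))
  ), class = "tephra_truth")

  perfect <- tibble::tibble(feature_id = sprintf("F%02d", 1:10), verdict = "remove")
  m <- evaluate_calls(perfect, truth)
  expect_equal(c(m$precision, m$recall, m$f1), c(1, 1, 1))

  none <- tibble::tibble(feature_id = character(0), verdict = character(0))
  m0 <- evaluate_calls(none, truth)
  expect_equal(m0$recall, 0)
  expect_equal(m0$precision, 0)
  expect_false(m0$precision_defined)

  mixed <- tibble::tibble(
    feature_id = sprintf("F%02d", c(1:8, 11:12)),  # 8 TP, 2 FP, 2 FN
    verdict = "remove"
  )
  m1 <- evaluate_calls(mixed, truth)
  expect_equal(c(m1$tp, m1$fp, m1$fn), c(8, 2, 2))
  expect_equal(c(m1$precision, m1$recall, m1$f1), c(0.8, 0.8, 0.8))

  expect_error(
    evaluate_calls(tibble::tibble(feature_id = "nope", verdict = "remove"), truth),
    "unknown feature"
  )
})

test_that("compositional error is near 0 for the true community and near 1 for fluid only", {
  cfg <- sim_config(carryover_fixed = 0, lib_meanlog = log(2e5))
  sim <- simulate_dataset(cfg, seed = 9)
  expect_lt(as.numeric(composition_error(sim$dataset$counts, sim$truth)), 0.1)

  # a core column made only of fluid-specific taxa sits at distance ~1
  df_feat <- sim$truth$features$feature_id[sim$truth$features$origin == "drillfluid_only"]
  fake <- matrix(100L, length(df_feat), 1,
                 dimnames = list(df_feat, "C33"))
  expect_gt(as.numeric(composition_error(fake, sim$truth)), 0.99)

  bad <- matrix(1L, 1, 1, dimnames = list("ASV0001", "not_a_core"))
  expect_error(composition_error(bad, sim$truth), "no drill-core samples")
})

test_that("simulation outputs round-trip through the on-disk interchange formats", {
  sim <- simulate_dataset(sim_config(), seed = 11)
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  tab <- read_feature_table(file.path(dir, "feature_table.tsv"))
  md <- read_metadata(file.path(dir, "metadata.tsv"))
  tax <- read_taxonomy(file.path(dir, "taxonomy.tsv"))
  expect_identical(tab, sim$dataset$counts)
  expect_identical(md$sample_id, sim$dataset$metadata$sample_id)
  expect_identical(tax$genus, sim$dataset$taxonomy$genus)
})
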