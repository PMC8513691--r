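# metadata for 10 true samples + 2 negative controls
prev_metadata <- function() {
  tibble::tibble(
    sample_id = c(paste0("S", 1:10), "NC1", "NC2"),
    sample_type = c(rep("drill_core", 10), rep("negative_control", 2)),
    core_category = c(rep("DC_3", 10), "none", "none"),
    depth_m = c(rep(100, 10), NA, NA),
    temperature_C = NA_real_,
    is_control = c(rep(FALSE, 10), TRUE, TRUE)
  )
}

test_that("prevalence test removes control-enriched features and skips control-absent ones", {
  counts <- rbind(
    kit = c(1L, rep(0L, 9), 5L, 7L),        # 1/10 true, 2/2 controls
    even = c(rep(1L, 5), rep(0L, 5), 3L, 0L), # 5/10 true, 1/2 controls
    endo = c(rep(2L, 10), 0L, 0L)            # absent from controls
  )
  colnames(counts) <- prev_metadata()$sample_id
  calls <- prevalence_contaminant_test(counts, prev_metadata())

  kit <- calls[calls$feature_id == "kit", ]
  expect_equal(kit$verdict, "remove")
  expect_equal(kit$p, fisher_oracle_p(1, 10, 2, 2), tolerance = 1e-12)

  even <- calls[calls$feature_id == "even", ]
  expect_equal(even$verdict, "retain")  # equal prevalence fractions
  expect_equal(even$p, 1)

  expect_false("endo" %in% calls$feature_id)
})

test_that("prevalence test demands negative controls and enough true samples", {
  md <- prev_metadata()[1:10, ]
  counts <- matrix(1L, 1, 10, dimnames = list("x", md$sample_id))
  expect_error(prevalence_contaminant_test(counts, md), "negative controls")

  md2 <- prev_metadata()[c(1, 11, 12), ]
  counts2 <- matrix(1L, 1, 3, dimnames = list("x", md2$sample_id))
  expect_error(prevalence_contaminant_test(counts2, md2), "true samples")
})

test_that("taxonomy screen applies the five lineage rules case-insensitively", {
  tax <- tibble::tibble(
    feature_id = paste0("F", 1:6),
    kingdom = c("Bacteria", "Bacteria", "Eukaryota", "UNASSIGNED", "Bacteria", "Bacteria"),
    phylum = "P", class = "C",
    order = c("Chloroplast", "O", "O", "O", "O", "O"),
    family = c("F", "Mitochondria", "F", "F", "F", "F"),
    genus = c("G", "G", "G", "G", "cutibacterium", "Marinobacter"),
    species = "S"
  )
  calls <- taxonomy_screen(tax, blocklist = c("Cutibacterium"))
  expect_setequal(
    paste(calls$feature_id, calls$rule),
    c("F1 chloroplast", "F2 mitochondria", "F3 eukaryote",
      "F4 unassigned_kingdom", "F5 genus_blocklist")
  )
  expect_true(all(calls$verdict == "remove"))
  expect_false("F6" %in% calls$feature_id)
  expect_equal(nrow(taxonomy_screen(tax[6, ], blocklist = character())), 0)
})

test_that("presence patterns reflect group membership and the count threshold", {
  counts <- matrix(
    c(0L, 0L, 0L, 9L,
      5L, 0L, 2L, 0L,
      3L, 0L, 0L, 0L),
    nrow = 3, byrow = TRUE,
    dimnames = list(c("sw_only", "suba_df", "low"),
                    c("a1", "m1", "d1", "w1"))
  )
  groups <- list(SUB_A = "a1", SUB_M = "m1", DF = "d1", SW = "w1")
  pat <- presence_pattern(counts, groups)
  expect_equal(unlist(pat[pat$feature_id == "sw_only", c("SUB_A", "SUB_M", "DF", "SW")]),
               c(SUB_A = FALSE, SUB_M = FALSE, DF = FALSE, SW = TRUE),
               ignore_attr = TRUE)
  expect_equal(unlist(pat[pat$feature_id == "suba_df", c("SUB_A", "SUB_M", "DF", "SW")]),
               c(SUB_A = TRUE, SUB_M = FALSE, DF = TRUE, SW = FALSE),
               ignore_attr = TRUE)

  pat5 <- presence_pattern(counts, groups, min_count = 5)
  expect_false(pat5$SUB_A[pat5$feature_id == "low"])

  expect_error(
    presence_pattern(counts, list(SUB_A = "a1", SUB_M = "a1", DF = "d1", SW = "w1")),
    "two overlap groups"
  )
})

test_that("overlap rules match an independent truth-table evaluation on all patterns", {
  pat <- tidyr::expand_grid(SUB_A = c(TRUE, FALSE), SUB_M = c(TRUE, FALSE),
                            DF = c(TRUE, FALSE), SW = c(TRUE, FALSE))
  pat$feature_id <- sprintf("p%02d", seq_len(nrow(pat)))
  calls <- overlap_classify(pat)
  # independent evaluation of the three boolean rules in priority order
  expected <- mapply(function(a, m, df, sw) {
    if (a && (df || sw)) "R1_subaerial_marine"
    else if (m && df && sw) "R3_inflow_retained"
    else if (m && df) "R2_drillfluid_only"
    else "endemic_candidate"
  }, pat$SUB_A, pat$SUB_M, pat$DF, pat$SW)
  expect_equal(calls$rule, unname(expected))
  expect_equal(calls$verdict == "remove",
               calls$rule %in% c("R1_subaerial_marine", "R2_drillfluid_only"))
  # submarine-only pattern is an endemic candidate
  sub_only <- calls$rule[pat$SUB_M & !pat$SUB_A & !pat$DF & !pat$SW]
  expect_equal(sub_only, "endemic_candidate")
})

test_that("overlap classification depends only on the presence pattern", {
  base <- matrix(
    c(1L, 0L, 4L, 0L, 0L,
      0L, 7L, 1L, 0L, 0L),
    nrow = 2, byrow = TRUE,
    dimnames = list(c("x", "y"), c("a1", "a2", "d1", "m1", "w1"))
  )
  groups <- list(SUB_A = c("a1", "a2"), SUB_M = "m1", DF = "d1", SW = "w1")
  r1 <- overlap_classify(presence_pattern(base, groups))
  # move counts between samples of the same group, scale wildly
  moved <- base
  moved["x", c("a1", "a2")] <- c(0L, 900L)
  moved["y", "d1"] <- 12000L
  r2 <- overlap_classify(presence_pattern(moved, groups))
  expect_equal(r1$rule, r2$rule)
  # permute feature order
  r3 <- overlap_classify(presence_pattern(base[c("y", "x"), ], groups))
  expect_equal(r3$rule[match(r1$feature_id, r3$feature_id)], r1$rule)
})

test_that("the Venn census partitions detected features", {
  counts <- matrix(rep(c(1L, 0L, 1L, 0L), 3), nrow = 3, byrow = TRUE,
                   dimnames = list(paste0("f", 1:3),
                                   c("a1", "m1", "d1", "w1")))
  groups <- list(SUB_A = "a1", SUB_M = "m1", DF = "d1", SW = "w1")
  cen <- venn_census(presence_pattern(counts, groups))
  expect_equal(nrow(cen), 15)
  expect_equal(cen$n[cen$region == "SUB_A+DF"], 3L)
  expect_equal(sum(cen$n), 3L)

  # a realized census reproduces its construction region by region
  spec_cen <- reference_census()
  fx <- incidence_from_census(spec_cen)
  got <- venn_census(fx$patterns)
  key <- paste(spec_cen$SUB_A, spec_cen$SUB_M, spec_cen$DF, spec_cen$SW)
  got_key <- paste(got$SUB_A, got$SUB_M, got$DF, got$SW)
  expect_equal(got$n[match(key, got_key)], spec_cen$n)
  expect_equal(sum(got$n), sum(spec_cen$n))
})

test_that("applying calls deletes flagged features and excluded sample types", {
  ds <- toy_dataset()
  calls <- tibble::tibble(feature_id = "ASV1", stage = "taxonomy",
                          verdict = "remove", rule = "chloroplast",
                          evidence = "x", p = NA_real_)
  cleaned <- apply_calls(ds, calls)
  expect_false("ASV1" %in% rownames(cleaned$counts))
  expect_false(any(cleaned$metadata$sample_type %in%
                     c("drilling_fluid", "negative_control")))
  kept <- intersect(colnames(ds$counts), colnames(cleaned$counts))
  expect_identical(cleaned$counts[, kept], ds$counts[rownames(cleaned$counts), kept])

  # zero calls: identity on features, sample types still dropped
  none <- calls[0, ]
  same <- apply_calls(ds, none)
  expect_identical(rownames(same$counts), rownames(ds$counts))

  # removed-read fraction arithmetic on a 3x3 toy
  toy <- matrix(c(5L, 0L, 1L, 2L, 3L, 4L, 1L, 1L, 1L), 3,
                dimnames = list(paste0("t", 1:3), c("s1", "s2", "s3")))
  md <- tibble::tibble(sample_id = c("s1", "s2", "s3"),
                       sample_type = "seawater", core_category = "none",
                       depth_m = NA_real_, temperature_C = NA_real_,
                       is_control = FALSE)
  tds <- harmonize(toy, md)
  cl <- apply_calls(tds, tibble::tibble(feature_id = "t1", verdict = "remove"))
  rep <- attr(cl, "removal_report")
  expect_equal(rep$fraction_removed,
               1 - colSums(toy[-1, ]) / colSums(toy), ignore_attr = TRUE)

  all_calls <- tibble::tibble(feature_id = rownames(ds$counts), verdict = "remove")
  expect_error(apply_calls(ds, all_calls), "all features removed")
  expect_error(apply_calls(ds, tibble::tibble(feature_id = "zzz", verdict = "remove")),
               "unknown feature")
})

test_that("the cascade's remove set is R1 and R2, disjoint from R3, and counts add up", {
  fx <- incidence_from_census(reference_census())
  calls <- overlap_classify(fx$patterns)
  removed <- calls$feature_id[calls$verdict == "remove"]
  r3 <- calls$feature_id[calls$rule == "R3_inflow_retained"]
  expect_length(intersect(removed, r3), 0)
  tallies <- table(calls$rule)
  expect_equal(sum(tallies), nrow(fx$patterns))
  expect_equal(length(removed),
               sum(tallies[c("R1_subaerial_marine", "R2_drillfluid_only")]))
})

test_that("default overlap grouping splits cores at the subaerial boundary", {
  sim <- simulate_dataset(sim_config(), seed = 1)
  g <- default_overlap_groups(sim$dataset$metadata)
  expect_setequal(g$SUB_A, c("C4", "C9", "C13", "C17"))
  expect_length(g$SUB_M, 13)
  expect_length(g$DF, 8)
  expect_length(g$SW, 4)
})
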